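#' Landscape specification between two sequences
#'
#' Defines the combinatorial genotype space spanned by a \code{source} and a
#' \code{target} sequence of equal length. In \code{"biallelic"} mode each
#' site admits only the source and target symbols (a singleton where they
#' agree), so the space is a hypercube with \code{2^d} vertices, where
#' \code{d} is the number of differing sites. In \code{"full"} mode every
#' site ranges over a supplied alphabet; the full space is never
#' materialized, but its size and neighbor queries are available.
#'
#' Symbols are case-normalized to uppercase on ingestion, matching the
#' case-insensitive word-frequency fitness proxy used downstream.
#'
#' @param source,target character scalars of equal, positive length.
#' @param mode `"biallelic"` (default) or `"full"`.
#' @param alphabet character vector of single symbols used at every site in
#'   full mode (default `LETTERS`).
#' @return An object of class `landscape_spec` with fields `source`,
#'   `target`, `L`, `mode`, `site_alphabets` (list of per-site symbol sets)
#'   and `differing_sites` (integer indices where source and target differ).
#' @examples
#' spec <- landscape_spec("WORD", "GENE")
#' spec$differing_sites   # 1 2 3 4
#' space_size(spec)       # 16
#' @export
landscape_spec <- function(source, target, mode = c("biallelic", "full"),
                           alphabet = LETTERS) {
  mode <- match.arg(mode)
  src <- split_symbols(source)
  tgt <- split_symbols(target)
  if (length(src) != length(tgt)) {
    stop("source and target must have equal length (got ",
         length(src), " and ", length(tgt), ")")
  }
  differing <- which(src != tgt)
  if (mode == "biallelic") {
    site_alphabets <- lapply(seq_along(src), function(i) {
      unique(c(src[i], tgt[i]))
    })
  } else {
    alphabet <- toupper(alphabet)
    if (anyDuplicated(alphabet) || any(nchar(alphabet) != 1L)) {
      stop("alphabet must be distinct single characters")
    }
    if (!all(c(src, tgt) %in% alphabet)) {
      stop("source/target contain symbols outside the supplied alphabet")
    }
    site_alphabets <- rep(list(alphabet), length(src))
  }
  structure(
    list(source = paste(src, collapse = ""),
         target = paste(tgt, collapse = ""),
         L = length(src),
         mode = mode,
         site_alphabets = site_alphabets,
         differing_sites = differing),
    class = "landscape_spec")
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat("Landscape spec: ", x$source, " -> ", x$target,
      " (", x$mode, ", L = ", x$L,
      ", d = ", length(x$differing_sites), ")\n", sep = "")
  cat("Space size:", format(space_size(x), big.mark = ","), "\n")
  invisible(x)
}

# split a word into uppercase single-character symbols; errors on empty or
# non-scalar input
split_symbols <- function(word) {
  if (!is.character(word) || length(word) != 1L || is.na(word)) {
    stop("sequence must be a single character string")
  }
  if (nchar(word) == 0L) stop("sequence must be nonempty")
  strsplit(toupper(word), "", fixed = TRUE)[[1]]
}

# maximum number of differing sites we will enumerate (2^20 ~ 1M vertices)
MAX_ENUM_SITES <- 20L
# maximum d for direct-path enumeration (9! = 362,880 paths)
MAX_PATH_SITES <- 9L

#' Enumerate the biallelic hypercube between two sequences
#'
#' Returns every genotype formable by choosing, at each site, either the
#' source or the target symbol: `2^d` genotypes for `d` differing sites,
#' always including source and target. Output is sorted lexicographically
#' (C locale) for reproducibility.
#'
#' @param source,target equal-length character scalars, or a single
#'   `landscape_spec` passed as `source`.
#' @return character vector of genotypes.
#' @examples
#' h <- build_hypercube("WORD", "GENE")
#' length(h)                         # 16
#' all(c("WORE", "GORE", "WERE") %in% h)
#' @export
build_hypercube <- function(source, target = NULL) {
  spec <- as_landscape_spec(source, target)
  d <- length(spec$differing_sites)
  if (d > MAX_ENUM_SITES) {
    stop("refusing to enumerate 2^", d, " genotypes (d = ", d,
         " differing sites exceeds the limit of ", MAX_ENUM_SITES, ")")
  }
  src <- split_symbols(spec$source)
  choices <- spec$site_alphabets
  if (spec$mode == "full") {
    stop("full-alphabet spaces are not materialized; use space_size() and ",
         "one_mutant_neighbors() instead")
  }
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  genotypes <- do.call(paste0, grid)
  sort_c(unique(genotypes))
}

# coerce (source, target) or an existing spec into a landscape_spec
as_landscape_spec <- function(source, target = NULL) {
  if (inherits(source, "landscape_spec")) return(source)
  landscape_spec(source, target)
}

# locale-independent lexicographic sort (radix sort uses C collation)
sort_c <- function(x) sort(x, method = "radix")

#' Size of a genotype space
#'
#' Biallelic mode: `2^d` for `d` differing sites. Full mode: the product of
#' per-site alphabet sizes (e.g. four sites over 26 letters gives
#' `26^4 = 456976`).
#'
#' @param spec a `landscape_spec`.
#' @param mode optional override of the spec's mode.
#' @return numeric scalar (may exceed integer range).
#' @examples
#' space_size(landscape_spec("WORD", "GENE"))               # 16
#' space_size(landscape_spec("WORD", "GENE", mode = "full")) # 456976
#' @export
space_size <- function(spec, mode = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  mode <- if (is.null(mode)) spec$mode else match.arg(mode, c("biallelic", "full"))
  if (mode == "biallelic") {
    2 ^ length(spec$differing_sites)
  } else {
    if (spec$mode == "biallelic") {
      stop("spec was built in biallelic mode; rebuild with mode = \"full\" ",
           "to query the full-alphabet size")
    }
    prod(vapply(spec$site_alphabets, length, integer(1)))
  }
}

#' One-mutant neighbors of a genotype
#'
#' All genotypes in the space at Hamming distance exactly 1 from `g`. In a
#' biallelic space with `d` differing sites every genotype has exactly `d`
#' neighbors; in full mode each site contributes `|alphabet| - 1`.
#'
#' @param g genotype string (member of the space).
#' @param spec a `landscape_spec`.
#' @return character vector of neighbor genotypes, lexicographically sorted.
#' @examples
#' spec <- landscape_spec("WORD", "GENE")
#' one_mutant_neighbors("WORE", spec)  # GORE, WERE, WONE, WORD
#' @export
one_mutant_neighbors <- function(g, spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  sym <- split_symbols(g)
  if (length(sym) != spec$L) {
    stop("genotype '", g, "' has length ", length(sym),
         " but the space has L = ", spec$L)
  }
  ok <- vapply(seq_len(spec$L), function(i) {
    sym[i] %in% spec$site_alphabets[[i]]
  }, logical(1))
  if (!all(ok)) {
    stop("genotype '", g, "' is outside the space: symbol at site ",
         which(!ok)[1], " not in that site's alphabet")
  }
  out <- character(0)
  for (i in seq_len(spec$L)) {
    for (a in setdiff(spec$site_alphabets[[i]], sym[i])) {
      nb <- sym
      nb[i] <- a
      out <- c(out, paste(nb, collapse = ""))
    }
  }
  sort_c(out)
}

#' Enumerate direct mutational paths from source to target
#'
#' A direct path changes each differing site exactly once, always to the
#' target symbol, so there are `d!` of them for `d` differing sites (24 for
#' a four-site landscape). Paths are returned in lexicographic order of
#' their site permutation.
#'
#' @param spec a biallelic `landscape_spec`.
#' @return list of paths; each path is a list with `genotypes` (character,
#'   length `d + 1`) and `step_sites` (integer, length `d`: the site changed
#'   at each step).
#' @examples
#' paths <- enumerate_direct_paths(landscape_spec("WORD", "GENE"))
#' length(paths)               # 24
#' paths[[1]]$genotypes[1]     # "WORD"
#' @export
enumerate_direct_paths <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (spec$mode != "biallelic") {
    stop("direct paths are defined for biallelic specs")
  }
  d <- length(spec$differing_sites)
  if (d > MAX_PATH_SITES) {
    stop("refusing to enumerate ", d, "! paths (d = ", d,
         " exceeds the limit of ", MAX_PATH_SITES, ")")
  }
  src <- split_symbols(spec$source)
  tgt <- split_symbols(spec$target)
  perms <- permutations_lex(spec$differing_sites)
  lapply(perms, function(order) {
    sym <- src
    genotypes <- paste(sym, collapse = "")
    for (site in order) {
      sym[site] <- tgt[site]
      genotypes <- c(genotypes, paste(sym, collapse = ""))
    }
    list(genotypes = genotypes, step_sites = order)
  })
}

# all permutations of v in lexicographic order; v assumed sorted ascending.
# For v empty returns the single empty permutation.
permutations_lex <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(v))
  out <- vector("list", factorial(n))
  k <- 0L
  recurse <- function(prefix, rest) {
    if (length(rest) == 0L) {
      k <<- k + 1L
      out[[k]] <<- prefix
      return(invisible(NULL))
    }
    for (i in seq_along(rest)) {
      recurse(c(prefix, rest[i]), rest[-i])
    }
  }
  recurse(integer(0), v)
  out
}

#' Write a genotype space as edge and node lists
#'
#' Serializes the biallelic hypercube to a plain-text edge list (one
#' `genotype TAB genotype` adjacency pair per line, each undirected edge
#' once with the lexicographically smaller genotype first) and a node-list
#' CSV with columns `genotype` and `hamming_to_source`.
#'
#' @param spec a biallelic `landscape_spec`.
#' @param edge_file,node_file output paths; `NULL` skips that file.
#' @return invisibly, a list with the edge data.frame and node data.frame.
#' @export
write_space <- function(spec, edge_file = NULL, node_file = NULL) {
  genotypes <- build_hypercube(spec)
  edges <- list()
  for (g in genotypes) {
    for (nb in one_mutant_neighbors(g, spec)) {
      if (g < nb) edges[[length(edges) + 1L]] <- c(g, nb)
    }
  }
  edge_df <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  names(edge_df) <- c("from", "to")
  src <- split_symbols(spec$source)
  node_df <- data.frame(
    genotype = genotypes,
    hamming_to_source = vapply(genotypes, function(g) {
      sum(split_symbols(g) != src)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(edge_file)) {
    utils::write.table(edge_df, edge_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(node_file)) {
    utils::write.csv(node_df, node_file, row.names = FALSE, quote = FALSE)
  }
  invisible(list(edges = edge_df, nodes = node_df))
}

# Hamming distance between two equal-length words
hamming <- function(a, b) {
  sum(split_symbols(a) != split_symbols(b))
}
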