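# Independent brute-force oracles, deliberately implemented differently
# from the package internals (index arithmetic instead of recursion, raw
# string surgery instead of spec objects).

# all genotypes between src and tgt by binary masks over differing sites
oracle_hypercube <- function(src, tgt) {
  s <- strsplit(toupper(src), "")[[1]]
  t <- strsplit(toupper(tgt), "")[[1]]
  diffs <- which(s != t)
  d <- length(diffs)
  out <- character(2^d)
  for (mask in 0:(2^d - 1)) {
    g <- s
    for (b in seq_len(d)) {
      if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) {
        g[diffs[b]] <- t[diffs[b]]
      }
    }
    out[mask + 1L] <- paste(g, collapse = "")
  }
  unique(out)
}

# permutations via factorial-base decoding (Lehmer codes), not recursion
oracle_permutations <- function(v) {
  n <- length(v)
  if (n == 0) return(list(integer(0)))
  total <- factorial(n)
  lapply(seq_len(total) - 1L, function(code) {
    avail <- v
    perm <- integer(n)
    for (pos in seq_len(n)) {
      f <- factorial(n - pos)
      idx <- code %/% f
      code <- code %% f
      perm[pos] <- avail[idx + 1L]
      avail <- avail[-(idx + 1L)]
    }
    perm
  })
}

# number of accessible direct paths by direct enumeration over Lehmer-coded
# site orderings
oracle_count_accessible <- function(src, tgt, fitness, strict = TRUE) {
  s <- strsplit(toupper(src), "")[[1]]
  t <- strsplit(toupper(tgt), "")[[1]]
  diffs <- which(s != t)
  n_acc <- 0L
  for (perm in oracle_permutations(diffs)) {
    g <- s
    f_prev <- fitness[[paste(g, collapse = "")]]
    ok <- TRUE
    for (site in perm) {
      g[site] <- t[site]
      f_cur <- fitness[[paste(g, collapse = "")]]
      if (if (strict) f_cur <= f_prev else f_cur < f_prev) {
        ok <- FALSE
        break
      }
      f_prev <- f_cur
    }
    if (ok) n_acc <- n_acc + 1L
  }
  n_acc
}

# peaks by exhaustive single-site flips
oracle_peaks <- function(src, tgt, fitness) {
  s <- strsplit(toupper(src), "")[[1]]
  t <- strsplit(toupper(tgt), "")[[1]]
  diffs <- which(s != t)
  genos <- oracle_hypercube(src, tgt)
  peaks <- character(0)
  for (g in genos) {
    gs <- strsplit(g, "")[[1]]
    fitter <- FALSE
    for (site in diffs) {
      nb <- gs
      nb[site] <- if (gs[site] == s[site]) t[site] else s[site]
      if (fitness[[paste(nb, collapse = "")]] > fitness[[g]]) fitter <- TRUE
    }
    if (!fitter) peaks <- c(peaks, g)
  }
  peaks
}

# random word pair with exactly d differing sites, plus a random fitness
# table over its hypercube
random_landscape <- function(d, seed) {
  set.seed(seed)
  L <- d + sample(0:2, 1)
  src <- sample(LETTERS, L, replace = TRUE)
  tgt <- src
  flip <- sample(seq_len(L), d)
  for (i in flip) {
    tgt[i] <- sample(setdiff(LETTERS, src[i]), 1)
  }
  src <- paste(src, collapse = "")
  tgt <- paste(tgt, collapse = "")
  genos <- oracle_hypercube(src, tgt)
  fitness <- stats::setNames(stats::runif(length(genos)), genos)
  list(source = src, target = tgt, fitness = fitness)
}

word_gene_spec <- function() landscape_spec("WORD", "GENE")

hamming_chars <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
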