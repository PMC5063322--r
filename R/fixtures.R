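#' Generate a synthetic landscape fixture
#'
#' Builds an `environment_series` over the biallelic hypercube between
#' `source` and `target` with one of four archetypes whose qualitative
#' structure is asserted at generation time (bad parameter combinations
#' error rather than silently producing a different landscape). Fixtures
#' encode qualitative orderings, not any real corpus values.
#'
#' \describe{
#'   \item{`additive`}{fitness `base * (1 + inc)^m` where `m` is the
#'     number of sites matching the target: a smooth landscape, every
#'     direct path accessible, unique peak at the target.}
#'   \item{`dominant_interior_peak`}{additive, then the `peak` genotype is
#'     multiplied by `peak_multiplier` (default `1e3`, i.e. orders of
#'     magnitude above the rest) and the source is raised just above its
#'     one-mutant neighbors. The population must leave the source against
#'     selection, and the interior peak dominates the landscape — the
#'     trapping / stochastic-tunneling regime.}
#'   \item{`source_trapped`}{additive, then the source is raised above all
#'     its one-mutant neighbors: no accessible direct path leaves it.}
#'   \item{`env_flip`}{two environments. The first is additive (everything
#'     accessible, and the second member of `flip_pair` outranks the
#'     first). In the second the source is raised above the whole
#'     landscape, reversing the `flip_pair` order and closing every path
#'     out of the source.}
#' }
#'
#' @param source,target equal-length words defining the hypercube.
#' @param archetype one of `"additive"`, `"dominant_interior_peak"`,
#'   `"source_trapped"`, `"env_flip"`.
#' @param base baseline fitness (default `1e-6`, a plausible word-usage
#'   frequency scale).
#' @param inc per-matching-site multiplicative increment (default 0.5).
#' @param peak genotype receiving the dominant-peak multiplier (required
#'   for `dominant_interior_peak`; e.g. `"WERE"` for WORD -> GENE).
#' @param peak_multiplier multiplier for the dominant peak (default `1e3`).
#' @param flip_pair two genotypes whose fitness order differs between the
#'   two `env_flip` environments; default: the source and its neighbor at
#'   the first differing site (e.g. GENE and BENE for GENE -> BIRD).
#' @param environments environment labels; defaults: `"1900"` for
#'   single-environment archetypes, `c("1800", "2000")` for `env_flip`.
#' @param jitter_sd standard deviation of optional multiplicative
#'   log-normal noise (default 0, fully deterministic). The advertised
#'   orderings are re-asserted after jittering.
#' @param seed RNG seed, used only when `jitter_sd > 0`.
#' @return an `environment_series`; its `fixture` attribute records the
#'   archetype and parameters.
#' @examples
#' fx <- make_landscape_fixture("WORD", "GENE",
#'                              archetype = "dominant_interior_peak",
#'                              peak = "WERE")
#' find_peaks(landscape_spec("WORD", "GENE"), fx$tables[[1]])$peaks
#' @export
make_landscape_fixture <- function(source, target,
                                   archetype = c("additive",
                                                 "dominant_interior_peak",
                                                 "source_trapped",
                                                 "env_flip"),
                                   base = 1e-6, inc = 0.5,
                                   peak = NULL, peak_multiplier = 1e3,
                                   flip_pair = NULL,
                                   environments = NULL,
                                   jitter_sd = 0, seed = 1L) {
  archetype <- match.arg(archetype)
  if (base <= 0) stop("base fitness must be positive")
  if (inc <= 0) stop("per-step increment must be positive")
  spec <- landscape_spec(source, target)
  genotypes <- build_hypercube(spec)
  tgt <- split_symbols(spec$target)
  matches <- vapply(genotypes, function(g) {
    sum(split_symbols(g) == tgt)
  }, numeric(1))
  additive <- base * (1 + inc) ^ matches
  names(additive) <- genotypes

  jitter <- function(v) {
    if (jitter_sd <= 0) return(v)
    set.seed(seed)
    v * exp(stats::rnorm(length(v), 0, jitter_sd))
  }
  boost_source <- function(v) {
    nb <- one_mutant_neighbors(spec$source, spec)
    # sqrt(1 + inc) puts the source strictly between its neighbors' level
    # and the next additive level, avoiding exact fitness ties
    v[spec$source] <- sqrt(1 + inc) * max(v[nb])
    v
  }
  assert_source_trapped <- function(v) {
    nb <- one_mutant_neighbors(spec$source, spec)
    if (!all(v[spec$source] > v[nb])) {
      stop("fixture parameters break the advertised ordering: source is ",
           "not fitter than all its neighbors")
    }
  }

  if (archetype == "env_flip") {
    if (is.null(environments)) environments <- c("1800", "2000")
    if (length(environments) != 2) {
      stop("env_flip needs exactly 2 environment labels")
    }
    if (is.null(flip_pair)) {
      first_diff <- spec$differing_sites[1]
      sym <- split_symbols(spec$source)
      sym[first_diff] <- tgt[first_diff]
      flip_pair <- c(spec$source, paste(sym, collapse = ""))
    }
    flip_pair <- toupper(flip_pair)
    if (!all(flip_pair %in% genotypes)) {
      stop("flip_pair genotypes must lie in the hypercube")
    }
    v1 <- jitter(additive)
    v2 <- additive
    v2[spec$source] <- (1 + inc) * max(additive)
    v2 <- jitter(v2)
    if (!(v1[flip_pair[2]] > v1[flip_pair[1]] &&
          v2[flip_pair[1]] > v2[flip_pair[2]])) {
      stop("fixture parameters break the advertised ordering: flip pair (",
           flip_pair[1], ", ", flip_pair[2],
           ") is not reversed between environments")
    }
    nb <- one_mutant_neighbors(spec$source, spec)
    if (!all(v2[spec$source] > v2[nb])) {
      stop("fixture parameters break the advertised ordering: source is ",
           "not a peak in the second environment")
    }
    series <- environment_series(list(
      fitness_table(v1, environments[1]),
      fitness_table(v2, environments[2])))
  } else {
    if (is.null(environments)) environments <- "1900"
    v <- additive
    if (archetype == "dominant_interior_peak") {
      if (is.null(peak)) stop("dominant_interior_peak requires a peak genotype")
      peak <- toupper(peak)
      if (!peak %in% genotypes) stop("peak '", peak, "' is not in the hypercube")
      if (peak %in% c(spec$source, spec$target)) {
        stop("peak must be an interior genotype (not source or target)")
      }
      if (peak_multiplier <= 1) stop("peak_multiplier must exceed 1")
      v <- boost_source(v)
      v[peak] <- v[peak] * peak_multiplier
      v <- jitter(v)
      if (!all(v[peak] > v[setdiff(genotypes, peak)])) {
        stop("fixture parameters break the advertised ordering: '", peak,
             "' is not the unique global maximum")
      }
      assert_source_trapped(v)
    } else if (archetype == "source_trapped") {
      v <- jitter(boost_source(v))
      assert_source_trapped(v)
    } else {
      v <- jitter(v)
      # additive: fitness must stay strictly increasing in matches-to-target
      by_m <- split(v, matches)
      mlev <- as.numeric(names(by_m))
      for (k in seq_len(length(by_m) - 1)) {
        if (max(by_m[[k]]) >= min(by_m[[k + 1]])) {
          stop("fixture parameters break the advertised ordering: additive ",
               "fitness is not strictly increasing in matches to target ",
               "(jitter too large?)")
        }
      }
    }
    series <- environment_series(lapply(environments, function(e) {
      fitness_table(v, e)
    }))
  }
  attr(series, "fixture") <- list(
    archetype = archetype, source = spec$source, target = spec$target,
    base = base, inc = inc, peak = peak, peak_multiplier = peak_multiplier,
    flip_pair = flip_pair, jitter_sd = jitter_sd, seed = seed,
    note = "synthetic fixture: qualitative orderings only, no real corpus values")
  series
}

#' Write synthetic ngram-export files reproducing a fitness series
#'
#' Writes a Google-Books-style 1-gram export TSV and a totalcounts file
#' whose computed frequencies reproduce the given series to within
#' `1 / total`: each word's match count is `round(fitness * total)`.
#' Errors if rounding would not preserve the strict fitness orderings
#' within any environment (choose a larger `total`). Environment labels
#' must be integer years. With `split_case = TRUE` each word's count is
#' split across a capitalized and a lowercase row, exercising
#' case-insensitive aggregation downstream.
#'
#' @param series an `environment_series` with all fitness values in
#'   \[0, 1\] (frequencies).
#' @param dir output directory (created if needed).
#' @param total corpus total word count per year (default `1e9`).
#' @param split_case split each count across case variants (default
#'   `TRUE`).
#' @return list with `ngram_file` and `totals_file` paths.
#' @export
make_ngram_files <- function(series, dir, total = 1e9, split_case = TRUE) {
  stopifnot(inherits(series, "environment_series"))
  years <- suppressWarnings(as.integer(series$environments))
  if (any(is.na(years))) {
    stop("ngram files need integer-year environment labels")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- character(0)
  for (k in seq_along(series$environments)) {
    vals <- series$tables[[k]]$values
    if (any(vals > 1)) {
      stop("fitness values must be frequencies in [0, 1] to be encoded as ",
           "ngram counts")
    }
    counts <- round(vals * total)
    # rounding must preserve every strict ordering in this environment
    o <- order(vals)
    sv <- vals[o]; sc <- counts[o]
    strict <- which(diff(sv) > 0)
    if (any(sc[strict + 1] <= sc[strict])) {
      stop("rounding at total = ", format(total, scientific = TRUE),
           " does not preserve the fitness orderings; increase total")
    }
    for (w in names(counts)) {
      n <- counts[[w]]
      if (n == 0) next
      vol <- max(1, round(n / 100))
      if (split_case) {
        n1 <- n %/% 2
        n2 <- n - n1
        lower <- tolower(w)
        capped <- paste0(toupper(substr(lower, 1, 1)),
                         substr(lower, 2, nchar(lower)))
        if (n1 > 0) {
          rows <- c(rows, paste(capped, years[k], n1, vol, sep = "\t"))
        }
        rows <- c(rows, paste(lower, years[k], n2, vol, sep = "\t"))
      } else {
        rows <- c(rows, paste(tolower(w), years[k], n, vol, sep = "\t"))
      }
    }
  }
  ngram_file <- file.path(dir, "synthetic-1grams.tsv")
  totals_file <- file.path(dir, "synthetic-totalcounts.txt")
  writeLines(rows, ngram_file)
  groups <- paste(years, format(total, scientific = FALSE),
                  round(total / 500), round(total / 1e5), sep = ",")
  writeLines(paste(groups, collapse = " "), totals_file)
  list(ngram_file = ngram_file, totals_file = totals_file)
}
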