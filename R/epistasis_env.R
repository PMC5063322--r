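# tolerance used to call a computed interaction exactly zero (floating noise)
EPSILON_TOL <- 1e-12

#' Pairwise epistasis from the four-point test
#'
#' Given the fitness of the four genotypes spanned by two sites on a fixed
#' background — `f00` (neither substitution), `f01`, `f10` (each single),
#' `f11` (both) — the log-scale interaction is
#' `epsilon = log f11 - log f10 - log f01 + log f00`. Multiplicative
#' fitness (`f11 = f10 * f01 / f00`) gives `epsilon = 0`. The linear scale
#' replaces log fitness by fitness (additivity instead of
#' multiplicativity).
#'
#' Sign classification follows the standard taxonomy: `none` when epsilon
#' is zero (within tolerance) and no single-substitution effect changes
#' sign across backgrounds; `magnitude` when epsilon is nonzero but both
#' effects keep their sign; `sign` when exactly one effect flips sign;
#' `reciprocal_sign` when both do.
#'
#' @param f00,f01,f10,f11 fitness values; strictly positive on the log
#'   scale (apply a pseudocount upstream if the landscape contains zeros).
#' @param scale `"log"` (default) or `"linear"`.
#' @return an `epistasis_result`: list with `epsilon`, `sign_class`,
#'   `effects` (the four conditional effects) and `scale`.
#' @examples
#' pairwise_epistasis(1, 2, 2, 4)$epsilon       # 0 (multiplicative)
#' pairwise_epistasis(1, 2, 2, 1)$sign_class    # "reciprocal_sign"
#' @export
pairwise_epistasis <- function(f00, f01, f10, f11,
                               scale = c("log", "linear")) {
  scale <- match.arg(scale)
  f <- c(f00 = f00, f01 = f01, f10 = f10, f11 = f11)
  if (any(!is.finite(f))) stop("fitness values must be finite")
  if (scale == "log") {
    if (any(f <= 0)) {
      stop("log-scale epistasis requires strictly positive fitness; ",
           "apply a pseudocount upstream (got ",
           paste(names(f)[f <= 0], collapse = ", "), " <= 0)")
    }
    g <- log(f)
  } else {
    if (any(f < 0)) stop("fitness values must be non-negative")
    g <- f
  }
  eps <- g[["f11"]] - g[["f10"]] - g[["f01"]] + g[["f00"]]
  # effect of substitution A (first site) on each background of B, and
  # vice versa
  effects <- c(dA_b0 = g[["f10"]] - g[["f00"]],
               dA_b1 = g[["f11"]] - g[["f01"]],
               dB_a0 = g[["f01"]] - g[["f00"]],
               dB_a1 = g[["f11"]] - g[["f10"]])
  flips_A <- sign_flip(effects[["dA_b0"]], effects[["dA_b1"]])
  flips_B <- sign_flip(effects[["dB_a0"]], effects[["dB_a1"]])
  sign_class <- if (flips_A && flips_B) {
    "reciprocal_sign"
  } else if (flips_A || flips_B) {
    "sign"
  } else if (abs(eps) > EPSILON_TOL) {
    "magnitude"
  } else {
    "none"
  }
  structure(list(epsilon = unname(eps), sign_class = sign_class,
                 effects = effects, scale = scale),
            class = "epistasis_result")
}

# a substitution's effect flips sign when it is strictly beneficial on one
# background and strictly deleterious on the other
sign_flip <- function(e1, e2) {
  (e1 > EPSILON_TOL & e2 < -EPSILON_TOL) ||
    (e1 < -EPSILON_TOL & e2 > EPSILON_TOL)
}

#' All-pairs epistasis scan over a biallelic landscape
#'
#' Computes the four-point interaction for every pair of differing sites on
#' every shared background of the remaining differing sites:
#' `choose(d, 2) * 2^(d - 2)` results for `d >= 2` (24 for `d = 4`).
#'
#' @param spec a biallelic `landscape_spec`.
#' @param table a `fitness_table` covering the hypercube.
#' @param scale `"log"` (default) or `"linear"`.
#' @return data.frame with columns `site_i`, `site_j`, `background` (the
#'   background genotype carrying the source symbol at both focal sites),
#'   `epsilon` and `sign_class`.
#' @export
all_pairs_epistasis <- function(spec, table, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(spec, "landscape_spec"))
  d_sites <- spec$differing_sites
  if (length(d_sites) < 2) {
    stop("need at least 2 differing sites for pairwise epistasis")
  }
  src <- split_symbols(spec$source)
  tgt <- split_symbols(spec$target)
  rows <- list()
  pairs <- utils::combn(d_sites, 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    others <- setdiff(d_sites, c(i, j))
    # enumerate backgrounds: source/target choice at each remaining site
    n_bg <- 2 ^ length(others)
    for (b in seq_len(n_bg) - 1L) {
      sym <- src
      if (length(others) > 0) {
        bits <- as.integer(intToBits(b))[seq_along(others)]
        sym[others[bits == 1L]] <- tgt[others[bits == 1L]]
      }
      g00 <- sym
      g10 <- sym; g10[i] <- tgt[i]
      g01 <- sym; g01[j] <- tgt[j]
      g11 <- sym; g11[i] <- tgt[i]; g11[j] <- tgt[j]
      words <- vapply(list(g00, g01, g10, g11), paste, character(1),
                      collapse = "")
      f <- fitness_of(table, words)
      res <- pairwise_epistasis(f[1], f[2], f[3], f[4], scale = scale)
      rows[[length(rows) + 1L]] <- data.frame(
        site_i = i, site_j = j, background = words[1],
        epsilon = res$epsilon, sign_class = res$sign_class,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$site_i, out$site_j, out$background), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Landscape-by-environment interaction report
#'
#' Quantifies how the landscape's topography changes across environments:
#' per-environment accessibility counts, Spearman rank correlation of
#' genotype fitness between every environment pair, and all fitness-order
#' flip events — genotype pairs strictly ordered one way in one environment
#' and the opposite way in another (the allele-level genotype-by-environment
#' effects that compose the landscape-level interaction).
#'
#' @param spec a biallelic `landscape_spec`.
#' @param series an `environment_series` with at least 2 environments
#'   covering the hypercube.
#' @param strict passed to [count_accessible()].
#' @return an `environment_interaction_report`: list with
#'   `accessibility_by_environment` (named integer vector),
#'   `rank_correlations` (data.frame `env_a`, `env_b`, `rank_correlation`),
#'   `rank_change_events` (data.frame `genotype_a`, `genotype_b`, `env_a`,
#'   `env_b`) and `ranks` (genotype-by-environment rank matrix; rank 1 =
#'   fittest).
#' @export
environment_interaction <- function(spec, series, strict = TRUE) {
  stopifnot(inherits(series, "environment_series"))
  envs <- series$environments
  if (length(envs) < 2) stop("need at least 2 environments")
  genotypes <- build_hypercube(spec)
  fmat <- vapply(envs, function(e) {
    fitness_of(series$tables[[e]], genotypes)
  }, numeric(length(genotypes)))
  rownames(fmat) <- genotypes
  ranks <- apply(-fmat, 2, rank, ties.method = "average")
  access <- vapply(envs, function(e) {
    count_accessible(spec, series$tables[[e]], strict = strict)$n_accessible
  }, integer(1))
  ep <- utils::combn(envs, 2)
  cors <- data.frame(
    env_a = ep[1, ], env_b = ep[2, ],
    rank_correlation = vapply(seq_len(ncol(ep)), function(k) {
      stats::cor(fmat[, ep[1, k]], fmat[, ep[2, k]], method = "spearman")
    }, numeric(1)),
    stringsAsFactors = FALSE)
  flips <- list()
  gp <- utils::combn(genotypes, 2)
  for (k in seq_len(ncol(ep))) {
    a <- ep[1, k]; b <- ep[2, k]
    da <- fmat[gp[1, ], a] - fmat[gp[2, ], a]
    db <- fmat[gp[1, ], b] - fmat[gp[2, ], b]
    hit <- which(da * db < 0)  # strictly ordered both ways
    if (length(hit) > 0) {
      flips[[length(flips) + 1L]] <- data.frame(
        genotype_a = gp[1, hit], genotype_b = gp[2, hit],
        env_a = a, env_b = b, stringsAsFactors = FALSE)
    }
  }
  flips <- if (length(flips)) {
    do.call(rbind, flips)
  } else {
    data.frame(genotype_a = character(0), genotype_b = character(0),
               env_a = character(0), env_b = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(flips) <- NULL
  structure(list(environments = envs,
                 accessibility_by_environment = access,
                 rank_correlations = cors,
                 rank_change_events = flips,
                 ranks = ranks),
            class = "environment_interaction_report")
}

#' @export
print.environment_interaction_report <- function(x, ...) {
  cat("Landscape-by-environment interaction across ",
      length(x$environments), " environments\n", sep = "")
  cat("Accessible direct paths: ",
      paste(sprintf("%s=%d", names(x$accessibility_by_environment),
                    x$accessibility_by_environment), collapse = ", "),
      "\n", sep = "")
  cat("Mean rank correlation: ",
      format(mean(x$rank_correlations$rank_correlation), digits = 3),
      "; ", nrow(x$rank_change_events), " order-flip events\n", sep = "")
  invisible(x)
}

#' Write epistasis / interaction results to CSV
#'
#' @param epistasis data.frame from [all_pairs_epistasis()], or `NULL`.
#' @param interaction an `environment_interaction_report`, or `NULL`.
#' @param epistasis_file,correlation_file output paths.
#' @return invisibly `NULL`.
#' @export
write_epistasis_csv <- function(epistasis = NULL, interaction = NULL,
                                epistasis_file = NULL,
                                correlation_file = NULL) {
  if (!is.null(epistasis) && !is.null(epistasis_file)) {
    utils::write.csv(epistasis, epistasis_file, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(interaction) && !is.null(correlation_file)) {
    utils::write.csv(interaction$rank_correlations, correlation_file,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}
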