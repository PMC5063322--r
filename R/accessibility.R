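#' Test whether a mutational path is accessible
#'
#' A path is accessible when fitness increases at every step (strictly, by
#' default: each successive genotype has higher fitness than the one before
#' it). In non-strict mode equal-fitness steps are allowed. When a path is
#' blocked, the earliest violating step is reported: step `i` is the move
#' from the `i`-th to the `(i+1)`-th genotype of the path (1-based), so a
#' fitness sequence `(1, 2, 2, 9)` blocks at step 2 in strict mode.
#'
#' @param path a path as produced by [enumerate_direct_paths()] (a list
#'   with `genotypes`), or a plain character vector of genotypes.
#' @param table a `fitness_table` covering all path genotypes.
#' @param strict require strictly increasing fitness (default `TRUE`).
#' @return list with `accessible` (logical) and `first_blocked_step`
#'   (integer, `NA` when accessible).
#' @examples
#' tab <- fitness_table(c(A = 1, B = 2, C = 5))
#' is_accessible(c("A", "B", "C"), tab)$accessible  # TRUE
#' @export
is_accessible <- function(path, table, strict = TRUE) {
  genotypes <- if (is.list(path)) path$genotypes else path
  f <- fitness_of(table, genotypes)
  steps <- diff(f)
  blocked <- if (strict) steps <= 0 else steps < 0
  if (any(blocked)) {
    list(accessible = FALSE, first_blocked_step = which(blocked)[1])
  } else {
    list(accessible = TRUE, first_blocked_step = NA_integer_)
  }
}

#' Accessibility report over all direct paths
#'
#' Evaluates every direct path of a biallelic landscape (all `d!` orderings
#' of the differing sites) against one environment's fitness table.
#'
#' @param spec a biallelic `landscape_spec`.
#' @param table a `fitness_table` covering the hypercube.
#' @param strict require strictly increasing fitness (default `TRUE`).
#' @return an `accessibility_report`: list with `environment`, `paths`
#'   (data.frame: `path_id`, `site_order`, `accessible`,
#'   `first_blocked_step`), `n_paths`, `n_accessible` and
#'   `fraction_accessible`.
#' @export
count_accessible <- function(spec, table, strict = TRUE) {
  paths <- enumerate_direct_paths(spec)
  verdicts <- lapply(paths, is_accessible, table = table, strict = strict)
  df <- data.frame(
    path_id = seq_along(paths),
    site_order = vapply(paths, function(p) {
      paste(p$step_sites, collapse = ">")
    }, character(1)),
    accessible = vapply(verdicts, `[[`, logical(1), "accessible"),
    first_blocked_step = vapply(verdicts, `[[`, integer(1),
                                "first_blocked_step"),
    stringsAsFactors = FALSE)
  n_acc <- sum(df$accessible)
  structure(
    list(environment = table$environment,
         paths = df,
         n_paths = nrow(df),
         n_accessible = n_acc,
         fraction_accessible = n_acc / nrow(df)),
    class = "accessibility_report")
}

#' @export
print.accessibility_report <- function(x, ...) {
  cat("Accessibility report (environment ", x$environment, "): ",
      x$n_accessible, " / ", x$n_paths, " direct paths accessible (",
      format(100 * x$fraction_accessible, digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' Find fitness peaks of a landscape
#'
#' A peak (local optimum) is a genotype with no strictly fitter one-mutant
#' neighbor. In non-strict mode, peaks that have an equal-fitness neighbor
#' are additionally flagged as plateau members rather than silently merged.
#'
#' @param spec a biallelic `landscape_spec`.
#' @param table a `fitness_table` covering the hypercube.
#' @param strict retained for interface symmetry; the peak definition is
#'   always "no strictly fitter neighbor". With `strict = FALSE` the
#'   `plateau` field distinguishes peaks tied with a neighbor.
#' @param basins if `TRUE`, also map every genotype to the peak reached by
#'   a lexicographic greedy walk started there.
#' @return a `peak_set`: list with `environment`, `peaks` (character),
#'   `plateau` (character subset of peaks with an equal-fitness neighbor)
#'   and optionally `basins` (named character vector genotype -> peak).
#' @export
find_peaks <- function(spec, table, strict = TRUE, basins = FALSE) {
  genotypes <- build_hypercube(spec)
  fit <- fitness_of(table, genotypes)
  names(fit) <- genotypes
  is_peak <- vapply(genotypes, function(g) {
    nb <- one_mutant_neighbors(g, spec)
    length(nb) == 0 || all(fit[nb] <= fit[[g]])
  }, logical(1))
  plateau <- vapply(genotypes, function(g) {
    nb <- one_mutant_neighbors(g, spec)
    length(nb) > 0 && any(fit[nb] == fit[[g]])
  }, logical(1))
  res <- list(environment = table$environment,
              peaks = genotypes[is_peak],
              plateau = genotypes[is_peak & plateau])
  if (basins) {
    res$basins <- vapply(genotypes, function(g) {
      w <- greedy_walk(g, spec, table)
      w$genotypes[length(w$genotypes)]
    }, character(1))
  }
  structure(res, class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("Peaks (environment ", x$environment, "): ",
      paste(x$peaks, collapse = ", "), "\n", sep = "")
  if (length(x$plateau)) {
    cat("  (on plateaus: ", paste(x$plateau, collapse = ", "), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Greedy adaptive walk
#'
#' From `start`, repeatedly move to the strictly fittest one-mutant
#' neighbor until no neighbor is fitter; the endpoint is always a peak.
#' Ties among equally fittest neighbors are broken lexicographically
#' (default, reproducible) or uniformly at random.
#'
#' @param start starting genotype.
#' @param spec a biallelic `landscape_spec`.
#' @param table a `fitness_table` covering the hypercube.
#' @param tie_rule `"lexicographic"` or `"random"`.
#' @param seed RNG seed used only when `tie_rule = "random"`.
#' @return a path: list with `genotypes` and `step_sites`.
#' @export
greedy_walk <- function(start, spec, table,
                        tie_rule = c("lexicographic", "random"),
                        seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  if (tie_rule == "random") set.seed(seed)
  cur <- toupper(start)
  fitness_of(table, cur)  # membership check
  genotypes <- cur
  step_sites <- integer(0)
  max_steps <- 2 ^ length(spec$differing_sites)
  for (step in seq_len(max_steps)) {
    nb <- one_mutant_neighbors(cur, spec)
    if (length(nb) == 0) break
    fnb <- fitness_of(table, nb)
    fcur <- fitness_of(table, cur)
    if (max(fnb) <= fcur) break
    best <- nb[fnb == max(fnb)]
    nxt <- if (tie_rule == "lexicographic" || length(best) == 1L) {
      sort_c(best)[1]
    } else {
      best[sample.int(length(best), 1L)]
    }
    step_sites <- c(step_sites,
                    which(split_symbols(cur) != split_symbols(nxt)))
    genotypes <- c(genotypes, nxt)
    cur <- nxt
  }
  list(genotypes = genotypes, step_sites = step_sites)
}

#' Ruggedness summary of one landscape-environment pair
#'
#' Composes [find_peaks()] and [count_accessible()]: a smooth (additive)
#' landscape has a single peak and every direct path accessible, i.e.
#' `(1, 1.0)`; ruggedness shows up as extra peaks and blocked paths.
#'
#' @inheritParams count_accessible
#' @return list with `environment`, `n_peaks`, `peaks`, `n_paths`,
#'   `n_accessible` and `fraction_accessible`.
#' @export
ruggedness_summary <- function(spec, table, strict = TRUE) {
  pk <- find_peaks(spec, table, strict = strict)
  acc <- count_accessible(spec, table, strict = strict)
  list(environment = table$environment,
       n_peaks = length(pk$peaks),
       peaks = pk$peaks,
       n_paths = acc$n_paths,
       n_accessible = acc$n_accessible,
       fraction_accessible = acc$fraction_accessible)
}

#' Write an accessibility report to CSV / JSON
#'
#' @param report an `accessibility_report`.
#' @param csv_file,json_file output paths; `NULL` skips.
#' @return the report, invisibly.
#' @export
write_accessibility_report <- function(report, csv_file = NULL,
                                       json_file = NULL) {
  stopifnot(inherits(report, "accessibility_report"))
  if (!is.null(csv_file)) {
    utils::write.csv(report$paths, csv_file, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_file)) {
    jsonlite::write_json(
      list(environment = report$environment,
           n_paths = report$n_paths,
           n_accessible = report$n_accessible,
           fraction_accessible = report$fraction_accessible),
      json_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
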