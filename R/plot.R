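#' Render a trajectory figure for a landscape
#'
#' Draws the hypercube as a layered node-and-arrow diagram (layers =
#' Hamming distance from the source, as in the classic word-landscape
#' trajectory figures), with the strictly uphill steps of the focal
#' environment highlighted, alongside a log-scale panel of every
#' genotype's fitness across environments. Figures are structural
#' summaries, not publication graphics.
#'
#' @param spec a biallelic `landscape_spec`.
#' @param series an `environment_series` covering the hypercube.
#' @param out output file (`.png` or `.pdf`).
#' @param env focal environment for the uphill-step highlighting; default
#'   the first in the series.
#' @param pseudo_frac zero fitness cannot be drawn on a log axis; zeros are
#'   replaced by `pseudo_frac` times the smallest positive value and the
#'   panel is annotated (default `1e-2`).
#' @param width,height device size in pixels (png) or inches (pdf).
#' @return invisibly, a list with `file`, `n_nodes`, `n_edges`,
#'   `n_uphill_edges`.
#' @export
render_trajectory_figure <- function(spec, series, out, env = NULL,
                                     pseudo_frac = 1e-2,
                                     width = 1400, height = 700) {
  stopifnot(inherits(spec, "landscape_spec"),
            inherits(series, "environment_series"))
  if (length(series$environments) == 0) stop("empty environment series")
  if (is.null(env)) env <- series$environments[1]
  if (!env %in% series$environments) {
    stop("environment '", env, "' not in the series")
  }
  genotypes <- build_hypercube(spec)
  if (length(genotypes) == 0) stop("empty landscape")
  src <- split_symbols(spec$source)
  layer <- vapply(genotypes, function(g) {
    sum(split_symbols(g) != src)
  }, numeric(1))
  # vertical spread within each layer
  ypos <- stats::ave(seq_along(genotypes), layer, FUN = function(i) {
    seq_along(i) - (length(i) + 1) / 2
  })
  xpos <- layer
  names(xpos) <- names(ypos) <- genotypes
  edges <- list()
  for (g in genotypes) {
    for (nb in one_mutant_neighbors(g, spec)) {
      if (g < nb) edges[[length(edges) + 1L]] <- c(g, nb)
    }
  }
  fit <- fitness_of(series$tables[[env]], genotypes)
  names(fit) <- genotypes
  # a forward step (toward the target layer) is highlighted when it is
  # strictly uphill in fitness — the steps an accessible trajectory can use
  uphill <- vapply(edges, function(e) {
    fwd <- if (xpos[e[1]] < xpos[e[2]]) e else rev(e)
    fit[fwd[2]] > fit[fwd[1]]
  }, logical(1))

  ext <- tolower(tools::file_ext(out))
  if (ext == "pdf") {
    grDevices::pdf(out, width = max(width, 14) / 100 * 1,
                   height = max(height, 7) / 100 * 1)
  } else {
    grDevices::png(out, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  multi_env <- length(series$environments) > 1
  graphics::par(mfrow = c(1, if (multi_env) 2 else 1),
                mar = c(4, 4, 3, 1))

  graphics::plot(xpos, ypos, type = "n", axes = FALSE,
                 xlab = "substitutions from source", ylab = "",
                 main = paste0(spec$source, " -> ", spec$target,
                               " (environment ", env, ")"))
  graphics::axis(1, at = sort(unique(layer)))
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    # orient the arrow uphill
    a <- if (fit[e[1]] <= fit[e[2]]) e else rev(e)
    graphics::arrows(xpos[a[1]], ypos[a[1]], xpos[a[2]], ypos[a[2]],
                     length = 0.08,
                     col = if (uphill[k]) "firebrick" else "grey70",
                     lwd = if (uphill[k]) 2 else 1)
  }
  graphics::points(xpos, ypos, pch = 21, cex = 3.2, bg = "white")
  graphics::text(xpos, ypos, genotypes, cex = 0.55)

  if (multi_env) {
    fmat <- vapply(series$environments, function(e) {
      fitness_of(series$tables[[e]], genotypes)
    }, numeric(length(genotypes)))
    annotated <- FALSE
    if (any(fmat == 0)) {
      pos <- fmat[fmat > 0]
      floor_val <- if (length(pos)) min(pos) * pseudo_frac else pseudo_frac
      fmat[fmat == 0] <- floor_val
      annotated <- TRUE
    }
    graphics::matplot(t(log10(fmat)), type = "b", pch = 16, lty = 1,
                      axes = FALSE, xlab = "environment",
                      ylab = "log10 fitness",
                      main = "fitness across environments")
    graphics::axis(1, at = seq_along(series$environments),
                   labels = series$environments)
    graphics::axis(2)
    if (annotated) {
      graphics::mtext("zeros drawn at pseudocount floor", side = 3,
                      cex = 0.7)
    }
  }
  invisible(list(file = out, n_nodes = length(genotypes),
                 n_edges = length(edges),
                 n_uphill_edges = sum(uphill)))
}
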