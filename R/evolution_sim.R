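#' Wright-Fisher simulation configuration
#'
#' Parameters for a haploid, asexual, non-overlapping-generations
#' Wright-Fisher simulation on a landscape: fitness-proportional selection,
#' then per-site mutation, then multinomial resampling of `N` individuals.
#'
#' @param N population size (individuals).
#' @param mu per-site, per-generation mutation probability in \[0, 1\].
#' @param generations number of generations to simulate.
#' @param init named numeric vector of initial genotype counts summing to
#'   `N`, or a single genotype string meaning "all `N` individuals carry
#'   this genotype".
#' @param seed integer RNG seed; identical (config, table) pairs give
#'   identical trajectories.
#' @param environment environment label recorded in the result.
#' @param fixation_threshold frequency at which a genotype is recorded as
#'   fixed (default 0.99).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(N, mu, generations, init, seed = 1L,
                       environment = NULL, fixation_threshold = 0.99) {
  if (!is.numeric(N) || N < 1) stop("N must be a positive integer")
  if (!is.numeric(mu) || mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (!is.numeric(generations) || generations < 1) {
    stop("generations must be a positive integer")
  }
  if (is.character(init) && is.null(names(init)) && length(init) == 1L) {
    init <- stats::setNames(N, toupper(init))
  }
  if (is.null(names(init)) || any(init < 0)) {
    stop("init must be a named vector of non-negative genotype counts")
  }
  names(init) <- toupper(names(init))
  if (sum(init) != N) {
    stop("initial counts sum to ", sum(init), ", expected N = ", N)
  }
  if (fixation_threshold <= 0 || fixation_threshold > 1) {
    stop("fixation_threshold must lie in (0, 1]")
  }
  structure(list(N = as.integer(N), mu = mu,
                 generations = as.integer(generations),
                 init = init, seed = as.integer(seed),
                 environment = environment,
                 fixation_threshold = fixation_threshold),
            class = "sim_config")
}

# Per-generation genotype-to-genotype mutation matrix. Each individual
# mutates independently at each site with probability mu, switching to the
# alternative symbol (biallelic) or to a uniform choice among the
# alternatives (multi-allele sites). M[i, j] = P(offspring genotype j |
# parent genotype i); rows sum to 1.
mutation_matrix <- function(genotypes, spec, mu) {
  n <- length(genotypes)
  syms <- strsplit(genotypes, "", fixed = TRUE)
  nalt <- vapply(spec$site_alphabets, length, integer(1)) - 1L
  active <- which(nalt > 0L)
  M <- matrix(0, n, n, dimnames = list(genotypes, genotypes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      diffs <- which(syms[[i]] != syms[[j]])
      if (length(setdiff(diffs, active)) > 0) next  # unreachable
      p <- 1
      for (s in active) {
        p <- p * if (s %in% diffs) mu / nalt[s] else (1 - mu)
      }
      M[i, j] <- p
    }
  }
  M
}

#' Simulate Wright-Fisher evolution on a landscape
#'
#' Each generation applies, in order: (1) selection — the expected
#' offspring share of genotype g is proportional to `count(g) * fitness(g)`;
#' (2) mutation — every individual mutates at each site independently with
#' probability `mu`, switching to the alternative biallelic symbol; (3)
#' multinomial resampling of `N` individuals from the post-mutation
#' expected frequencies. All randomness comes from the seeded generator, so
#' identical inputs give bit-identical trajectories.
#'
#' @param config a [sim_config()].
#' @param spec a biallelic `landscape_spec`.
#' @param table a `fitness_table` covering the hypercube.
#' @param expectation if `TRUE`, run the deterministic infinite-population
#'   expectation recursion instead of sampling (exposes the exact selection
#'   plus mutation dynamics for testing and analysis).
#' @return a `sim_result`: list with `genotypes`, `trajectory` (matrix of
#'   frequencies, one row per genotype, columns = generations 0..G),
#'   `fixation_events` (data.frame `genotype`, `generation` of first
#'   reaching the fixation threshold), `max_frequency` (named vector), and
#'   the `config`.
#' @examples
#' spec <- landscape_spec("AB", "BA")
#' tab <- fitness_table(c(AB = 1, AA = 2, BB = 2, BA = 4))
#' cfg <- sim_config(N = 1000, mu = 1e-3, generations = 50, init = "AB",
#'                   seed = 7)
#' res <- wright_fisher(cfg, spec, tab)
#' res$max_frequency["BA"]
#' @export
wright_fisher <- function(config, spec, table, expectation = FALSE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(spec, "landscape_spec"))
  genotypes <- build_hypercube(spec)
  fit <- fitness_of(table, genotypes)
  names(fit) <- genotypes
  bad <- setdiff(names(config$init), genotypes)
  if (length(bad) > 0) {
    stop("initial genotype(s) outside the space: ", paste(bad, collapse = ", "))
  }
  counts <- stats::setNames(numeric(length(genotypes)), genotypes)
  counts[names(config$init)] <- config$init
  present <- counts > 0
  if (all(fit[present] == 0)) {
    stop("all genotypes present in the initial population have zero fitness")
  }
  M <- mutation_matrix(genotypes, spec, config$mu)
  G <- config$generations
  N <- config$N
  traj <- matrix(NA_real_, nrow = length(genotypes), ncol = G + 1L,
                 dimnames = list(genotypes, 0:G))
  traj[, 1] <- counts / N
  set.seed(config$seed)
  p <- counts / N
  for (gen in seq_len(G)) {
    w <- p * fit
    sw <- sum(w)
    if (sw == 0) {
      stop("population reached an all-zero-fitness state at generation ", gen)
    }
    p_sel <- w / sw
    q <- as.vector(p_sel %*% M)          # post-mutation expected frequencies
    q <- pmax(q, 0)
    q <- q / sum(q)
    p <- if (expectation) q else as.vector(stats::rmultinom(1, N, q)) / N
    traj[, gen + 1L] <- p
    # without mutation a monomorphic population is absorbing; freeze it
    if (config$mu == 0 && any(p == 1) && gen < G) {
      traj[, (gen + 2L):(G + 1L)] <- p
      break
    }
  }
  max_freq <- apply(traj, 1, max)
  thr <- config$fixation_threshold
  fixed <- which(max_freq >= thr)
  fixation_events <- data.frame(
    genotype = character(0), generation = integer(0),
    stringsAsFactors = FALSE)
  if (length(fixed) > 0) {
    fixation_events <- data.frame(
      genotype = genotypes[fixed],
      generation = vapply(fixed, function(i) {
        as.integer(which(traj[i, ] >= thr)[1] - 1L)
      }, integer(1)),
      stringsAsFactors = FALSE)
    fixation_events <- fixation_events[order(fixation_events$generation), ]
    rownames(fixation_events) <- NULL
  }
  structure(list(genotypes = genotypes,
                 trajectory = traj,
                 fixation_events = fixation_events,
                 max_frequency = max_freq,
                 config = config,
                 environment = table$environment),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Wright-Fisher result: N = ", x$config$N, ", mu = ", x$config$mu,
      ", ", x$config$generations, " generations, environment ",
      x$environment, "\n", sep = "")
  final <- x$trajectory[, ncol(x$trajectory)]
  top <- sort(final[final > 0], decreasing = TRUE)
  cat("Final composition:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  if (nrow(x$fixation_events)) {
    cat("Fixation events:",
        paste(sprintf("%s@g%d", x$fixation_events$genotype,
                      x$fixation_events$generation), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Detect stochastic tunneling in a simulation result
#'
#' Tunneling: the final genotype reaches the fixation threshold while the
#' intermediate stepping-stone never rises above a low frequency cap — the
#' intermediate is not skipped, but only ever appears at low frequency long
#' enough to seed the fitter double mutant.
#'
#' @param result a `sim_result`.
#' @param intermediate,final genotype strings present in the result.
#' @param intermediate_cap maximum frequency the intermediate may attain
#'   (default 0.05).
#' @param fixation_threshold frequency the final genotype must reach
#'   (default 0.99).
#' @return logical.
#' @export
detect_tunneling <- function(result, intermediate, final,
                             intermediate_cap = 0.05,
                             fixation_threshold = 0.99) {
  stopifnot(inherits(result, "sim_result"))
  if (intermediate_cap <= 0 || fixation_threshold >= 1 + 1e-12 ||
      intermediate_cap >= fixation_threshold) {
    stop("need 0 < intermediate_cap < fixation_threshold <= 1")
  }
  intermediate <- toupper(intermediate)
  final <- toupper(final)
  missing <- setdiff(c(intermediate, final), result$genotypes)
  if (length(missing) > 0) {
    stop("genotype(s) absent from result: ", paste(missing, collapse = ", "))
  }
  final_fixed <- result$max_frequency[[final]] >= fixation_threshold
  intermediate_low <- result$max_frequency[[intermediate]] < intermediate_cap
  final_fixed && intermediate_low
}

#' Estimate fixation probabilities by replicate simulation
#'
#' Runs `replicates` seeded Wright-Fisher simulations and reports, for each
#' genotype, the fraction of replicates in which it reached the fixation
#' threshold, with the binomial standard error `sqrt(p (1 - p) / r)`.
#' Replicate `i` uses seed `config$seed + i`.
#'
#' @inheritParams wright_fisher
#' @param replicates number of replicate simulations (>= 1).
#' @return data.frame with columns `genotype`, `p_fix`, `se`.
#' @export
fixation_probability_estimate <- function(config, spec, table, replicates) {
  if (!is.numeric(replicates) || replicates < 1) {
    stop("replicates must be >= 1")
  }
  replicates <- as.integer(replicates)
  genotypes <- build_hypercube(spec)
  fixed_counts <- stats::setNames(integer(length(genotypes)), genotypes)
  for (i in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + i
    res <- wright_fisher(cfg, spec, table)
    if (nrow(res$fixation_events) > 0) {
      # first genotype to reach the threshold counts as the fixation event
      g <- res$fixation_events$genotype[1]
      fixed_counts[g] <- fixed_counts[g] + 1L
    }
  }
  p <- fixed_counts / replicates
  data.frame(genotype = genotypes,
             p_fix = unname(p),
             se = unname(sqrt(p * (1 - p) / replicates)),
             stringsAsFactors = FALSE)
}

#' Write a simulation trajectory as tidy CSV
#'
#' One row per (generation, genotype) with the genotype's frequency.
#'
#' @param result a `sim_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  traj <- result$trajectory
  df <- data.frame(
    generation = rep(as.integer(colnames(traj)), each = nrow(traj)),
    genotype = rep(rownames(traj), times = ncol(traj)),
    frequency = as.vector(traj),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
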