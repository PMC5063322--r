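# small helper: fitness table from a named vector
ftab <- function(...) fitness_table(c(...), environment = "t")

test_that("is_accessible requires monotone fitness along the path", {
  tab <- ftab(A = 1, B = 2, C = 5, D = 9, E = 10)
  path <- c("A", "B", "C", "D", "E")
  expect_true(is_accessible(path, tab)$accessible)

  tie <- ftab(A = 1, B = 2, C = 2, D = 9, E = 10)
  v <- is_accessible(path, tie)
  expect_false(v$accessible)
  expect_equal(v$first_blocked_step, 2)
  expect_true(is_accessible(path, tie, strict = FALSE)$accessible)

  down <- ftab(A = 5, B = 2, C = 3, D = 9, E = 10)
  expect_equal(is_accessible(path, down)$first_blocked_step, 1)
  expect_error(is_accessible(c("A", "Z"), tab), "missing")
})

test_that("the 1800-ordering GENE->BIRD path is an accessible trajectory", {
  fx <- make_landscape_fixture("GENE", "BIRD", "env_flip")
  path <- c("GENE", "BENE", "BEND", "BIND", "BIRD")
  v <- is_accessible(path, fx$tables[["1800"]])
  expect_true(v$accessible)
  expect_true(is.na(v$first_blocked_step))
})

test_that("count_accessible matches per-path verdicts and the archetypes", {
  spec <- landscape_spec("WORD", "GENE")
  add <- make_landscape_fixture("WORD", "GENE", "additive")$tables[[1]]
  rep_add <- count_accessible(spec, add)
  expect_equal(rep_add$n_paths, 24)
  expect_equal(rep_add$n_accessible, 24)
  expect_equal(rep_add$fraction_accessible, 1)
  expect_true(all(rep_add$paths$accessible))

  trapped <- make_landscape_fixture("WORD", "GENE",
                                    "source_trapped")$tables[[1]]
  rep_tr <- count_accessible(spec, trapped)
  expect_equal(rep_tr$n_accessible, 0)
  expect_true(all(rep_tr$paths$first_blocked_step == 1))

  # WORD out-ranks WORE in the trapping fixture: no direct path leaves WORD
  dom <- make_landscape_fixture("WORD", "GENE", "dominant_interior_peak",
                                peak = "WERE")$tables[[1]]
  expect_gt(dom$values[["WORD"]], dom$values[["WORE"]])
  expect_equal(count_accessible(spec, dom)$n_accessible, 0)
})

test_that("count_accessible equals the brute-force oracle on random landscapes", {
  for (seed in 1:25) {
    d <- sample(2:6, 1)
    lc <- random_landscape(d, seed = 2000 + seed)
    spec <- landscape_spec(lc$source, lc$target)
    tab <- fitness_table(lc$fitness, "r")
    got <- count_accessible(spec, tab)$n_accessible
    expect_equal(got, oracle_count_accessible(lc$source, lc$target,
                                              lc$fitness))
  }
})

test_that("find_peaks matches exhaustive neighbor comparison", {
  spec <- landscape_spec("WORD", "GENE")
  dom <- make_landscape_fixture("WORD", "GENE", "dominant_interior_peak",
                                peak = "WERE")$tables[[1]]
  pk <- find_peaks(spec, dom)
  expect_true("WERE" %in% pk$peaks)
  expect_setequal(pk$peaks, oracle_peaks("WORD", "GENE", dom$values))
  # WERE is the global maximum by construction
  expect_equal(names(which.max(dom$values)), "WERE")

  add <- make_landscape_fixture("WORD", "GENE", "additive")$tables[[1]]
  expect_identical(find_peaks(spec, add)$peaks, "GENE")

  flat <- fitness_table(setNames(rep(1, 16), build_hypercube(spec)), "f")
  pf <- find_peaks(spec, flat)
  expect_length(pf$peaks, 16)          # no strictly fitter neighbor anywhere
  expect_length(pf$plateau, 16)        # but every peak sits on a plateau

  for (seed in 1:10) {
    lc <- random_landscape(sample(2:5, 1), seed = 3000 + seed)
    got <- find_peaks(landscape_spec(lc$source, lc$target),
                      fitness_table(lc$fitness, "r"))$peaks
    expect_setequal(got, oracle_peaks(lc$source, lc$target, lc$fitness))
  }
})

test_that("greedy walks climb to a peak and break ties reproducibly", {
  spec <- landscape_spec("WORD", "GENE")
  add <- make_landscape_fixture("WORD", "GENE", "additive")$tables[[1]]
  w <- greedy_walk("WORD", spec, add)
  expect_length(w$genotypes, 5)
  expect_identical(w$genotypes[5], "GENE")

  # starting on a peak yields a single-genotype path
  expect_identical(greedy_walk("GENE", spec, add)$genotypes, "GENE")

  # lexicographic tie-break: two equally fittest neighbors
  spec2 <- landscape_spec("AA", "BB")
  tab2 <- fitness_table(c(AA = 1, AB = 2, BA = 2, BB = 3), "t")
  w2 <- greedy_walk("AA", spec2, tab2)
  expect_identical(w2$genotypes, c("AA", "AB", "BB"))

  # every greedy endpoint is a peak; walks terminate within 2^d steps
  for (seed in 1:10) {
    lc <- random_landscape(sample(2:5, 1), seed = 4000 + seed)
    sp <- landscape_spec(lc$source, lc$target)
    tab <- fitness_table(lc$fitness, "r")
    peaks <- find_peaks(sp, tab)$peaks
    for (g in sample(names(lc$fitness), 4)) {
      w <- greedy_walk(g, sp, tab)
      expect_lte(length(w$genotypes), 2^length(sp$differing_sites))
      expect_true(w$genotypes[length(w$genotypes)] %in% peaks)
    }
  }
})

test_that("verdicts are invariant under monotone fitness transformations", {
  for (seed in 1:5) {
    lc <- random_landscape(4, seed = 5000 + seed)
    spec <- landscape_spec(lc$source, lc$target)
    raw <- fitness_table(lc$fitness, "r")
    logged <- fitness_table(log(lc$fitness) + 10, "r")  # strictly increasing
    expect_identical(count_accessible(spec, raw)$paths$accessible,
                     count_accessible(spec, logged)$paths$accessible)
    expect_identical(find_peaks(spec, raw)$peaks,
                     find_peaks(spec, logged)$peaks)
    expect_identical(greedy_walk(lc$source, spec, raw)$genotypes,
                     greedy_walk(lc$source, spec, logged)$genotypes)
  }
})

test_that("ruggedness_summary composes peaks and accessibility", {
  spec <- landscape_spec("WORD", "GENE")
  add <- make_landscape_fixture("WORD", "GENE", "additive")$tables[[1]]
  rs <- ruggedness_summary(spec, add)
  expect_equal(rs$n_peaks, 1)
  expect_equal(rs$fraction_accessible, 1)

  flat <- fitness_table(setNames(rep(1, 16), build_hypercube(spec)), "f")
  rf <- ruggedness_summary(spec, flat)
  expect_equal(rf$n_peaks, 16)
  expect_equal(rf$fraction_accessible, 0)

  dom <- make_landscape_fixture("WORD", "GENE", "dominant_interior_peak",
                                peak = "WERE")$tables[[1]]
  rd <- ruggedness_summary(spec, dom)
  expect_gte(rd$n_peaks, 1)
  expect_equal(rd$fraction_accessible, 0)
})

test_that("accessibility reports serialize to CSV and JSON", {
  spec <- landscape_spec("WORD", "GENE")
  add <- make_landscape_fixture("WORD", "GENE", "additive")$tables[[1]]
  rep <- count_accessible(spec, add)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_accessibility_report(rep, csv, js)
  df <- read.csv(csv)
  expect_equal(nrow(df), 24)
  expect_true(all(df$accessible))
  j <- jsonlite::read_json(js)
  expect_equal(j$n_accessible, 24)
  expect_equal(j$fraction_accessible, 1)
})
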