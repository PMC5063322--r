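write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("ngram_frequency is the per-year count over corpus-total ratio", {
  records <- data.frame(ngram = c("word", "Gene", "gene"),
                        year = c(1950L, 1950L, 1950L),
                        match_count = c(50L, 30L, 70L),
                        volume_count = c(5L, 3L, 7L))
  totals <- c("1950" = 1e6)
  expect_equal(ngram_frequency("word", 1950, records, totals), 5e-5)
  expect_equal(ngram_frequency("gene", 1950, records, totals), 1e-4)
  expect_equal(ngram_frequency("absent", 1950, records, totals), 0)
  # case-insensitive in both query and records
  expect_equal(ngram_frequency("GENE", 1950, records, totals), 1e-4)
  expect_equal(ngram_frequency("gene", 1950, records, totals,
                               case_sensitive = TRUE), 7e-5)
  expect_error(ngram_frequency("word", 1800, records, totals), "1800")
})

test_that("read_ngram_file parses the export dialect and flags bad lines", {
  f <- write_tmp(c("gene\t1950\t12345\t678",
                   "word\t1950\t50\t5",
                   "bird\t1800\t99\t9"))
  rec <- read_ngram_file(f)
  expect_equal(nrow(rec), 3)
  expect_identical(rec$ngram[1], "gene")
  expect_identical(rec$year[1], 1950L)
  expect_identical(rec$match_count[1], 12345L)
  expect_identical(rec$volume_count[1], 678L)

  bad <- write_tmp("gene\tnineteen50\t12\t3")
  expect_error(read_ngram_file(bad), "line 1")
  short <- write_tmp(c("gene\t1950\t12\t3", "word\t1950\t5"))
  expect_error(read_ngram_file(short), "line 2")
  empty <- write_tmp(character(0))
  expect_warning(rec0 <- read_ngram_file(empty), "empty")
  expect_equal(nrow(rec0), 0)
})

test_that("read_totals_file handles both dialects and rejects duplicates", {
  tc <- write_tmp("1950,100,5,2 1951,200,6,3")
  expect_equal(read_totals_file(tc), c("1950" = 100, "1951" = 200))
  csv2 <- write_tmp(c("1800,500", "1900,600"))
  expect_equal(read_totals_file(csv2), c("1800" = 500, "1900" = 600))
  dup <- write_tmp("1950,100,5,2 1950,300,6,3")
  expect_error(read_totals_file(dup), "duplicate")
  zero <- write_tmp("1950,0,5,2")
  expect_error(read_totals_file(zero), "positive")
})

test_that("build_environment_series covers every word in every year", {
  words <- build_hypercube("WORD", "GENE")
  records <- data.frame(ngram = c("word", "gene", "were"),
                        year = rep(c(1800L, 1900L, 2000L), each = 3),
                        match_count = rep(c(10L, 20L, 5000L), 3),
                        volume_count = 1L)
  totals <- c("1800" = 1e6, "1900" = 2e6, "2000" = 4e6)
  series <- build_environment_series(words, c(1800, 1900, 2000),
                                     records, totals)
  expect_s3_class(series, "environment_series")
  expect_length(series$environments, 3)
  for (tab in series$tables) expect_length(tab$values, 16)
  expect_equal(series$tables[["1800"]]$values[["WORD"]], 1e-5)
  # absent words: zero by default, epsilon/total under pseudocount
  expect_equal(series$tables[["1800"]]$values[["GORE"]], 0)
  series_pc <- build_environment_series(words, 1800, records, totals,
                                        fill_policy = "pseudocount",
                                        pseudocount = 1)
  expect_equal(series_pc$tables[["1800"]]$values[["GORE"]], 1e-6)
})

test_that("word-set frequencies are proper frequencies", {
  words <- c("WORD", "GENE", "WERE")
  records <- data.frame(ngram = c("word", "gene", "were"),
                        year = 1900L,
                        match_count = c(100L, 300L, 40000L),
                        volume_count = 1L)
  totals <- c("1900" = 1e5)
  series <- build_environment_series(words, 1900, records, totals)
  vals <- series$tables[[1]]$values
  expect_true(all(vals >= 0 & vals <= 1))
  expect_lte(sum(vals), 1)
})

test_that("fitness CSV round-trips exactly and rejects bad rows", {
  fx <- make_landscape_fixture("WORD", "GENE", "dominant_interior_peak",
                               peak = "WERE",
                               environments = c("1800", "1900"))
  f <- tempfile(fileext = ".csv")
  write_fitness_csv(fx, f)
  back <- read_fitness_csv(f)
  expect_identical(back$environments, fx$environments)
  for (e in fx$environments) {
    g <- sort(names(fx$tables[[e]]$values), method = "radix")
    expect_identical(back$tables[[e]]$values[g], fx$tables[[e]]$values[g])
  }
  # a second write of the parsed series is byte-identical
  f2 <- tempfile(fileext = ".csv")
  write_fitness_csv(back, f2)
  expect_identical(readLines(f), readLines(f2))

  neg <- write_tmp(c("genotype,environment,fitness", "WORD,1900,-1"),
                   ext = ".csv")
  expect_error(read_fitness_csv(neg), "negative")
  dup <- write_tmp(c("genotype,environment,fitness",
                     "WORD,1900,0.5", "WORD,1900,0.7"), ext = ".csv")
  expect_error(read_fitness_csv(dup), "duplicate")
  badhdr <- write_tmp(c("word,env,fit", "WORD,1900,0.5"), ext = ".csv")
  expect_error(read_fitness_csv(badhdr), "header")
})

test_that("fitness tables validate their invariants", {
  expect_error(fitness_table(c(A = -1)), "non-negative")
  expect_error(fitness_table(c(1, 2)), "named")
  expect_error(fitness_table(c(A = 1, A = 2)), "duplicate")
  expect_error(environment_series(list(
    fitness_table(c(A = 1), "1800"),
    fitness_table(c(B = 1), "1900"))), "same genotype set")
  expect_error(environment_series(list(
    fitness_table(c(A = 1), "1800"),
    fitness_table(c(A = 2), "1800"))), "duplicate environment")
})
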