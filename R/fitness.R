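#' Per-environment fitness table
#'
#' A `fitness_table` maps genotype strings to non-negative fitness values
#' within one environment (for word landscapes, an environment is a year of
#' the book corpus and the fitness is a word-usage frequency, but any
#' non-negative proxy is accepted). Fitness is treated as relative
#' throughout the package: only ratios and orderings matter downstream, and
#' no normalization is imposed at storage time.
#'
#' @param values named numeric vector (names are genotype strings).
#' @param environment environment label (year or free string).
#' @return object of class `fitness_table` with fields `environment` and
#'   `values` (genotype names uppercased).
#' @export
fitness_table <- function(values, environment = "1") {
  if (length(values) > 0 &&
      (is.null(names(values)) || any(!nzchar(names(values))))) {
    stop("fitness values must be named by genotype")
  }
  if (length(values) == 0) values <- stats::setNames(numeric(0), character(0))
  if (any(is.na(values)) || any(values < 0)) {
    stop("fitness values must be non-negative and non-missing")
  }
  names(values) <- toupper(names(values))
  if (anyDuplicated(names(values))) {
    stop("duplicate genotype in fitness table: ",
         names(values)[duplicated(names(values))][1])
  }
  structure(list(environment = as.character(environment),
                 values = values),
            class = "fitness_table")
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("Fitness table, environment ", x$environment, ": ",
      length(x$values), " genotypes\n", sep = "")
  print(utils::head(sort(x$values, decreasing = TRUE), 5))
  invisible(x)
}

# fitness lookup with a hard error on missing genotypes
fitness_of <- function(table, genotypes) {
  stopifnot(inherits(table, "fitness_table"))
  genotypes <- toupper(genotypes)
  missing <- setdiff(genotypes, names(table$values))
  if (length(missing) > 0) {
    stop("genotype(s) missing from fitness table (environment ",
         table$environment, "): ", paste(missing, collapse = ", "))
  }
  unname(table$values[genotypes])
}

#' Ordered series of fitness tables across environments
#'
#' @param tables list of `fitness_table`, one per environment; labels must
#'   be unique and every table must cover the same genotype set.
#' @return object of class `environment_series` with fields `environments`
#'   (character vector of labels, in order) and `tables` (named list).
#' @export
environment_series <- function(tables) {
  if (length(tables) == 0) stop("need at least one fitness table")
  stopifnot(all(vapply(tables, inherits, logical(1), "fitness_table")))
  labels <- vapply(tables, function(t) t$environment, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate environment label: ", labels[duplicated(labels)][1])
  }
  genos <- sort_c(names(tables[[1]]$values))
  for (t in tables[-1]) {
    if (!identical(sort_c(names(t$values)), genos)) {
      stop("environment ", t$environment,
           " does not cover the same genotype set as ", labels[1])
    }
  }
  names(tables) <- labels
  structure(list(environments = labels, tables = tables),
            class = "environment_series")
}

#' @export
print.environment_series <- function(x, ...) {
  cat("Environment series: ", length(x$environments), " environments (",
      paste(utils::head(x$environments, 5), collapse = ", "),
      if (length(x$environments) > 5) ", ..." else "", "), ",
      length(x$tables[[1]]$values), " genotypes each\n", sep = "")
  invisible(x)
}

# ---- Google Books ngram-export plumbing -----------------------------------

#' Read a Google Books 1-gram export file
#'
#' The export dialect is tab-separated with one record per line:
#' `ngram TAB year TAB match_count TAB volume_count`.
#'
#' @param path file path.
#' @return data.frame with columns `ngram` (character), `year`,
#'   `match_count`, `volume_count` (integer). An empty file yields an empty
#'   data.frame with a warning.
#' @export
read_ngram_file <- function(path) {
  if (!file.exists(path)) stop("ngram file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("ngram file is empty: ", path)
    return(data.frame(ngram = character(0), year = integer(0),
                      match_count = integer(0), volume_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 4L) {
      stop("malformed ngram record at line ", i, " of ", path,
           ": expected 4 tab-separated fields, got ", length(p))
    }
    nums <- suppressWarnings(as.integer(p[2:4]))
    if (any(is.na(nums))) {
      stop("malformed ngram record at line ", i, " of ", path,
           ": year and counts must be integers (got '",
           paste(p[2:4], collapse = "', '"), "')")
    }
    if (any(nums[2:3] < 0)) {
      stop("negative count at line ", i, " of ", path)
    }
  }
  data.frame(
    ngram = vapply(parts, `[`, character(1), 1),
    year = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    match_count = vapply(parts, function(p) as.integer(p[3]), integer(1)),
    volume_count = vapply(parts, function(p) as.integer(p[4]), integer(1)),
    stringsAsFactors = FALSE)
}

#' Read a corpus totals file
#'
#' Accepts either the Google totalcounts dialect — whitespace-separated
#' groups of `year,match_count,page_count,volume_count` — or a two-column
#' CSV `year,total` (no header).
#'
#' @param path file path.
#' @return named numeric vector mapping year to total word count.
#' @export
read_totals_file <- function(path) {
  if (!file.exists(path)) stop("totals file not found: ", path)
  raw <- paste(readLines(path, warn = FALSE), collapse = " ")
  groups <- strsplit(trimws(raw), "[ \t]+")[[1]]
  groups <- groups[nzchar(groups)]
  if (length(groups) == 0) stop("totals file is empty: ", path)
  fields <- strsplit(groups, ",", fixed = TRUE)
  nfield <- unique(lengths(fields))
  if (!identical(nfield, 4L) && !identical(nfield, 2L)) {
    stop("unrecognized totals format in ", path,
         ": expected 4-field totalcounts groups or 2-column CSV rows")
  }
  years <- vapply(fields, function(f) suppressWarnings(as.integer(f[1])),
                  integer(1))
  totals <- vapply(fields, function(f) suppressWarnings(as.numeric(f[2])),
                   numeric(1))
  if (any(is.na(years)) || any(is.na(totals))) {
    stop("non-numeric year or total in ", path)
  }
  if (anyDuplicated(years)) {
    stop("duplicate year in totals file: ", years[duplicated(years)][1])
  }
  if (any(totals <= 0)) {
    stop("corpus totals must be positive (year ",
         years[which(totals <= 0)[1]], ")")
  }
  stats::setNames(totals, as.character(years))
}

#' N-gram frequency of a word in a year
#'
#' The usage-frequency fitness proxy: the number of appearances of a word
#' in a year's corpus divided by the total number of words in that year's
#' corpus. Aggregation over case variants (`"Gene"`, `"gene"`, ...) is the
#' default; a word absent from the records scores 0.
#'
#' @param word the word (1-gram) to score.
#' @param year integer year.
#' @param records data.frame from [read_ngram_file()].
#' @param totals named vector from [read_totals_file()].
#' @param case_sensitive if `TRUE`, match the word's case exactly.
#' @return non-negative frequency (0 when the word is absent).
#' @export
ngram_frequency <- function(word, year, records, totals,
                            case_sensitive = FALSE) {
  ykey <- as.character(as.integer(year))
  if (!ykey %in% names(totals)) {
    stop("no corpus total for year ", ykey)
  }
  total <- totals[[ykey]]
  if (total <= 0) stop("corpus total for year ", ykey, " is not positive")
  sel <- records$year == as.integer(year)
  if (case_sensitive) {
    sel <- sel & records$ngram == word
  } else {
    sel <- sel & tolower(records$ngram) == tolower(word)
  }
  sum(records$match_count[sel]) / total
}

#' Build an environment series from ngram records
#'
#' One fitness table per year, covering every word in `words`. Words absent
#' from the corpus in a year are filled per `fill_policy`: `"zero"` (a word
#' never printed has zero usage fitness) or `"pseudocount"` (fitness
#' `pseudocount / total`, useful before log-scale analyses).
#'
#' @param words character vector of genotype words.
#' @param years integer vector of environment years.
#' @param records,totals as in [ngram_frequency()].
#' @param fill_policy `"zero"` (default) or `"pseudocount"`.
#' @param pseudocount count added for absent words under the pseudocount
#'   policy (default 1).
#' @param case_sensitive passed to [ngram_frequency()].
#' @return an `environment_series` with one table per year.
#' @export
build_environment_series <- function(words, years, records, totals,
                                     fill_policy = c("zero", "pseudocount"),
                                     pseudocount = 1,
                                     case_sensitive = FALSE) {
  fill_policy <- match.arg(fill_policy)
  if (length(years) == 0) stop("years must be nonempty")
  words <- toupper(words)
  tables <- lapply(years, function(y) {
    total <- totals[[as.character(as.integer(y))]]
    if (is.null(total)) stop("no corpus total for year ", y)
    vals <- vapply(words, function(w) {
      f <- ngram_frequency(w, y, records, totals,
                           case_sensitive = case_sensitive)
      if (f == 0 && fill_policy == "pseudocount") f <- pseudocount / total
      f
    }, numeric(1))
    fitness_table(stats::setNames(vals, words), environment = as.character(y))
  })
  environment_series(tables)
}

# ---- CSV fitness tables ---------------------------------------------------

#' Read a genotype-by-environment fitness CSV
#'
#' Expects a header `genotype,environment,fitness`. Every environment must
#' cover the same genotype set; duplicates and negative fitness are errors.
#'
#' @param path file path.
#' @return an `environment_series`.
#' @export
read_fitness_csv <- function(path) {
  if (!file.exists(path)) stop("fitness file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  required <- c("genotype", "environment", "fitness")
  if (!identical(names(df), required)) {
    stop("fitness CSV must have header 'genotype,environment,fitness' (got '",
         paste(names(df), collapse = ","), "')")
  }
  if (any(is.na(df$fitness))) {
    stop("non-numeric fitness at row ", which(is.na(df$fitness))[1])
  }
  if (any(df$fitness < 0)) {
    stop("negative fitness at row ", which(df$fitness < 0)[1])
  }
  key <- paste(toupper(df$genotype), df$environment, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (genotype, environment) at row ",
         which(duplicated(key))[1])
  }
  envs <- unique(df$environment)
  tables <- lapply(envs, function(e) {
    sub <- df[df$environment == e, ]
    fitness_table(stats::setNames(sub$fitness, sub$genotype),
                  environment = e)
  })
  environment_series(tables)
}

#' Write an environment series as a fitness CSV
#'
#' The inverse of [read_fitness_csv()]: rows ordered by environment (series
#' order) then genotype (lexicographic), values printed with full precision
#' so a write-then-read round trip reproduces the series exactly.
#'
#' @param series an `environment_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fitness_csv <- function(series, path) {
  stopifnot(inherits(series, "environment_series"))
  rows <- do.call(rbind, lapply(series$environments, function(e) {
    vals <- series$tables[[e]]$values
    genos <- sort_c(names(vals))
    data.frame(genotype = genos, environment = e,
               fitness = format(unname(vals[genos]), digits = 17,
                                scientific = TRUE, trim = TRUE),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
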