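#' Speech-effect categories
#'
#' The closed taxonomy used to grade reported speech effects of microdeletion
#' syndromes, in increasing order of severity: normal, apraxic, dysarthric,
#' impaired, delayed, absent. Idiosyncratic speech is tracked as its own
#' category but by default folds into apraxic for aggregation, since apraxia
#' (a CNS disorder) typically subsumes it.
#'
#' @format character vector of category names.
#' @export
speech_categories <- c("NORMAL", "APRAXIC", "DYSARTHRIC", "IMPAIRED",
                       "DELAYED", "ABSENT")

# token -> category ruleset; abbreviations are the reported-effects codes
# (Del/Imp/Norm/Abs/Apr/Dys/Idio), matched case-insensitively on word
# boundaries, plus the spelt-out clinical words.
.effect_tokens <- list(
  DELAYED       = "\\bdel\\b|\\bdelay(ed|s)?\\b",
  IMPAIRED      = "\\bimp\\b|\\bimpair",
  NORMAL        = "\\bnorm\\b|\\bnormal\\b",
  ABSENT        = "\\babs\\b|\\babsen(t|ce)\\b",
  APRAXIC       = "\\bapr\\b|\\bapraxi",
  DYSARTHRIC    = "\\bdys\\b|\\bdysarthri",
  IDIOSYNCRATIC = "\\bidio\\b|\\bidiosyncratic\\b"
)

# descriptions that carry no speech-production anomaly
.normal_phrases <- "no significant|hearing loss"

.unavailable_phrases <- "not available"

#' Parse a reported-effects description into speech categories
#'
#' Every occurrence of a category code token (Del, Imp, Norm, Abs, Apr, Dys,
#' Idio; case-insensitive, word-bounded) or of the corresponding spelt-out
#' word maps to its category. Texts with no code token but a no-anomaly phrase
#' ("No significant ...", hearing-only findings) map to `NORMAL`. Texts with
#' no recognizable content (including "Not available") map to an empty set,
#' flagged via the `uncategorizable` attribute.
#'
#' @param text a single free-text effects description.
#' @param fold_idiosyncratic fold `IDIOSYNCRATIC` into `APRAXIC` (default), as
#'   used for severity-group aggregation.
#' @return character vector of categories (subset of [speech_categories], plus
#'   `"IDIOSYNCRATIC"` when not folded), with attribute `uncategorizable`.
#' @examples
#' parse_effects("Del, or Abs")
#' parse_effects("Norm")
#' @export
parse_effects <- function(text, fold_idiosyncratic = TRUE) {
  stopifnot(length(text) == 1L)
  txt <- if (is.na(text)) "" else trimws(text)
  if (!nzchar(txt) || grepl(.unavailable_phrases, txt, ignore.case = TRUE)) {
    return(structure(character(), uncategorizable = TRUE))
  }
  hit <- vapply(.effect_tokens, function(p) {
    grepl(p, txt, ignore.case = TRUE, perl = TRUE)
  }, logical(1))
  out <- names(.effect_tokens)[hit]
  if (length(out) == 0L && grepl(.normal_phrases, txt, ignore.case = TRUE)) {
    out <- "NORMAL"
  }
  if (fold_idiosyncratic && "IDIOSYNCRATIC" %in% out) {
    out <- unique(c(setdiff(out, "IDIOSYNCRATIC"), "APRAXIC"))
  }
  ord <- c(speech_categories, "IDIOSYNCRATIC")
  structure(out[order(match(out, ord))],
            uncategorizable = length(out) == 0L)
}

# "N (M)" / "-" / "-Same as above-" chain-count cell
.parse_count_cell <- function(x) {
  x <- trimws(x)
  if (grepl("same as above", x, ignore.case = TRUE)) {
    return(list(count = NA_integer_, connectivity = NA_integer_, same = TRUE))
  }
  if (x == "" || x == "-") {
    return(list(count = 0L, connectivity = 0L, same = FALSE))
  }
  m <- regmatches(x, regexec("^([0-9]+)\\s*\\(([0-9]+)\\)$", x))[[1]]
  if (length(m) != 3L) stop("malformed chain-count cell: '", x, "'")
  list(count = as.integer(m[2]), connectivity = as.integer(m[3]), same = FALSE)
}

#' Load syndrome records
#'
#' Reads a syndrome summary table (by default the packaged transcription of
#' the 76-row microdeletion-syndrome table) into one record per row. Chain
#' counts are given as `"N (M)"` cells holding the chainlink count and, in
#' parentheses, the chainlink connectivity; `"-"` means no chains at that
#' level and a "same as above" cell marks a duplicate-region row sharing the
#' previous row's counts (resolved by [build_cohort()]).
#'
#' @param path TSV with columns `syndrome`, `implicated`, `vn1`, `vn2`,
#'   `effects`; defaults to the packaged fixture.
#' @return a data frame with one row per record: `name`, `implicated` (list
#'   column), `vn1_count`, `vn1_connectivity`, `vn2_count`,
#'   `vn2_connectivity`, `effects`, `same_as_above`.
#' @export
syndrome_records <- function(path = voicechain_extdata("table1_fixture.tsv")) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  need <- c("syndrome", "implicated", "vn1", "vn2", "effects")
  if (!all(need %in% names(tab))) {
    stop("syndrome table needs columns: ", paste(need, collapse = ", "))
  }
  c1 <- lapply(tab$vn1, .parse_count_cell)
  c2 <- lapply(tab$vn2, .parse_count_cell)
  same <- vapply(c1, `[[`, logical(1), "same") |
    vapply(c2, `[[`, logical(1), "same")
  implicated <- lapply(tab$implicated, function(x) {
    x <- trimws(strsplit(x, ",")[[1]])
    if (length(x) == 0L || all(!nzchar(x))) character() else normalize_symbol(x[nzchar(x)])
  })
  data.frame(
    name = tab$syndrome,
    implicated = I(implicated),
    vn1_count = vapply(c1, `[[`, integer(1), "count"),
    vn1_connectivity = vapply(c1, `[[`, integer(1), "connectivity"),
    vn2_count = vapply(c2, `[[`, integer(1), "count"),
    vn2_connectivity = vapply(c2, `[[`, integer(1), "connectivity"),
    effects = tab$effects,
    same_as_above = same,
    stringsAsFactors = FALSE
  )
}

# strip the "(a)"/"(b)" variant suffix used for duplicate regions
.base_region <- function(name) sub("\\s*\\([ab]\\)$", "", name)

#' Build the analyzable syndrome cohort
#'
#' Applies the cohort rules: duplicate-region rows (same region split in the
#' literature by symptoms, not gene content) are merged, carrying a single
#' copy of the chain counts and the union of speech categories and implicated
#' genes; records without usable speech information are excluded. Rows that
#' carry their own counts must agree with the row they duplicate, otherwise
#' the merge is ambiguous and an error is raised.
#'
#' On the packaged 76-row table this yields 73 analyzable syndromes.
#'
#' @param records a data frame from [syndrome_records()].
#' @param fold_idiosyncratic passed to [parse_effects()].
#' @return a data frame of class `syndrome_cohort` with columns `name`,
#'   `merged_names`, the four count columns, `implicated` and `categories`
#'   (list columns), `effects`, and `anomalous` (any non-NORMAL category).
#'   Attribute `n_merged` gives the record count after merging but before
#'   dropping unannotated rows.
#' @export
build_cohort <- function(records, fold_idiosyncratic = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  merged <- list()
  order_seen <- character()
  for (i in seq_len(nrow(records))) {
    base <- .base_region(records$name[i])
    cats <- parse_effects(records$effects[i], fold_idiosyncratic)
    rec <- list(
      name = base, merged_names = records$name[i],
      vn1_count = records$vn1_count[i],
      vn1_connectivity = records$vn1_connectivity[i],
      vn2_count = records$vn2_count[i],
      vn2_connectivity = records$vn2_connectivity[i],
      implicated = records$implicated[[i]],
      categories = as.character(cats),
      effects = records$effects[i],
      same = records$same_as_above[i]
    )
    if (!is.null(merged[[base]])) {
      prev <- merged[[base]]
      if (!rec$same &&
          (rec$vn1_count != prev$vn1_count ||
           rec$vn2_count != prev$vn2_count ||
           rec$vn1_connectivity != prev$vn1_connectivity ||
           rec$vn2_connectivity != prev$vn2_connectivity)) {
        stop("ambiguous merge: duplicate region '", base,
             "' has differing chain counts")
      }
      prev$merged_names <- c(prev$merged_names, rec$merged_names)
      prev$implicated <- sort(unique(c(prev$implicated, rec$implicated)))
      prev$categories <- unique(c(prev$categories, rec$categories))
      prev$effects <- paste(prev$effects, rec$effects, sep = " | ")
      merged[[base]] <- prev
    } else {
      merged[[base]] <- rec
      order_seen <- c(order_seen, base)
    }
  }
  merged <- merged[order_seen]
  keep <- vapply(merged, function(r) length(r$categories) > 0, logical(1))
  cohort <- merged[keep]
  out <- data.frame(
    name = vapply(cohort, `[[`, character(1), "name"),
    merged_names = I(lapply(cohort, `[[`, "merged_names")),
    vn1_count = vapply(cohort, `[[`, integer(1), "vn1_count"),
    vn1_connectivity = vapply(cohort, `[[`, integer(1), "vn1_connectivity"),
    vn2_count = vapply(cohort, `[[`, integer(1), "vn2_count"),
    vn2_connectivity = vapply(cohort, `[[`, integer(1), "vn2_connectivity"),
    implicated = I(lapply(cohort, `[[`, "implicated")),
    categories = I(lapply(cohort, `[[`, "categories")),
    effects = vapply(cohort, `[[`, character(1), "effects"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$anomalous <- vapply(out$categories, function(cc) {
    any(cc != "NORMAL")
  }, logical(1))
  attr(out, "n_merged") <- length(merged)
  class(out) <- c("syndrome_cohort", class(out))
  out
}

#' Level-1/level-2 co-occurrence summary of a cohort
#'
#' Splits the cohort into syndromes with level-1 chains (`vn1_count > 0`) and
#' those with only level-2 chains, and reports how often each group co-occurs
#' with a speech anomaly (any non-NORMAL category). Every syndrome of the
#' motivating cohort has level-2 chains, so the level-2 co-occurrence rate is
#' computed over the whole cohort. Percentages are rounded to one decimal.
#'
#' @param cohort a [build_cohort()] result.
#' @return a list with `n`, `n_level1`, `n_level2_only`,
#'   `pct_level1_with_anomaly`, `pct_level2_with_anomaly`, `n_normal_only`.
#' @export
cooccurrence_stats <- function(cohort) {
  stopifnot(inherits(cohort, "syndrome_cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  lvl1 <- cohort$vn1_count > 0
  list(
    n = nrow(cohort),
    n_level1 = sum(lvl1),
    n_level2_only = sum(!lvl1),
    pct_level1_with_anomaly =
      if (any(lvl1)) round(100 * mean(cohort$anomalous[lvl1]), 1) else NA_real_,
    pct_level2_with_anomaly = round(100 * mean(cohort$anomalous), 1),
    n_normal_only = sum(!cohort$anomalous)
  )
}

#' Per-category chainlink statistics and severity rank ordering
#'
#' For each speech category, over the syndromes whose category set contains it
#' (membership is non-exclusive, so rows overlap), computes the count of
#' syndromes and the mean and median of the level-2 chainlink counts and
#' connectivities. Medians use the midpoint-of-middle-two convention; the
#' `mean_*_reported` columns round means to the nearest integer as they are
#' conventionally reported. Categories are then rank-ordered by ascending mean
#' chainlink count, ties broken by ascending mean connectivity; the ordering
#' is returned in the `ordering` attribute and rendered by the print method.
#'
#' @param cohort a [build_cohort()] result.
#' @param categories category names to tabulate, in reporting order.
#' @return a data frame of class `category_stats`, one row per category, with
#'   `NA` statistics for empty categories.
#' @export
category_stats <- function(cohort, categories = speech_categories) {
  stopifnot(inherits(cohort, "syndrome_cohort"))
  rows <- lapply(categories, function(cc) {
    idx <- vapply(cohort$categories, function(s) cc %in% s, logical(1))
    n <- sum(idx)
    if (n == 0L) {
      return(data.frame(category = cc, n = 0L, mean_count = NA_real_,
                        median_count = NA_real_, mean_connectivity = NA_real_,
                        median_connectivity = NA_real_))
    }
    data.frame(
      category = cc, n = n,
      mean_count = mean(cohort$vn2_count[idx]),
      median_count = stats::median(cohort$vn2_count[idx]),
      mean_connectivity = mean(cohort$vn2_connectivity[idx]),
      median_connectivity = stats::median(cohort$vn2_connectivity[idx])
    )
  })
  out <- do.call(rbind, rows)
  out$mean_count_reported <- round(out$mean_count)
  out$mean_connectivity_reported <- round(out$mean_connectivity)
  nonempty <- out[out$n > 0, ]
  ord <- nonempty$category[order(nonempty$mean_count, nonempty$mean_connectivity)]
  attr(out, "ordering") <- ord
  class(out) <- c("category_stats", class(out))
  out
}

#' Rank-ordering string of category statistics
#'
#' Renders the severity ordering in the conventional
#' `normal(32,404) < ... < absent(60,902)` form, using the reported (integer)
#' means of chainlink count and connectivity.
#'
#' @param stats a [category_stats()] result.
#' @return a single string.
#' @export
category_ordering <- function(stats) {
  stopifnot(inherits(stats, "category_stats"))
  ord <- attr(stats, "ordering")
  parts <- vapply(ord, function(cc) {
    r <- stats[stats$category == cc, ]
    sprintf("%s(%d,%d)", tolower(cc), r$mean_count_reported,
            r$mean_connectivity_reported)
  }, character(1))
  paste(parts, collapse = " < ")
}

#' @export
print.category_stats <- function(x, ...) {
  df <- as.data.frame(x)
  df$mean_count <- round(df$mean_count, 2)
  df$mean_connectivity <- round(df$mean_connectivity, 2)
  print(df, row.names = FALSE)
  cat("\nordering:", category_ordering(x), "\n")
  invisible(x)
}

#' Per-category count sets
#'
#' Extracts, for each category, the set of per-syndrome level-2 chainlink
#' counts (or connectivities) -- the integer sets the dispersion model is
#' fitted to.
#'
#' @param cohort a [build_cohort()] result.
#' @param metric `"count"` or `"connectivity"`.
#' @param categories categories to extract.
#' @return named list of integer vectors.
#' @export
category_count_sets <- function(cohort, metric = c("count", "connectivity"),
                                categories = speech_categories) {
  stopifnot(inherits(cohort, "syndrome_cohort"))
  metric <- match.arg(metric)
  col <- if (metric == "count") "vn2_count" else "vn2_connectivity"
  sets <- lapply(categories, function(cc) {
    idx <- vapply(cohort$categories, function(s) cc %in% s, logical(1))
    cohort[[col]][idx]
  })
  names(sets) <- categories
  sets
}
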