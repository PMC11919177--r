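#' Define a questionnaire scale
#'
#' A scale definition records how one self-report instrument is laid out:
#' how many items it has, the Likert response bounds, the data-frame
#' column prefix its items use, and (optionally) a partition of items
#' into subscales that are scored separately.
#'
#' @param name Scale identifier, e.g. `"phq"`.
#' @param n_items Number of items.
#' @param response_min,response_max Integer Likert bounds (inclusive).
#' @param prefix Column prefix; item `k` lives in column `<prefix>_<k>`.
#' @param subscales Named list mapping construct label to an integer
#'   vector of item indices, or `NULL` when the total score is the only
#'   construct. Subscale item sets must be disjoint and within
#'   `1:n_items`.
#' @param constructs Construct label(s) produced by this scale. For a
#'   scale without subscales this is a single label for the total score.
#'
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(name, n_items, response_min, response_max,
                             prefix = name, subscales = NULL,
                             constructs = toupper(name)) {
  stopifnot(n_items >= 1, response_min < response_max)
  if (!is.null(subscales)) {
    idx <- unlist(subscales, use.names = FALSE)
    if (anyDuplicated(idx) || any(idx < 1) || any(idx > n_items))
      stop("subscale item lists must be disjoint and within [1, n_items]")
    constructs <- names(subscales)
  }
  structure(
    list(name = name, n_items = n_items,
         response_min = response_min, response_max = response_max,
         prefix = prefix, subscales = subscales,
         constructs = constructs, scoring = "sum"),
    class = "scale_definition")
}

#' Item column names of a scale
#' @param scale A [scale_definition()].
#' @return Character vector `<prefix>_1 ... <prefix>_<n_items>`.
#' @export
item_columns <- function(scale) {
  paste0(scale$prefix, "_", seq_len(scale$n_items))
}

#' The five instruments of the two-wave study
#'
#' PHQ-9 (9 items, 0-3, depressive symptoms), GAD-7 (7 items, 0-3,
#' anxiety symptoms), RRS (22 items, 1-4, scored as three subscales:
#' symptom rumination `SR`, brooding `BD`, reflective pondering `RP`),
#' ANIS (10 items, 1-5, attention to negative information, `NAB`), and
#' the short-form ATQ (8 items, 1-5, negative automatic thoughts,
#' `NAT`). The RRS subscale item map (SR = 1-12, BD = 13-17,
#' RP = 18-22) is a fixed convention matching the subscale sizes of the
#' instrument.
#'
#' @return Named list of [scale_definition()] objects.
#' @export
default_scales <- function() {
  list(
    phq  = scale_definition("phq", 9, 0, 3, constructs = "PHQ"),
    gad  = scale_definition("gad", 7, 0, 3, constructs = "GAD"),
    rrs  = scale_definition("rrs", 22, 1, 4,
                            subscales = list(SR = 1:12, BD = 13:17,
                                             RP = 18:22)),
    anis = scale_definition("anis", 10, 1, 5, constructs = "NAB"),
    atq  = scale_definition("atq", 8, 1, 5, constructs = "NAT")
  )
}

# construct label -> (scale name, item indices), in canonical order
construct_map <- function(scales = default_scales()) {
  out <- list()
  for (sc in scales) {
    if (is.null(sc$subscales)) {
      out[[sc$constructs]] <- list(scale = sc, items = seq_len(sc$n_items))
    } else {
      for (lab in names(sc$subscales))
        out[[lab]] <- list(scale = sc, items = sc$subscales[[lab]])
    }
  }
  out[construct_labels()]
}

#' Score questionnaire records
#'
#' Sums item responses into the seven construct scores (scale totals,
#' and subscale totals for the RRS). All items of every scale must be
#' present; record-validity filtering ([apply_qc()]) guarantees this for
#' retained records.
#'
#' @param records Data frame with one row per respondent-wave, item
#'   columns named `<prefix>_<k>` (e.g. `phq_1`), and optionally `code`
#'   and `wave` columns which are carried through.
#' @param scales Scale definitions, as from [default_scales()].
#'
#' @return Data frame with `code`/`wave` (when present) and one column
#'   per construct label.
#' @export
score_records <- function(records, scales = default_scales()) {
  cmap <- construct_map(scales)
  out <- data.frame(row.names = seq_len(nrow(records)))
  for (key in c("code", "wave"))
    if (key %in% names(records)) out[[key]] <- records[[key]]
  for (lab in names(cmap)) {
    sc <- cmap[[lab]]$scale
    cols <- item_columns(sc)[cmap[[lab]]$items]
    miss <- !cols %in% names(records)
    if (any(miss))
      stop("missing item column(s) for scale '", sc$name, "': ",
           paste(cols[miss], collapse = ", "))
    vals <- as.matrix(records[, cols, drop = FALSE])
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop("missing response in scale '", sc$name, "', item ",
           cmap[[lab]]$items[bad[["col"]]], " (row ", bad[["row"]], ")")
    }
    out[[lab]] <- rowSums(vals)
  }
  rownames(out) <- NULL
  out
}

#' Record-validity filter configuration
#'
#' Thresholds for [apply_qc()]. Records are excluded, in fixed order,
#' when: the record is unparseable (a response outside its scale's
#' range, or a non-finite quality field); a lie-detection item was
#' answered incorrectly; one or more item responses are missing; the
#' response time is below `min_rt_s` (strictly); age (or the age-grade
#' pair) is out of range; any construct total is an outlier
#' (`|z| > outlier_z`); or any demographic field is missing. Each
#' excluded record is attributed to the first rule it triggers.
#'
#' @param min_rt_s Minimum plausible response time in seconds
#'   (default 480, i.e. 8 minutes; records strictly below are dropped).
#' @param outlier_z Absolute z-score threshold on construct totals.
#' @param age_range Inclusive age bounds applied when `grade_age` is
#'   `NULL`.
#' @param grade_age Optional named list mapping grade to an inclusive
#'   `c(min, max)` age range; when given, a record whose age falls
#'   outside its grade's range is an age-grade mismatch.
#' @param outlier_ref Optional reference statistics for the outlier
#'   rule: a named list `construct -> c(mean, sd)`. When `NULL`
#'   (default) the mean and sd are computed within the filtered sample
#'   itself, over records surviving the earlier rules.
#' @param demographic_cols Character vector naming demographic columns
#'   that must be non-missing; `NULL` means every column not otherwise
#'   used by the filter.
#'
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_rt_s = 480, outlier_z = 3,
                      age_range = c(18, 24), grade_age = NULL,
                      outlier_ref = NULL, demographic_cols = NULL) {
  structure(list(min_rt_s = min_rt_s, outlier_z = outlier_z,
                 age_range = age_range, grade_age = grade_age,
                 outlier_ref = outlier_ref,
                 demographic_cols = demographic_cols),
            class = "qc_config")
}

qc_reasons <- c("unparseable", "lie", "missing", "fast", "age_grade",
                "outlier", "demographic")

#' Apply record-validity filters to one wave
#'
#' @param records Data frame of raw records for a single wave: item
#'   columns, `code`, `wave`, `rt_s` (response time, seconds), `lie_ok`
#'   (logical), `age`, `grade`, and any demographic columns.
#' @param config A [qc_config()].
#' @param scales Scale definitions.
#'
#' @return A list with `retained` (the surviving rows) and `report`, a
#'   `qc_report` object with fields `n_input`, `n_retained`,
#'   `exclusions` (named counts in rule order), `retained_codes`, and
#'   `reason` (per-input-record attribution, `NA` for retained rows).
#'   Counts conserve: `n_input = n_retained + sum(exclusions)`.
#' @export
apply_qc <- function(records, config = qc_config(),
                     scales = default_scales()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  all_items <- unlist(lapply(scales, item_columns), use.names = FALSE)
  items_present <- intersect(all_items, names(records))
  imat <- if (n > 0) as.matrix(records[, items_present, drop = FALSE])
          else matrix(numeric(0), 0, 0)

  # 1. unparseable: out-of-range / non-integer responses, broken QC fields
  if (n > 0) {
    bad <- rep(FALSE, n)
    for (sc in scales) {
      cols <- intersect(item_columns(sc), names(records))
      if (!length(cols)) next
      v <- as.matrix(records[, cols, drop = FALSE])
      out_of_range <- !is.na(v) &
        (v < sc$response_min | v > sc$response_max | v != round(v))
      bad <- bad | rowSums(out_of_range) > 0
    }
    if ("rt_s" %in% names(records))
      bad <- bad | !is.finite(records$rt_s)
    if ("lie_ok" %in% names(records))
      bad <- bad | is.na(records$lie_ok)
    reason[bad] <- "unparseable"
  }

  flag <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }

  # 2. lie-detection failure
  if ("lie_ok" %in% names(records))
    flag(!records$lie_ok, "lie")
  # 3. any missing item response
  if (ncol(imat) > 0)
    flag(rowSums(is.na(imat)) > 0, "missing")
  # 4. too-fast completion
  if ("rt_s" %in% names(records))
    flag(records$rt_s < config$min_rt_s, "fast")
  # 5. age / age-grade mismatch
  if ("age" %in% names(records)) {
    if (is.null(config$grade_age)) {
      ok <- !is.na(records$age) &
        records$age >= config$age_range[1] &
        records$age <= config$age_range[2]
    } else {
      rng <- config$grade_age[as.character(records$grade)]
      ok <- mapply(function(a, r) {
        !is.null(r) && !is.na(a) && a >= r[1] && a <= r[2]
      }, records$age, rng)
    }
    flag(!ok, "age_grade")
  }
  # 6. outlier construct totals among surviving records
  pool <- which(is.na(reason))
  if (length(pool) >= 2 || (!is.null(config$outlier_ref) && length(pool) >= 1)) {
    sc_pool <- score_records(records[pool, , drop = FALSE], scales)
    labs <- construct_labels()
    z <- matrix(0, length(pool), length(labs), dimnames = list(NULL, labs))
    for (lab in labs) {
      x <- sc_pool[[lab]]
      if (!is.null(config$outlier_ref)) {
        ref <- config$outlier_ref[[lab]]
        if (is.null(ref)) next
        mu <- ref[1]; sdev <- ref[2]
      } else {
        mu <- mean(x); sdev <- sd(x)
      }
      if (!is.finite(sdev) || sdev <= 0) next
      z[, lab] <- (x - mu) / sdev
    }
    out <- pool[apply(abs(z) > config$outlier_z, 1, any)]
    reason[out] <- "outlier"
  }
  # 7. missing demographics
  demo <- config$demographic_cols
  if (is.null(demo)) {
    used <- c("code", "wave", items_present, "rt_s", "lie_ok", "age", "grade")
    demo <- setdiff(names(records), used)
  }
  demo <- intersect(demo, names(records))
  if (length(demo)) {
    dmat <- records[, demo, drop = FALSE]
    miss <- Reduce(`|`, lapply(dmat, function(x) is.na(x) | x == ""))
    flag(miss, "demographic")
  }

  keep <- is.na(reason)
  exclusions <- setNames(integer(length(qc_reasons)), qc_reasons)
  tab <- table(factor(reason[!keep], levels = qc_reasons))
  exclusions[names(tab)] <- as.integer(tab)
  report <- structure(
    list(n_input = n, n_retained = sum(keep), exclusions = exclusions,
         retained_codes = if ("code" %in% names(records))
           records$code[keep] else which(keep),
         reason = reason),
    class = "qc_report")
  list(retained = records[keep, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Record-validity report: ", x$n_retained, "/", x$n_input,
      " retained\n", sep = "")
  shown <- x$exclusions[x$exclusions > 0]
  if (length(shown))
    cat("  excluded:", paste(names(shown), shown, sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Match respondents across the two waves
#'
#' Inner join of the two waves' score tables on the respondent code,
#' reporting how many respondents appear in one wave only.
#'
#' @param scores_t1,scores_t2 Score tables (as from [score_records()])
#'   containing a `code` column; codes must be unique within a wave.
#'
#' @return A `matched_waves` object: `t1` and `t2` score tables aligned
#'   row-for-row on matched codes, `codes`, and `counts`
#'   (`t1_only`, `t2_only`, `matched`).
#' @export
match_waves <- function(scores_t1, scores_t2) {
  for (s in list(scores_t1, scores_t2))
    if (anyDuplicated(s$code))
      stop("duplicate respondent code within a wave: ",
           s$code[duplicated(s$code)][1])
  common <- intersect(scores_t1$code, scores_t2$code)
  i1 <- match(common, scores_t1$code)
  i2 <- match(common, scores_t2$code)
  structure(
    list(t1 = scores_t1[i1, , drop = FALSE],
         t2 = scores_t2[i2, , drop = FALSE],
         codes = common,
         counts = c(t1_only = nrow(scores_t1) - length(common),
                    t2_only = nrow(scores_t2) - length(common),
                    matched = length(common))),
    class = "matched_waves")
}

#' @export
print.matched_waves <- function(x, ...) {
  cat("Matched waves:", x$counts[["matched"]], "matched,",
      x$counts[["t1_only"]], "T1-only,",
      x$counts[["t2_only"]], "T2-only\n")
  invisible(x)
}

#' Prevalence above a cutoff
#'
#' Fraction of respondents whose construct score is at or above a
#' clinical cutoff. Cutoffs are configuration, not package defaults:
#' conventional screening cutoffs (e.g. 10 for the PHQ-9 and GAD-7
#' totals) are a common choice.
#'
#' @param scores Score table.
#' @param construct Construct label, e.g. `"PHQ"`.
#' @param cutoff Numeric threshold; scores `>= cutoff` count.
#' @return Proportion in `[0, 1]`.
#' @export
prevalence <- function(scores, construct, cutoff) {
  x <- scores[[construct]]
  if (is.null(x)) stop("unknown construct: ", construct)
  mean(x >= cutoff)
}

#' Paired t tests between waves
#'
#' Two-sided paired t statistics per construct for T2 - T1 change.
#' A zero-variance difference vector is reported as t = 0 with the
#' `degenerate` flag set.
#'
#' @param matched A [match_waves()] result.
#' @return Data frame: construct, mean_t1, mean_t2, t, df, p, degenerate.
#' @export
compare_waves <- function(matched) {
  labs <- intersect(construct_labels(), names(matched$t1))
  n <- nrow(matched$t1)
  if (n < 2) stop("paired comparison needs at least 2 matched respondents")
  res <- lapply(labs, function(lab) {
    d <- matched$t2[[lab]] - matched$t1[[lab]]
    if (sd(d) == 0) {
      data.frame(construct = lab, mean_t1 = mean(matched$t1[[lab]]),
                 mean_t2 = mean(matched$t2[[lab]]),
                 t = 0, df = n - 1, p = NA_real_, degenerate = TRUE)
    } else {
      tt <- t.test(d)
      data.frame(construct = lab, mean_t1 = mean(matched$t1[[lab]]),
                 mean_t2 = mean(matched$t2[[lab]]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Welch t tests between two independent samples
#'
#' A construct with (near-)zero variance in both groups is reported as
#' t = 0 with the `degenerate` flag set.
#'
#' @param scores_a,scores_b Score tables for the two groups.
#' @return Data frame: construct, mean_a, mean_b, t, df, p, degenerate.
#' @export
compare_samples <- function(scores_a, scores_b) {
  labs <- intersect(construct_labels(), names(scores_a))
  if (nrow(scores_a) < 2 || nrow(scores_b) < 2)
    stop("independent comparison needs at least 2 records per group")
  res <- lapply(labs, function(lab) {
    tt <- tryCatch(t.test(scores_a[[lab]], scores_b[[lab]]),
                   error = function(e) NULL)
    data.frame(construct = lab,
               mean_a = mean(scores_a[[lab]]),
               mean_b = mean(scores_b[[lab]]),
               t = if (is.null(tt)) 0 else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               degenerate = is.null(tt))
  })
  do.call(rbind, res)
}
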