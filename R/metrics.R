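#' Round half away from zero
#'
#' Display rounding used throughout the report layer (metrics and ratios to
#' two decimals, demographic percentages to integers). R's `round()` rounds
#' half to even; printed tables in this field round half up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulps so that values stored imprecisely just under .5
  # (e.g. 1.005 * 100 = 100.49999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Tally case outcomes into a confusion table
#'
#' @param outcomes Case-outcome tibble with a `state` column.
#' @return An object of class `confusion_counts`: a list with `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
confusion <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0L) {
    stop("cannot tally an empty outcome list", call. = FALSE)
  }
  stopifnot(all(outcomes$state %in% c("TP", "FN", "TN", "FP")))
  structure(
    list(
      tp = sum(outcomes$state == "TP"),
      fn = sum(outcomes$state == "FN"),
      tn = sum(outcomes$state == "TN"),
      fp = sum(outcomes$state == "FP")
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> TP %d  FN %d  TN %d  FP %d\n",
    x$tp, x$fn, x$tn, x$fp
  ))
  invisible(x)
}

#' Case-level metric panel from confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n`, PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`. A metric whose
#' denominator is zero is returned as `NA` (an explicit undefined flag,
#' never a silent zero); an empty table is an error.
#'
#' @param counts A `confusion_counts` object or a list with fields `tp`,
#'   `fn`, `tn`, `fp`.
#' @param mfpi Optional mFPI value to carry along in the panel.
#' @return An object of class `metric_set`: a list with the five fractions
#'   plus `mfpi` and the source `counts`.
#' @examples
#' metric_set(list(tp = 39, fn = 20, tn = 243, fp = 10))
#' @export
metric_set <- function(counts, mfpi = NULL) {
  n <- counts$tp + counts$fn + counts$tn + counts$fp
  if (n == 0) stop("metric_set of zero cases is undefined", call. = FALSE)
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(
      sensitivity = frac(counts$tp, counts$tp + counts$fn),
      specificity = frac(counts$tn, counts$tn + counts$fp),
      accuracy = (counts$tp + counts$tn) / n,
      ppv = frac(counts$tp, counts$tp + counts$fp),
      npv = frac(counts$tn, counts$tn + counts$fn),
      mfpi = if (is.null(mfpi)) NA_real_ else mfpi,
      counts = counts
    ),
    class = "metric_set"
  )
}

metric_names <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  cat("<metric_set>\n")
  for (m in metric_names) {
    cat(sprintf(
      "  %-11s %s\n", m,
      ifelse(is.na(x[[m]]), "undefined", sprintf("%.2f", round_half_up(x[[m]], digits)))
    ))
  }
  if (!is.na(x$mfpi)) cat(sprintf("  %-11s %.3f\n", "mfpi", x$mfpi))
  invisible(x)
}

#' Per-reader and pooled metric panels
#'
#' Pooled (group and overall) metrics are micro-averages: confusion counts
#' are summed across the readers of a group before the metric formulas are
#' applied, matching how overall columns of reader-study tables are built
#' and how GEE marginal means behave. Per-reader panels are also returned.
#'
#' @param outcomes Reader case outcomes: tibble with `reader_id`, `arm`
#'   (`"pre_cad"` / `"post_cad"`), `image_id`, `state`, `fp_lesion_count`.
#' @param groups A data frame `reader_id`, `group` assigning each reader to
#'   a reader group (e.g. general physicians vs radiologists).
#' @return A list with `per_reader` (tibble: reader, group, arm, metrics)
#'   and `pooled` (tibble: group — including `"overall"` — by arm).
#' @export
pooled_metrics <- function(outcomes, groups) {
  stopifnot(all(c("reader_id", "arm", "image_id", "state") %in% names(outcomes)))
  outcomes <- outcomes[outcomes$arm %in% c("pre_cad", "post_cad"), ]
  img_sets <- split(outcomes$image_id, interaction(outcomes$reader_id, outcomes$arm, drop = TRUE))
  ref <- sort(img_sets[[1]])
  same <- vapply(img_sets, function(s) identical(sort(s), ref), logical(1))
  if (!all(same)) {
    stop("all readers must contribute both arms over the same image set",
      call. = FALSE
    )
  }
  outcomes <- dplyr::left_join(outcomes, groups, by = "reader_id")
  if (any(is.na(outcomes$group))) {
    stop("every reader_id must appear in the group assignment", call. = FALSE)
  }
  panel_row <- function(df) {
    ms <- metric_set(confusion(df), mfpi = mfpi(df))
    tibble::as_tibble(ms[c(metric_names, "mfpi")])
  }
  per_reader <- outcomes |>
    dplyr::group_by(.data$reader_id, .data$group, .data$arm) |>
    dplyr::group_modify(~ panel_row(.x)) |>
    dplyr::ungroup()
  pooled_g <- outcomes |>
    dplyr::group_by(.data$group, .data$arm) |>
    dplyr::group_modify(~ panel_row(.x)) |>
    dplyr::ungroup()
  pooled_all <- outcomes |>
    dplyr::group_by(.data$arm) |>
    dplyr::group_modify(~ panel_row(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(group = "overall", .before = 1)
  list(per_reader = per_reader, pooled = dplyr::bind_rows(pooled_g, pooled_all))
}

#' Naive with-CAD / without-CAD metric ratios
#'
#' Elementwise division of the with-CAD panel by the without-CAD panel,
#' rounded half-up to two decimals for display. These are descriptive;
#' inference on the ratios (robust CIs, p-values) lives in [fit_gee()].
#' An undefined metric in either arm propagates as `NA`.
#'
#' @param pre,post `metric_set` objects (or lists with the five metric
#'   fields) for the without-CAD and with-CAD arms.
#' @param digits Display rounding (default two decimals).
#' @return A tibble `metric`, `pre`, `post`, `ratio`.
#' @export
ratio_report <- function(pre, post, digits = 2) {
  ratio <- vapply(metric_names, function(m) {
    a <- pre[[m]]
    b <- post[[m]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) NA_real_ else b / a
  }, numeric(1))
  tibble::tibble(
    metric = metric_names,
    pre = unname(vapply(metric_names, function(m) pre[[m]] %||% NA_real_, numeric(1))),
    post = unname(vapply(metric_names, function(m) post[[m]] %||% NA_real_, numeric(1))),
    ratio = unname(round_half_up(ratio, digits))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Eligibility filter for candidate malignant radiographs
#'
#' Applies the exclusion cascade that defines the malignant test set, in
#' fixed order: metastatic (non-primary) lesions; mass lesions larger than
#' 30 mm; non-nodular presentations; nodules not visible on the radiograph
#' (including ground-glass nodules under 5 mm). A candidate failing several
#' criteria is counted once, at the first failing criterion, so the cascade
#' counts always conserve the input size.
#'
#' @param candidates Data frame with logical/numeric columns
#'   `is_metastasis`, `size_mm`, `is_nodular`, `visible_on_radiograph` and
#'   optionally `is_ggn_under_5mm`.
#' @return A list with `retained` (the surviving rows) and `report`, a list
#'   of class `eligibility_report` with the cascade counts.
#' @export
eligibility_filter <- function(candidates) {
  req <- c("is_metastasis", "size_mm", "is_nodular", "visible_on_radiograph")
  missing <- setdiff(req, names(candidates))
  if (length(missing) > 0) {
    stop(sprintf(
      "candidates lack required attribute(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  ggn <- if ("is_ggn_under_5mm" %in% names(candidates)) {
    candidates$is_ggn_under_5mm
  } else {
    rep(FALSE, nrow(candidates))
  }
  if (anyNA(candidates[req]) || anyNA(ggn)) {
    stop("eligibility attributes must not contain NA", call. = FALSE)
  }
  stage <- rep("retained", nrow(candidates))
  stage[!candidates$visible_on_radiograph | ggn] <- "not_visible"
  stage[!candidates$is_nodular] <- "non_nodular"
  stage[candidates$size_mm > 30] <- "over_30mm"
  stage[candidates$is_metastasis] <- "metastasis"
  report <- structure(
    list(
      collected = nrow(candidates),
      excluded_metastasis = sum(stage == "metastasis"),
      excluded_over_30mm = sum(stage == "over_30mm"),
      excluded_non_nodular = sum(stage == "non_nodular"),
      excluded_not_visible = sum(stage == "not_visible"),
      remaining = sum(stage == "retained")
    ),
    class = "eligibility_report"
  )
  list(retained = candidates[stage == "retained", ], report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("<eligibility_report>\n")
  cat(sprintf("  collected            %d\n", x$collected))
  cat(sprintf("  - metastasis         %d\n", x$excluded_metastasis))
  cat(sprintf("  - mass > 30 mm       %d\n", x$excluded_over_30mm))
  cat(sprintf("  - non-nodular        %d\n", x$excluded_non_nodular))
  cat(sprintf("  - not visible        %d\n", x$excluded_not_visible))
  cat(sprintf("  remaining            %d\n", x$remaining))
  invisible(x)
}

#' Cohort demographic summary
#'
#' Builds the demographic table of a test set: lesion size bins, laterality,
#' location and overlapping-structure counts with integer percentages over
#' the number of cancers, and per-vendor malignant fractions over per-vendor
#' image totals. Percentages round half up; an empty cohort yields zero
#' counts and no percentages.
#'
#' @param images Image table (`image_id`, `label`, `vendor`).
#' @param lesions Lesion table (`image_id`, `size_bin`, `laterality`,
#'   `location`, `overlap_structure`).
#' @return A list of tibbles: `totals`, `size_bin`, `laterality`,
#'   `location`, `overlap`, `vendor`.
#' @export
cohort_summary <- function(images, lesions) {
  n_cancer <- sum(images$label == "malignant")
  count_pct <- function(values, levels) {
    n <- unname(vapply(levels, function(l) sum(values == l), integer(1)))
    tibble::tibble(
      level = levels, n = n,
      pct = if (n_cancer > 0) round_half_up(100 * n / n_cancer) else NA_real_
    )
  }
  vendor_levels <- sort(unique(images$vendor))
  vendor <- tibble::tibble(
    vendor = vendor_levels,
    n_malignant = unname(vapply(vendor_levels, function(v) {
      sum(images$vendor == v & images$label == "malignant")
    }, integer(1))),
    n_total = unname(vapply(vendor_levels, function(v) sum(images$vendor == v), integer(1)))
  )
  vendor$pct_malignant <- ifelse(
    vendor$n_total > 0,
    round_half_up(100 * vendor$n_malignant / vendor$n_total), NA_real_
  )
  list(
    totals = tibble::tibble(
      n_images = nrow(images), n_cancers = n_cancer,
      n_normal = sum(images$label == "normal"),
      size_mean = if (n_cancer > 0) mean(lesions$size_mm) else NA_real_,
      size_sd = if (n_cancer > 1) stats::sd(lesions$size_mm) else NA_real_
    ),
    size_bin = count_pct(lesions$size_bin, c("<=10", "11-20", "21-30")),
    laterality = count_pct(lesions$laterality, c("right", "left")),
    location = count_pct(lesions$location, c("upper", "middle", "lower")),
    overlap = count_pct(
      lesions$overlap_structure,
      c("heart", "clavicle", "diaphragm", "hilar_vessels", "none")
    ),
    vendor = vendor
  )
}
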