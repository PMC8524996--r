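#' Write a study bundle to a directory
#'
#' Serializes a bundle as inspectable plain text: `manifest.json` plus CSV
#' tables `images.csv`, `lesions.csv`, `annotations.csv`, `readers.csv`.
#' All values are written at full precision; rounding happens only in the
#' report layer.
#'
#' @param bundle A `study_bundle`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    bundle$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  for (tab in c("images", "lesions", "annotations", "readers")) {
    utils::write.csv(bundle[[tab]], file.path(dir, paste0(tab, ".csv")),
      row.names = FALSE
    )
  }
  invisible(dir)
}

#' Read and validate a study bundle
#'
#' Reads the `manifest.json` + CSV layout written by [write_bundle()].
#' Annotation (and lesion) boxes may use either the corner dialect
#' (`x_min, y_min, x_max, y_max`) or the width/height dialect
#' (`x, y, width, height`, with `(x, y)` the top-left corner); the latter
#' is converted on read and the dialect recorded in the manifest. Schema
#' violations, broken referential integrity and duplicate annotation rows
#' are errors naming the offending rows.
#'
#' @param dir Directory holding the bundle.
#' @return A `study_bundle`.
#' @export
read_bundle <- function(dir) {
  need <- file.path(dir, c("manifest.json", "images.csv", "annotations.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop(sprintf("bundle is missing: %s", paste(basename(missing), collapse = ", ")),
      call. = FALSE
    )
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  read_tab <- function(name, required = TRUE) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      if (required) stop(sprintf("bundle is missing %s.csv", name), call. = FALSE)
      return(NULL)
    }
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  images <- read_tab("images")
  lesions <- read_tab("lesions", required = FALSE)
  annotations <- read_tab("annotations")
  readers <- read_tab("readers", required = FALSE)
  if (is.null(lesions)) {
    lesions <- tibble::tibble(
      image_id = character(), x_min = numeric(), y_min = numeric(),
      x_max = numeric(), y_max = numeric()
    )
  }
  dialect <- "corners"
  conv <- convert_box_dialect(annotations, "annotations")
  annotations <- conv$table
  if (conv$converted) dialect <- "xywh"
  conv <- convert_box_dialect(lesions, "lesions")
  lesions <- conv$table
  if (conv$converted) dialect <- "xywh"
  manifest$box_dialect <- dialect
  validate_bundle_tables(images, lesions, annotations, readers)
  if (is.null(readers)) {
    ids <- unique(annotations$reader_id[annotations$source == "reader"])
    readers <- tibble::tibble(
      reader_id = ids[!is.na(ids)], group = "all"
    )
  }
  structure(
    list(
      manifest = manifest, images = images, lesions = lesions,
      annotations = annotations, readers = readers
    ),
    class = "study_bundle"
  )
}

# accept (x, y, width, height) annotation files: converted to corners
convert_box_dialect <- function(tab, what) {
  if (all(box_cols %in% names(tab))) {
    return(list(table = tab, converted = FALSE))
  }
  xywh <- c("x", "y", "width", "height")
  if (all(xywh %in% names(tab))) {
    if (nrow(tab) > 0 && any(tab$width <= 0 | tab$height <= 0)) {
      bad <- which(tab$width <= 0 | tab$height <= 0)
      stop(sprintf(
        "%s.csv: non-positive width/height in row(s) %s",
        what, paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    tab$x_min <- tab$x
    tab$y_min <- tab$y
    tab$x_max <- tab$x + tab$width
    tab$y_max <- tab$y + tab$height
    tab <- tab[setdiff(names(tab), xywh)]
    return(list(table = tab, converted = TRUE))
  }
  stop(sprintf(
    "%s.csv: box columns must be (%s) or (%s)",
    what, paste(box_cols, collapse = ", "), paste(xywh, collapse = ", ")
  ), call. = FALSE)
}

validate_bundle_tables <- function(images, lesions, annotations, readers) {
  if (!all(c("image_id", "label") %in% names(images))) {
    stop("images.csv must have columns image_id, label", call. = FALSE)
  }
  check_study_tables(images, lesions)
  req <- c("source", "reader_id", "arm", "image_id", box_cols)
  missing <- setdiff(req, names(annotations))
  if (length(missing) > 0) {
    stop(sprintf(
      "annotations.csv lacks column(s): %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(annotations) > 0) {
    validate_boxes(annotations, "annotations.csv")
    bad_arm <- which(!(
      (annotations$source == "cad" & annotations$arm == "cad") |
        (annotations$source == "reader" &
          annotations$arm %in% c("pre_cad", "post_cad") &
          !is.na(annotations$reader_id))
    ))
    if (length(bad_arm) > 0) {
      stop(sprintf(
        "annotations.csv: inconsistent source/arm/reader_id in row(s) %s",
        paste(utils::head(bad_arm, 10), collapse = ", ")
      ), call. = FALSE)
    }
    unknown <- which(!annotations$image_id %in% images$image_id)
    if (length(unknown) > 0) {
      stop(sprintf(
        "annotations.csv: unknown image_id in row(s) %s",
        paste(utils::head(unknown, 10), collapse = ", ")
      ), call. = FALSE)
    }
    key <- do.call(paste, c(annotations[req], sep = "\r"))
    dup <- which(duplicated(key))
    if (length(dup) > 0) {
      stop(sprintf(
        "annotations.csv: duplicate (source, reader, arm, image, box) row(s) %s",
        paste(utils::head(dup, 10), collapse = ", ")
      ), call. = FALSE)
    }
  }
  if (!is.null(readers) && !all(c("reader_id", "group") %in% names(readers))) {
    stop("readers.csv must have columns reader_id, group", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate a study bundle
#'
#' The full descriptive analysis of one bundle: per-case outcomes for every
#' annotation set, per-reader and pooled (group and overall) metric panels
#' with mFPI, the standalone CAD panel, naive with-CAD/without-CAD ratios
#' of the pooled overall metrics, and the cohort demographic summary.
#'
#' @param bundle A `study_bundle`.
#' @param policy A [match_policy()].
#' @return A list of class `study_evaluation` with elements `outcomes`,
#'   `per_reader`, `pooled`, `cad` (a `metric_set`), `naive_ratios`,
#'   `cohort`.
#' @export
evaluate_study <- function(bundle, policy = match_policy()) {
  outcomes <- classify_bundle(bundle, policy)
  reader_out <- outcomes[outcomes$source == "reader", ]
  pm <- pooled_metrics(reader_out, bundle$readers[c("reader_id", "group")])
  cad_out <- outcomes[outcomes$source == "cad", ]
  cad_ms <- metric_set(confusion(cad_out), mfpi = mfpi(cad_out))
  overall <- pm$pooled[pm$pooled$group == "overall", ]
  pre <- as.list(overall[overall$arm == "pre_cad", ])
  post <- as.list(overall[overall$arm == "post_cad", ])
  structure(
    list(
      outcomes = outcomes,
      per_reader = pm$per_reader,
      pooled = pm$pooled,
      cad = cad_ms,
      naive_ratios = ratio_report(pre, post),
      cohort = cohort_summary(bundle$images, bundle$lesions)
    ),
    class = "study_evaluation"
  )
}

#' @export
print.study_evaluation <- function(x, ...) {
  cat("<study_evaluation>\n")
  cat("Pooled metrics by group and arm:\n")
  print(dplyr::mutate(x$pooled, dplyr::across(
    dplyr::all_of(c(metric_names, "mfpi")), ~ round_half_up(.x, 2)
  )))
  cat("Standalone CAD:\n")
  print(x$cad)
  cat("Naive with-CAD / without-CAD ratios (overall, descriptive):\n")
  print(x$naive_ratios)
  invisible(x)
}

#' Write evaluation and transition reports as CSV
#'
#' Emits `outcomes.csv` (per-case outcomes with reader and arm),
#' `metrics_per_reader.csv`, `metrics_pooled.csv`, `metrics_cad.csv`,
#' `ratios_naive.csv`, the cohort summary tables
#' (`cohort_<attribute>.csv`) and, when transitions are supplied,
#' `transitions_counts.csv` / `transitions_rates.csv`. Report numbers equal
#' the library-API numbers exactly; only display rounding is applied where
#' documented.
#'
#' @param evaluation A [evaluate_study()] result.
#' @param dir Target directory (created if missing).
#' @param transitions Optional [transition_analysis()] result.
#' @param gee Optional [gee_ratio_panel()] tibble, written as `gee.csv`.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(evaluation, dir, transitions = NULL, gee = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  }
  w(evaluation$outcomes, "outcomes.csv")
  w(evaluation$per_reader, "metrics_per_reader.csv")
  w(evaluation$pooled, "metrics_pooled.csv")
  cad <- evaluation$cad
  w(
    tibble::as_tibble(cad[c(metric_names, "mfpi")]),
    "metrics_cad.csv"
  )
  w(evaluation$naive_ratios, "ratios_naive.csv")
  for (nm in c("totals", "size_bin", "laterality", "location", "overlap", "vendor")) {
    w(evaluation$cohort[[nm]], sprintf("cohort_%s.csv", nm))
  }
  if (!is.null(transitions)) {
    w(transitions$counts, "transitions_counts.csv")
    w(transitions$rates, "transitions_rates.csv")
  }
  if (!is.null(gee)) w(gee, "gee.csv")
  invisible(dir)
}
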