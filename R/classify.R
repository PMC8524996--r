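#' Classify a single image against one set of annotation boxes
#'
#' Applies the case-level definitions: a malignant image is TP when at least
#' one annotation matches its lesion at the policy's IoU threshold and FN
#' otherwise; a normal image is TN when it carries no annotations and FP
#' otherwise. Every annotation not matched to a lesion counts as a
#' false-positive lesion (on a normal image, all of them), which is what the
#' mFPI numerator sums.
#'
#' @param image A one-row data frame with columns `image_id` and `label`
#'   (`"malignant"` or `"normal"`).
#' @param boxes A box table of annotations on this image (possibly empty).
#'   If it has an `image_id` column, it must equal the image's.
#' @param policy A [match_policy()].
#' @param lesion For a malignant image, a box table with its ground-truth
#'   lesion box(es); ignored for normal images.
#' @return A one-row tibble with `image_id`, `state` (`"TP"`, `"FN"`,
#'   `"TN"`, `"FP"`), `fp_lesion_count` and `matched_iou` (IoU of the first
#'   matched pair, `NA` when nothing matched).
#' @export
classify_case <- function(image, boxes, policy = match_policy(),
                          lesion = NULL) {
  stopifnot(nrow(image) == 1L, image$label %in% c("malignant", "normal"))
  if (!is.null(boxes) && nrow(boxes) > 0 && "image_id" %in% names(boxes)) {
    if (any(boxes$image_id != image$image_id)) {
      stop(sprintf(
        "boxes reference image(s) %s but image is %s",
        paste(unique(setdiff(boxes$image_id, image$image_id)), collapse = ", "),
        image$image_id
      ), call. = FALSE)
    }
  }
  if (is.null(boxes)) boxes <- bbox(numeric(), numeric(), numeric(), numeric())
  n_boxes <- nrow(boxes)
  if (identical(image$label, "normal")) {
    state <- if (n_boxes == 0L) "TN" else "FP"
    return(tibble::tibble(
      image_id = image$image_id, state = state,
      fp_lesion_count = n_boxes, matched_iou = NA_real_
    ))
  }
  if (is.null(lesion) || nrow(lesion) == 0L) {
    stop("malignant image must carry a ground-truth lesion", call. = FALSE)
  }
  mr <- match_boxes(boxes, lesion, policy)
  n_matched <- nrow(mr$matched_pairs)
  tibble::tibble(
    image_id = image$image_id,
    state = if (n_matched >= 1L) "TP" else "FN",
    fp_lesion_count = n_boxes - n_matched,
    matched_iou = if (n_matched >= 1L) mr$matched_pairs$iou[1] else NA_real_
  )
}

#' Classify every image of a study against one annotation set
#'
#' Images with no annotation rows are treated as "no boxes" (readers mark
#' only suspected nodules), so an empty annotation table yields TN on every
#' normal image and FN on every malignant one. Results are ordered by
#' `image_id`.
#'
#' @param images Image table with columns `image_id`, `label`.
#' @param lesions Lesion table with `image_id` plus box columns; one row per
#'   lesion (the study regime has exactly one per malignant image).
#' @param annotations Box table with an `image_id` column: the marks of one
#'   reader arm or of the CAD. May have zero rows.
#' @param policy A [match_policy()].
#' @return A tibble with one row per image: `image_id`, `label`, `state`,
#'   `fp_lesion_count`, `matched_iou`.
#' @export
classify_study <- function(images, lesions, annotations,
                           policy = match_policy()) {
  check_study_tables(images, lesions)
  if (is.null(annotations) || nrow(annotations) == 0L) {
    annotations <- tibble::tibble(
      image_id = character(), x_min = numeric(), y_min = numeric(),
      x_max = numeric(), y_max = numeric()
    )
  }
  unknown <- setdiff(unique(annotations$image_id), images$image_id)
  if (length(unknown) > 0) {
    stop(sprintf(
      "annotations reference unknown image_id(s): %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  validate_boxes(annotations, "annotation")
  single <- !anyDuplicated(lesions$image_id)
  if (single) {
    out <- classify_vectorized(images, lesions, annotations, policy)
  } else {
    out <- classify_by_image(images, lesions, annotations, policy)
  }
  dplyr::arrange(out, .data$image_id)
}

# Fast path for the one-lesion-per-image regime: with a single lesion the
# one-to-one matching reduces to "does the best box reach the threshold".
classify_vectorized <- function(images, lesions, annotations, policy) {
  thr <- policy$iou_threshold
  if (nrow(annotations) > 0) {
    les <- lesions[c("image_id", box_cols)]
    names(les)[-1] <- paste0("les_", box_cols)
    ann <- dplyr::left_join(annotations, les, by = "image_id")
    has_lesion <- !is.na(ann$les_x_min)
    iou <- rep(NA_real_, nrow(ann))
    if (any(has_lesion)) {
      a <- ann[has_lesion, box_cols]
      b <- ann[has_lesion, paste0("les_", box_cols)]
      names(b) <- box_cols
      iou[has_lesion] <- box_iou(a, b)
    }
    ann$iou <- iou
    per_image <- ann |>
      dplyr::group_by(.data$image_id) |>
      dplyr::summarise(
        n_boxes = dplyr::n(),
        best_iou = ifelse(all(is.na(.data$iou)), NA_real_,
          max(.data$iou, na.rm = TRUE)
        ),
        .groups = "drop"
      )
  } else {
    per_image <- tibble::tibble(
      image_id = character(), n_boxes = integer(), best_iou = numeric()
    )
  }
  out <- images[c("image_id", "label")] |>
    dplyr::left_join(per_image, by = "image_id") |>
    dplyr::mutate(
      n_boxes = ifelse(is.na(.data$n_boxes), 0L, .data$n_boxes),
      matched = !is.na(.data$best_iou) & .data$best_iou >= thr,
      state = dplyr::case_when(
        .data$label == "malignant" & .data$matched ~ "TP",
        .data$label == "malignant" ~ "FN",
        .data$n_boxes == 0L ~ "TN",
        TRUE ~ "FP"
      ),
      fp_lesion_count = as.integer(.data$n_boxes - .data$matched),
      matched_iou = ifelse(.data$matched, .data$best_iou, NA_real_)
    )
  out[c("image_id", "label", "state", "fp_lesion_count", "matched_iou")]
}

# General path: full one-to-one matching per image (multi-lesion inputs).
classify_by_image <- function(images, lesions, annotations, policy) {
  rows <- lapply(seq_len(nrow(images)), function(i) {
    img <- images[i, ]
    boxes <- annotations[annotations$image_id == img$image_id, ]
    les <- lesions[lesions$image_id == img$image_id, ]
    if (identical(img$label, "normal")) {
      return(classify_case(img, boxes, policy))
    }
    mr <- match_boxes(boxes[box_cols], les[box_cols], policy)
    n_matched <- nrow(mr$matched_pairs)
    tibble::tibble(
      image_id = img$image_id,
      state = if (n_matched >= 1L) "TP" else "FN",
      fp_lesion_count = nrow(boxes) - n_matched,
      matched_iou = if (n_matched >= 1L) mr$matched_pairs$iou[1] else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out, images[c("image_id", "label")], by = "image_id")[
    , c("image_id", "label", "state", "fp_lesion_count", "matched_iou")
  ]
}

check_study_tables <- function(images, lesions) {
  stopifnot(
    all(c("image_id", "label") %in% names(images)),
    all(images$label %in% c("malignant", "normal"))
  )
  if (anyDuplicated(images$image_id)) {
    stop("duplicate image_id in images table", call. = FALSE)
  }
  if (nrow(lesions) > 0) {
    validate_boxes(lesions, "lesion")
    bad <- setdiff(lesions$image_id, images$image_id[images$label == "malignant"])
    if (length(bad) > 0) {
      stop(sprintf(
        "lesions reference non-malignant or unknown image_id(s): %s",
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  mal <- images$image_id[images$label == "malignant"]
  missing_lesion <- setdiff(mal, lesions$image_id)
  if (length(missing_lesion) > 0) {
    stop(sprintf(
      "malignant image(s) without a ground-truth lesion: %s",
      paste(missing_lesion, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify every annotation set in a study bundle
#'
#' Runs [classify_study()] once per (source, reader, arm) combination —
#' every reader's pre-CAD and post-CAD arms plus the standalone CAD — using
#' a single shared code path, and stacks the per-case outcomes.
#'
#' @param bundle A `study_bundle` (see [simulate_study()] / [read_bundle()]).
#' @param policy A [match_policy()].
#' @return A tibble of case outcomes with columns `source`, `reader_id`,
#'   `arm`, `image_id`, `label`, `state`, `fp_lesion_count`, `matched_iou`.
#' @export
classify_bundle <- function(bundle, policy = match_policy()) {
  stopifnot(inherits(bundle, "study_bundle"))
  sets <- dplyr::bind_rows(
    tibble::tibble(source = "cad", reader_id = NA_character_, arm = "cad"),
    tidyr::expand_grid(
      source = "reader",
      reader_id = bundle$readers$reader_id,
      arm = c("pre_cad", "post_cad")
    )
  )
  ann <- bundle$annotations
  out <- lapply(seq_len(nrow(sets)), function(i) {
    s <- sets[i, ]
    sel <- ann$source == s$source & ann$arm == s$arm &
      (s$source == "cad" | ann$reader_id == s$reader_id)
    res <- classify_study(bundle$images, bundle$lesions, ann[sel, ], policy)
    dplyr::bind_cols(s[rep(1L, nrow(res)), ], res)
  })
  dplyr::bind_rows(out)
}

#' Mean false-positive indications per image (mFPI)
#'
#' Total false-positive lesion marks divided by the total number of images
#' in the set — the denominator counts all images, malignant and normal.
#'
#' @param outcomes A case-outcome tibble (from [classify_study()]) for one
#'   annotation set; must be non-empty.
#' @return A single non-negative number.
#' @examples
#' # 16 FP lesions over 312 images -> 0.0513
#' @export
mfpi <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0L) {
    stop("mFPI is undefined for an empty outcome list", call. = FALSE)
  }
  sum(outcomes$fp_lesion_count) / nrow(outcomes)
}
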