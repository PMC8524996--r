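#' Configuration of a synthetic reader study
#'
#' The defaults emulate the published chest-radiograph study conditions the
#' package is calibrated against: 59 malignant images (one nodule each) and
#' 253 normal images on 2000x2000-pixel radiographs; nodule size bins,
#' laterality, location, overlapping structure and vendor mix drawn from
#' the study's demographic table; a standalone CAD operating point of
#' sensitivity 0.66 with 0.05 false-positive marks per image; and two
#' groups of nine readers (general physicians, radiologists) with baseline
#' sensitivities 0.47 and 0.51, baseline specificity 0.96, and
#' CAD-conditioned decision-switching probabilities taken from the study's
#' transition table (FN to TP given CAD TP: 0.59 / 0.49; FP to TN given CAD
#' TN: 0.36 / 0.29; TN to FP given CAD FP: 0.15 / 0.22; TP to FN given CAD
#' FN: 0.02, a small nonzero default since the event occurred but no group
#' rate is usable).
#'
#' @param n_malignant,n_normal Image counts.
#' @param image_extent Width/height of the synthetic radiograph in pixels.
#' @param px_per_mm Fixed geometric scale used to turn nodule diameters
#'   into box sizes (default 5 px/mm).
#' @param size_bin_probs Named probabilities over `"<=10"`, `"11-20"`,
#'   `"21-30"` mm bins.
#' @param laterality_probs,location_probs,overlap_probs Named lesion
#'   attribute distributions.
#' @param vendor_probs Named distribution of vendors over all images.
#' @param vendor_malignant_probs Named distribution of vendors over
#'   malignant images (lets the per-vendor malignant fraction differ).
#' @param cad_sensitivity Per-lesion detection probability of the CAD.
#' @param cad_fp_rate Expected false-positive CAD marks per image
#'   (Poisson).
#' @param n_readers_per_group Readers per group (default 9).
#' @param baseline_sensitivity Named group means of reader pre-CAD
#'   per-lesion detection probability.
#' @param baseline_specificity Reader pre-CAD specificity (probability of
#'   leaving a normal image unmarked).
#' @param reader_concentration Beta concentration (a+b) of the per-reader
#'   baseline sensitivity around its group mean; larger is more
#'   homogeneous.
#' @param switch_probs Named list (one element per group) of named vectors
#'   `c(fn_tp, fp_tn, tp_fn, tn_fp)`: the probability that a reader flips
#'   the case state in each tracked (CAD state, before state) cell.
#' @param iou_range Range the target IoU of generated true-positive boxes
#'   is drawn from.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_malignant = 59L,
                         n_normal = 253L,
                         image_extent = c(2000L, 2000L),
                         px_per_mm = 5,
                         size_bin_probs = c("<=10" = 7, "11-20" = 33, "21-30" = 19) / 59,
                         laterality_probs = c(right = 39, left = 20) / 59,
                         location_probs = c(upper = 23, middle = 31, lower = 5) / 59,
                         overlap_probs = c(
                           heart = 2, clavicle = 6, diaphragm = 1,
                           hilar_vessels = 3, none = 47
                         ) / 59,
                         vendor_probs = c(FUJIFILM = 89, KONICA = 113, Philips = 110) / 312,
                         vendor_malignant_probs = c(FUJIFILM = 6, KONICA = 31, Philips = 22) / 59,
                         cad_sensitivity = 0.66,
                         cad_fp_rate = 0.05,
                         n_readers_per_group = 9L,
                         baseline_sensitivity = c(
                           general_physician = 0.47,
                           radiologist = 0.51
                         ),
                         baseline_specificity = 0.96,
                         reader_concentration = 40,
                         switch_probs = list(
                           general_physician = c(
                             fn_tp = 0.59, fp_tn = 0.36,
                             tp_fn = 0.02, tn_fp = 0.15
                           ),
                           radiologist = c(
                             fn_tp = 0.49, fp_tn = 0.29,
                             tp_fn = 0.02, tn_fp = 0.22
                           )
                         ),
                         iou_range = c(0.4, 0.9)) {
  cfg <- structure(
    list(
      n_malignant = as.integer(n_malignant),
      n_normal = as.integer(n_normal),
      image_extent = as.integer(rep(image_extent, length.out = 2)),
      px_per_mm = px_per_mm,
      size_bin_probs = size_bin_probs,
      laterality_probs = laterality_probs,
      location_probs = location_probs,
      overlap_probs = overlap_probs,
      vendor_probs = vendor_probs,
      vendor_malignant_probs = vendor_malignant_probs,
      cad_sensitivity = cad_sensitivity,
      cad_fp_rate = cad_fp_rate,
      n_readers_per_group = as.integer(n_readers_per_group),
      baseline_sensitivity = baseline_sensitivity,
      baseline_specificity = baseline_specificity,
      reader_concentration = reader_concentration,
      switch_probs = switch_probs,
      iou_range = iou_range
    ),
    class = "study_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_dist <- function(p, name) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("%s must be a probability distribution", name), call. = FALSE)
    }
  }
  chk_dist(cfg$size_bin_probs, "size_bin_probs")
  chk_dist(cfg$laterality_probs, "laterality_probs")
  chk_dist(cfg$location_probs, "location_probs")
  chk_dist(cfg$overlap_probs, "overlap_probs")
  chk_dist(cfg$vendor_probs, "vendor_probs")
  chk_dist(cfg$vendor_malignant_probs, "vendor_malignant_probs")
  probs <- c(
    cfg$cad_sensitivity, cfg$baseline_specificity,
    cfg$baseline_sensitivity, unlist(cfg$switch_probs)
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$cad_fp_rate < 0) stop("cad_fp_rate must be non-negative", call. = FALSE)
  if (!identical(sort(names(cfg$switch_probs)), sort(names(cfg$baseline_sensitivity)))) {
    stop("switch_probs and baseline_sensitivity must name the same groups",
      call. = FALSE
    )
  }
  if (cfg$iou_range[1] <= 0 || cfg$iou_range[2] > 1 ||
    cfg$iou_range[1] > cfg$iou_range[2]) {
    stop("iou_range must satisfy 0 < lo <= hi <= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> %d malignant + %d normal images, %d+%d readers\n",
    x$n_malignant, x$n_normal, x$n_readers_per_group, x$n_readers_per_group
  ))
  cat(sprintf(
    "  CAD: sensitivity %.2f, FP rate %.3f/image; reader baselines: %s\n",
    x$cad_sensitivity, x$cad_fp_rate,
    paste(sprintf("%s %.2f", names(x$baseline_sensitivity), x$baseline_sensitivity),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Switch probabilities hitting a target post-CAD pooled sensitivity
#'
#' Under the generator's state-switching model with reader and CAD
#' detections conditionally independent given the image, the pooled
#' post-CAD sensitivity of group g is
#' `s_g (1 - q (1 - c)) + (1 - s_g) c f_g`, with `s_g` the group baseline
#' sensitivity, `c` the CAD sensitivity, `q` the TP-to-FN switch rate and
#' `f_g` the FN-to-TP switch rate. This helper inverts that relation: it
#' returns the config's `switch_probs` with each group's `fn_tp` replaced
#' so that the pooled post-arm sensitivity equals `target_post_sensitivity`
#' in expectation (other cells unchanged).
#'
#' This calibration exists because the published transition-table switch
#' rates and the published arm sensitivities are mutually consistent only
#' under the negative reader/CAD miss association of the real data, which
#' the conditional-independence generator deliberately does not model; see
#' the methods vignette.
#'
#' @param config A [study_config()].
#' @param target_post_sensitivity Desired pooled with-CAD sensitivity.
#' @return A `switch_probs` list to pass back into [study_config()].
#' @export
switch_probs_for_sensitivity <- function(config, target_post_sensitivity) {
  stopifnot(inherits(config, "study_config"))
  c_sens <- config$cad_sensitivity
  out <- config$switch_probs
  for (g in names(out)) {
    s_g <- config$baseline_sensitivity[[g]]
    q <- out[[g]][["tp_fn"]]
    f <- (target_post_sensitivity - s_g * (1 - q * (1 - c_sens))) /
      ((1 - s_g) * c_sens)
    if (f < 0 || f > 1) {
      stop(sprintf(
        "target sensitivity %.3f not reachable for group %s (needs fn_tp = %.3f)",
        target_post_sensitivity, g, f
      ), call. = FALSE)
    }
    out[[g]][["fn_tp"]] <- f
  }
  out
}

size_bin_of <- function(size_mm) {
  cut(size_mm,
    breaks = c(0, 10, 20, 30), labels = c("<=10", "11-20", "21-30"),
    right = TRUE
  ) |> as.character()
}

#' Generate ground-truth images and lesions
#'
#' Samples image labels, vendors and lesion attributes from the configured
#' distributions and places one lesion box per malignant image inside a
#' lung-field region of the synthetic radiograph: a lateral band for the
#' configured side, a vertical band for the configured location, away from
#' the image margin. Box sizes derive from the nodule diameter at the fixed
#' px/mm scale with a mild random aspect ratio (the diameter is the longest
#' side). Uses the current RNG state; seed via [simulate_study()] or
#' `set.seed()` for determinism.
#'
#' @param config A [study_config()].
#' @return A list with tibbles `images` (`image_id`, `label`, `vendor`) and
#'   `lesions` (`image_id`, box corners, `size_mm`, `size_bin`,
#'   `laterality`, `location`, `overlap_structure`).
#' @export
generate_truth <- function(config) {
  validate_config(config)
  n_mal <- config$n_malignant
  n_nor <- config$n_normal
  n <- n_mal + n_nor
  W <- config$image_extent[1]
  H <- config$image_extent[2]
  max_size_px <- 30 * config$px_per_mm
  if (max_size_px > 0.25 * min(W, H)) {
    stop("infeasible geometry: lesions larger than the lung field", call. = FALSE)
  }
  ids <- sprintf("img%04d", seq_len(n))
  label <- c(rep("malignant", n_mal), rep("normal", n_nor))
  vendor <- character(n)
  vn <- names(config$vendor_probs)
  if (n_mal > 0) {
    vendor[label == "malignant"] <- sample(vn, n_mal,
      replace = TRUE, prob = config$vendor_malignant_probs
    )
  }
  if (n_nor > 0) {
    # normal-image vendor mix chosen so the whole set follows vendor_probs
    p_nor <- config$vendor_probs * n - config$vendor_malignant_probs * n_mal
    p_nor <- pmax(p_nor, 0)
    vendor[label == "normal"] <- sample(vn, n_nor,
      replace = TRUE, prob = p_nor / sum(p_nor)
    )
  }
  images <- tibble::tibble(image_id = ids, label = label, vendor = vendor)
  if (n_mal == 0) {
    lesions <- tibble::tibble(
      image_id = character(), x_min = numeric(), y_min = numeric(),
      x_max = numeric(), y_max = numeric(), size_mm = numeric(),
      size_bin = character(), laterality = character(),
      location = character(), overlap_structure = character()
    )
    return(list(images = images, lesions = lesions))
  }
  bin <- sample(names(config$size_bin_probs), n_mal,
    replace = TRUE, prob = config$size_bin_probs
  )
  size_mm <- numeric(n_mal)
  size_mm[bin == "<=10"] <- stats::runif(sum(bin == "<=10"), 6, 10)
  size_mm[bin == "11-20"] <- stats::runif(sum(bin == "11-20"), 11, 20)
  size_mm[bin == "21-30"] <- stats::runif(sum(bin == "21-30"), 21, 30)
  laterality <- sample(names(config$laterality_probs), n_mal,
    replace = TRUE, prob = config$laterality_probs
  )
  location <- sample(names(config$location_probs), n_mal,
    replace = TRUE, prob = config$location_probs
  )
  overlap <- sample(names(config$overlap_probs), n_mal,
    replace = TRUE, prob = config$overlap_probs
  )
  long_px <- size_mm * config$px_per_mm
  aspect <- stats::runif(n_mal, 0.7, 1)
  horiz <- stats::runif(n_mal) < 0.5
  w <- ifelse(horiz, long_px, long_px * aspect)
  h <- ifelse(horiz, long_px * aspect, long_px)
  x_band <- rbind(
    right = c(0.15, 0.45), left = c(0.55, 0.85)
  )[laterality, , drop = FALSE]
  y_band <- rbind(
    upper = c(0.15, 0.38), middle = c(0.38, 0.62), lower = c(0.62, 0.80)
  )[location, , drop = FALSE]
  cx <- unname(x_band[, 1] + stats::runif(n_mal) * (x_band[, 2] - x_band[, 1])) * W
  cy <- unname(y_band[, 1] + stats::runif(n_mal) * (y_band[, 2] - y_band[, 1])) * H
  cx <- pmin(pmax(cx, w / 2 + 1), W - w / 2 - 1)
  cy <- pmin(pmax(cy, h / 2 + 1), H - h / 2 - 1)
  lesions <- tibble::tibble(
    image_id = ids[label == "malignant"],
    x_min = cx - w / 2, y_min = cy - h / 2,
    x_max = cx + w / 2, y_max = cy + h / 2,
    size_mm = size_mm, size_bin = size_bin_of(size_mm),
    laterality = laterality, location = location,
    overlap_structure = overlap
  )
  stopifnot(identical(lesions$size_bin, bin))
  list(images = images, lesions = lesions)
}

#' Perturb a box to a target IoU with itself
#'
#' Returns a box of the same size as `truth`, translated along a random
#' direction by the exact distance at which its IoU with `truth` equals
#' `target_iou`. For a translated copy the intersection area is
#' `(w - d|ux|)(h - d|uy|)` and the union `2wh` minus it, so the required
#' intersection is `2wh t/(1+t)` and the shift distance is the smaller
#' root of a quadratic — no search needed. Used to materialize detections
#' that pass (or probe) the IoU correctness judgment at a known overlap.
#'
#' @param truth A one-row box table.
#' @param target_iou Fraction in (0, 1]; the result's IoU with `truth`
#'   equals it up to floating-point error (well within the 0.05 envelope
#'   the generator guarantees).
#' @param max_tries Retries with fresh directions before giving up
#'   (directions can be numerically degenerate for extreme aspect ratios).
#' @return A one-row box table.
#' @export
perturbed_box <- function(truth, target_iou, max_tries = 20L) {
  stopifnot(nrow(truth) == 1L)
  validate_boxes(truth)
  if (!is.numeric(target_iou) || length(target_iou) != 1 ||
    target_iou <= 0 || target_iou > 1) {
    stop("target_iou must lie in (0, 1]", call. = FALSE)
  }
  co <- perturb_corners(
    c(truth$x_min, truth$y_min, truth$x_max, truth$y_max),
    target_iou, max_tries
  )
  tibble::tibble(x_min = co[1], y_min = co[2], x_max = co[3], y_max = co[4])
}

# --- fast numeric-core helpers (corner vectors c(x_min, y_min, x_max, y_max));
# --- the generators run thousands of box operations per study, so the hot
# --- path avoids data-frame construction entirely.

iou_corners <- function(a, b) {
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(ix, 0) * max(iy, 0)
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

perturb_corners <- function(co, target_iou, max_tries = 20L) {
  if (target_iou == 1) return(co)
  w <- co[3] - co[1]
  h <- co[4] - co[2]
  inter_star <- 2 * w * h * target_iou / (1 + target_iou)
  for (k in seq_len(max_tries)) {
    theta <- stats::runif(1, 0, 2 * pi)
    ux <- cos(theta)
    uy <- sin(theta)
    a <- abs(ux)
    b <- abs(uy)
    # (w - d a)(h - d b) = inter_star, smaller positive root
    qa <- a * b
    qb <- -(w * b + h * a)
    qc <- w * h - inter_star
    if (qa < 1e-12) {
      d <- -qc / qb
    } else {
      disc <- qb^2 - 4 * qa * qc # = (wb - ha)^2 + 4ab inter_star >= 0
      d <- (-qb - sqrt(disc)) / (2 * qa)
    }
    if (!is.finite(d) || d < 0 || d * a >= w || d * b >= h) next
    # shrink infinitesimally so rounding can never push the realized IoU
    # below the target (the threshold comparison is inclusive)
    d <- d * (1 - 1e-9)
    out <- co + d * c(ux, uy, ux, uy)
    if (abs(iou_corners(out, co) - target_iou) <= 0.05) return(out)
  }
  stop("could not reach target IoU after bounded retries", call. = FALSE)
}

fp_corners <- function(config, lesion_co = NULL, avoid_iou = 0.3,
                       max_tries = 100L) {
  W <- config$image_extent[1]
  H <- config$image_extent[2]
  for (k in seq_len(max_tries)) {
    size <- stats::runif(1, 8, 30) * config$px_per_mm
    asp <- stats::runif(1, 0.7, 1)
    w <- size
    h <- size * asp
    cx <- stats::runif(1, 0.12 * W + w / 2, 0.88 * W - w / 2)
    cy <- stats::runif(1, 0.12 * H + h / 2, 0.85 * H - h / 2)
    out <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    if (is.null(lesion_co) || iou_corners(out, lesion_co) < avoid_iou) {
      return(out)
    }
  }
  stop("could not place a false-positive box away from the lesion", call. = FALSE)
}

# A random box away from the lesion: false-positive mark on a synthetic
# radiograph. IoU below `avoid_iou` with `lesion` is enforced by rejection.
random_fp_box <- function(config, lesion = NULL, avoid_iou = 0.3,
                          max_tries = 100L) {
  lesion_co <- if (is.null(lesion) || nrow(lesion) == 0L) NULL else {
    c(lesion$x_min[1], lesion$y_min[1], lesion$x_max[1], lesion$y_max[1])
  }
  co <- fp_corners(config, lesion_co, avoid_iou, max_tries)
  tibble::tibble(x_min = co[1], y_min = co[2], x_max = co[3], y_max = co[4])
}

#' Generate CAD annotations for a truth set
#'
#' Each lesion is detected independently with probability
#' `cad_sensitivity`; a detection materializes as a [perturbed_box()] at a
#' target IoU drawn uniformly from `iou_range` (so it passes the 0.3
#' judgment by construction). False-positive marks are added per image with
#' Poisson(`cad_fp_rate`) counts, placed away from the lesion (IoU < 0.3
#' enforced).
#'
#' @param truth A list `images`/`lesions` from [generate_truth()].
#' @param config A [study_config()].
#' @return An annotation tibble (`source = "cad"`, `arm = "cad"`).
#' @export
generate_cad <- function(truth, config) {
  images <- truth$images
  lesions <- truth$lesions
  n_img <- nrow(images)
  lesion_row <- match(images$image_id, lesions$image_id)
  les_mat <- as.matrix(lesions[box_cols])
  detect <- stats::runif(n_img) < config$cad_sensitivity
  n_fp <- stats::rpois(n_img, config$cad_fp_rate)
  total <- sum(detect & !is.na(lesion_row)) + sum(n_fp)
  co <- matrix(NA_real_, total, 4L)
  ids <- character(total)
  k <- 0L
  for (i in seq_len(n_img)) {
    les_co <- if (is.na(lesion_row[i])) NULL else les_mat[lesion_row[i], ]
    if (!is.null(les_co) && detect[i]) {
      tgt <- stats::runif(1, config$iou_range[1], config$iou_range[2])
      k <- k + 1L
      co[k, ] <- perturb_corners(les_co, tgt)
      ids[k] <- images$image_id[i]
    }
    for (j in seq_len(n_fp[i])) {
      k <- k + 1L
      co[k, ] <- fp_corners(config, les_co)
      ids[k] <- images$image_id[i]
    }
  }
  tibble::tibble(
    source = "cad", reader_id = NA_character_, arm = "cad",
    image_id = ids[seq_len(k)],
    x_min = co[seq_len(k), 1], y_min = co[seq_len(k), 2],
    x_max = co[seq_len(k), 3], y_max = co[seq_len(k), 4]
  )
}

#' Generate reader sessions (pre- and post-CAD arms)
#'
#' Pre-CAD arm: each reader carries a baseline detection probability drawn
#' from a Beta distribution around the group mean (concentration
#' `reader_concentration`); a detected lesion materializes as a
#' [perturbed_box()] in `iou_range`, and each normal image receives one
#' false-positive box with probability `1 - baseline_specificity`.
#'
#' Post-CAD arm: decision switching conditioned on the CAD's case
#' correctness — exactly the structure the transition analysis measures.
#' For each image the realized (CAD state, pre state) pair is looked up in
#' the group's `switch_probs`; on a flip the boxes are materialized
#' accordingly (FN to TP adopts the CAD's matching box; TN to FP adopts a
#' CAD false-positive box; FP to TN and TP to FN delete the reader's
#' boxes). All other cases keep the pre-arm boxes.
#'
#' @param truth A list `images`/`lesions` from [generate_truth()].
#' @param cad CAD annotations from [generate_cad()].
#' @param config A [study_config()].
#' @param policy The [match_policy()] used to judge the CAD's case states.
#' @return A list with `readers` (tibble `reader_id`, `group`,
#'   `baseline_sensitivity`) and `annotations` (both arms of every reader).
#' @export
generate_readers <- function(truth, cad, config, policy = match_policy()) {
  images <- truth$images
  lesions <- truth$lesions
  n_img <- nrow(images)
  cad_out <- classify_study(images, lesions, cad, policy)
  cad_state <- cad_out$state[match(images$image_id, cad_out$image_id)]
  # one CAD box per image available for adoption (matching / false-positive)
  cad_tp_box <- matrix(NA_real_, n_img, 4L)
  cad_fp_box <- matrix(NA_real_, n_img, 4L)
  if (nrow(cad) > 0) {
    les_idx <- match(cad$image_id, lesions$image_id)
    img_idx <- match(cad$image_id, images$image_id)
    iou_with_lesion <- rep(NA_real_, nrow(cad))
    has <- !is.na(les_idx)
    if (any(has)) {
      iou_with_lesion[has] <- box_iou(
        cad[has, box_cols], lesions[les_idx[has], box_cols]
      )
    }
    cad_mat <- as.matrix(cad[box_cols])
    for (r in seq_len(nrow(cad))) {
      i <- img_idx[r]
      if (!is.na(iou_with_lesion[r]) && iou_with_lesion[r] >= policy$iou_threshold) {
        if (is.na(cad_tp_box[i, 1])) cad_tp_box[i, ] <- cad_mat[r, ]
      } else if (is.na(cad_fp_box[i, 1])) {
        cad_fp_box[i, ] <- cad_mat[r, ]
      }
    }
  }
  groups <- names(config$baseline_sensitivity)
  readers <- tibble::tibble(
    reader_id = unlist(lapply(groups, function(g) {
      sprintf("%s_%02d", abbreviate_group(g), seq_len(config$n_readers_per_group))
    })),
    group = rep(groups, each = config$n_readers_per_group)
  )
  kappa <- config$reader_concentration
  readers$baseline_sensitivity <- stats::rbeta(
    nrow(readers),
    shape1 = config$baseline_sensitivity[readers$group] * kappa,
    shape2 = (1 - config$baseline_sensitivity[readers$group]) * kappa
  )
  is_mal <- images$label == "malignant"
  lesion_row <- match(images$image_id, lesions$image_id)
  les_mat <- as.matrix(lesions[box_cols])
  ann <- vector("list", nrow(readers))
  for (r in seq_len(nrow(readers))) {
    p_det <- readers$baseline_sensitivity[r]
    sw <- config$switch_probs[[readers$group[r]]]
    pre_box <- matrix(NA_real_, n_img, 4L)
    pre_state <- character(n_img)
    u_pre <- stats::runif(n_img)
    for (i in seq_len(n_img)) {
      if (is_mal[i]) {
        if (u_pre[i] < p_det) {
          tgt <- stats::runif(1, config$iou_range[1], config$iou_range[2])
          pre_box[i, ] <- perturb_corners(les_mat[lesion_row[i], ], tgt)
          pre_state[i] <- "TP"
        } else {
          pre_state[i] <- "FN"
        }
      } else {
        if (u_pre[i] < 1 - config$baseline_specificity) {
          pre_box[i, ] <- fp_corners(config, NULL)
          pre_state[i] <- "FP"
        } else {
          pre_state[i] <- "TN"
        }
      }
    }
    post_box <- pre_box
    cell <- paste(cad_state, pre_state, sep = ">")
    p_flip <- rep(0, n_img)
    p_flip[cell == "TP>FN"] <- sw[["fn_tp"]]
    p_flip[cell == "TN>FP"] <- sw[["fp_tn"]]
    p_flip[cell == "FN>TP"] <- sw[["tp_fn"]]
    p_flip[cell == "FP>TN"] <- sw[["tn_fp"]]
    flip <- stats::runif(n_img) < p_flip
    post_box[flip & cell == "TP>FN", ] <- cad_tp_box[flip & cell == "TP>FN", ]
    post_box[flip & cell == "FN>TP", ] <- NA_real_ # TP -> FN: delete the box
    post_box[flip & cell == "TN>FP", ] <- NA_real_ # FP -> TN: delete the box
    post_box[flip & cell == "FP>TN", ] <- cad_fp_box[flip & cell == "FP>TN", ]
    pack <- function(bm, arm) {
      hasb <- !is.na(bm[, 1])
      if (!any(hasb)) return(NULL)
      tibble::tibble(
        source = "reader", reader_id = readers$reader_id[r], arm = arm,
        image_id = images$image_id[hasb],
        x_min = bm[hasb, 1], y_min = bm[hasb, 2],
        x_max = bm[hasb, 3], y_max = bm[hasb, 4]
      )
    }
    ann[[r]] <- dplyr::bind_rows(
      pack(pre_box, "pre_cad"), pack(post_box, "post_cad")
    )
  }
  list(readers = readers, annotations = dplyr::bind_rows(ann))
}

abbreviate_group <- function(g) {
  switch(g,
    general_physician = "gp",
    radiologist = "rad",
    gsub("[^a-z0-9]", "", tolower(g))
  )
}

#' Simulate a complete synthetic reader study
#'
#' Runs [generate_truth()], [generate_cad()] and [generate_readers()] under
#' one seed and packages the result as a `study_bundle`: images, lesions,
#' annotations (CAD plus every reader's two arms), the reader roster, and a
#' provenance manifest holding the seed and configuration. The same seed
#' and configuration always reproduce the identical bundle.
#'
#' @param config A [study_config()].
#' @param seed Integer seed recorded in the bundle's provenance.
#' @param policy The [match_policy()] the generator uses for the CAD's case
#'   states (and records in the manifest).
#' @return An object of class `study_bundle`.
#' @examples
#' b <- simulate_study(study_config(n_malignant = 5, n_normal = 10), seed = 1)
#' b
#' @export
simulate_study <- function(config = study_config(), seed,
                           policy = match_policy()) {
  stopifnot(!missing(seed))
  validate_config(config)
  set.seed(as.integer(seed))
  truth <- generate_truth(config)
  cad <- generate_cad(truth, config)
  rd <- generate_readers(truth, cad, config, policy)
  structure(
    list(
      manifest = list(
        name = "synthetic reader study",
        seed = as.integer(seed),
        iou_threshold = policy$iou_threshold,
        assignment = policy$assignment,
        box_dialect = "corners",
        config = unclass(config)
      ),
      images = truth$images,
      lesions = truth$lesions,
      annotations = dplyr::bind_rows(cad, rd$annotations),
      readers = rd$readers
    ),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "<study_bundle> %d images (%d malignant), %d readers, %d annotation rows\n",
    nrow(x$images), sum(x$images$label == "malignant"),
    nrow(x$readers), nrow(x$annotations)
  ))
  if (!is.null(x$manifest$seed)) {
    cat(sprintf("  seed %d, IoU threshold %g\n",
      x$manifest$seed, x$manifest$iou_threshold))
  }
  invisible(x)
}
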