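test_that("truth generation matches configured counts and respects invariants", {
  cfg <- study_config()
  set.seed(1)
  truth <- generate_truth(cfg)
  expect_equal(sum(truth$images$label == "malignant"), 59)
  expect_equal(sum(truth$images$label == "normal"), 253)
  expect_equal(nrow(truth$lesions), 59)
  # exactly one lesion per malignant image, none elsewhere
  expect_equal(sort(truth$lesions$image_id),
    sort(truth$images$image_id[truth$images$label == "malignant"]))
  # boxes live inside the image and size_bin is consistent with size_mm
  W <- cfg$image_extent[1]
  expect_true(all(truth$lesions$x_min >= 0 & truth$lesions$x_max <= W))
  expect_true(all(truth$lesions$size_mm <= 30))
  long_side <- pmax(
    truth$lesions$x_max - truth$lesions$x_min,
    truth$lesions$y_max - truth$lesions$y_min
  )
  expect_equal(long_side, truth$lesions$size_mm * cfg$px_per_mm)
  # infeasible geometry is rejected
  expect_error(generate_truth(study_config(image_extent = c(300, 300))),
    "infeasible")
})

test_that("size-bin frequencies over many seeds approach the configured mix", {
  cfg <- study_config()
  set.seed(17)
  bins <- character(0)
  for (r in 1:60) {
    truth <- generate_truth(cfg)
    bins <- c(bins, truth$lesions$size_bin)
  }
  freq <- table(factor(bins, levels = names(cfg$size_bin_probs))) / length(bins)
  # multinomial se at n = 3540 is ~0.008; allow 4 se
  expect_true(all(abs(as.numeric(freq) - cfg$size_bin_probs) < 0.035))
})

test_that("perturbed boxes hit their target IoU across the whole range", {
  set.seed(73)
  truth <- bbox(400, 500, 520, 610)
  targets <- runif(1000, 0.05, 1)
  for (t in targets) {
    got <- box_iou(perturbed_box(truth, t), truth)
    expect_lt(abs(got - t), 0.05)
  }
  expect_equal(perturbed_box(truth, 1), truth)
  # the 0.3 boundary passes the matching threshold
  set.seed(74)
  at_thr <- perturbed_box(truth, 0.3)
  m <- match_boxes(at_thr, truth, match_policy(0.3))
  expect_equal(nrow(m$matched_pairs), 1)
  expect_error(perturbed_box(truth, 0), "target_iou")
})

test_that("generated TP boxes pass and FP boxes fail the IoU judgment by construction", {
  cfg <- study_config()
  set.seed(21)
  truth <- generate_truth(cfg)
  cad <- generate_cad(truth, cfg)
  joined <- dplyr::inner_join(
    cad, truth$lesions[c("image_id", "x_min", "y_min", "x_max", "y_max")],
    by = "image_id", suffix = c("", "_les")
  )
  iou <- box_iou(
    joined[c("x_min", "y_min", "x_max", "y_max")],
    stats::setNames(
      joined[paste0(c("x_min", "y_min", "x_max", "y_max"), "_les")],
      c("x_min", "y_min", "x_max", "y_max")
    )
  )
  # every box on a malignant image either clears 0.4 (a detection) or
  # stays under 0.3 (a placed false positive)
  expect_true(all(iou >= 0.4 - 0.05 | iou < 0.3))
  # with the FP rate at zero, normal images carry no CAD boxes
  cfg0 <- study_config(cad_fp_rate = 0)
  set.seed(22)
  truth0 <- generate_truth(cfg0)
  cad0 <- generate_cad(truth0, cfg0)
  normals <- truth0$images$image_id[truth0$images$label == "normal"]
  expect_false(any(cad0$image_id %in% normals))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_config()
  b1 <- simulate_study(cfg, seed = 123)
  b2 <- simulate_study(cfg, seed = 123)
  expect_identical(b1, b2)
  b3 <- simulate_study(cfg, seed = 124)
  expect_false(identical(b1$annotations, b3$annotations))
})

test_that("zero switch probabilities leave the post arm identical to the pre arm", {
  zero <- list(
    general_physician = c(fn_tp = 0, fp_tn = 0, tp_fn = 0, tn_fp = 0),
    radiologist = c(fn_tp = 0, fp_tn = 0, tp_fn = 0, tn_fp = 0)
  )
  b <- simulate_study(study_config(switch_probs = zero), seed = 55)
  out <- classify_bundle(b)
  pre <- out[out$arm == "pre_cad", c("reader_id", "image_id", "state")]
  post <- out[out$arm == "post_cad", c("reader_id", "image_id", "state")]
  pre <- dplyr::arrange(pre, reader_id, image_id)
  post <- dplyr::arrange(post, reader_id, image_id)
  expect_identical(pre, post)
})

test_that("switch-probability calibration inverts the post-arm sensitivity formula", {
  cfg <- study_config()
  target <- 0.58
  sw <- switch_probs_for_sensitivity(cfg, target)
  for (g in names(sw)) {
    s <- cfg$baseline_sensitivity[[g]]
    q <- sw[[g]][["tp_fn"]]
    f <- sw[[g]][["fn_tp"]]
    post <- s * (1 - q * (1 - cfg$cad_sensitivity)) +
      (1 - s) * cfg$cad_sensitivity * f
    expect_equal(post, target, tolerance = 1e-12)
  }
  expect_error(switch_probs_for_sensitivity(cfg, 0.99), "not reachable")
})

test_that("the pipeline recovers the generator's configured probabilities", {
  # Monte-Carlo calibration of the full pipeline at the default study size
  cfg <- study_config()
  reps <- 40
  cad_sens <- pre_sens <- post_minus_pre <- gp_fn_tp <- numeric(reps)
  for (r in seq_len(reps)) {
    b <- simulate_study(cfg, seed = 9000 + r)
    out <- classify_bundle(b)
    mal <- out$label == "malignant"
    cad_sens[r] <- mean(out$state[out$source == "cad" & mal] == "TP")
    pre_sens[r] <- mean(out$state[out$arm == "pre_cad" & mal] == "TP")
    post_minus_pre[r] <- mean(out$state[out$arm == "post_cad" & mal] == "TP") -
      pre_sens[r]
    tr <- readercad:::transition_analysis_outcomes(out, b$readers)$rates
    gp <- tr[tr$group == "general_physician" & tr$cad_state == "TP" &
      tr$before_state == "FN", ]
    gp_fn_tp[r] <- gp$changed / (gp$changed + gp$unchanged)
  }
  mc <- function(x) sd(x) / sqrt(reps)
  # CAD standalone sensitivity ~ configured 0.66
  expect_lt(abs(mean(cad_sens) - cfg$cad_sensitivity), 4 * mc(cad_sens) + 1e-3)
  # pooled pre-arm sensitivity ~ mean of the group baselines (0.49)
  expect_lt(
    abs(mean(pre_sens) - mean(cfg$baseline_sensitivity)),
    4 * mc(pre_sens) + 1e-3
  )
  # the general-physician FN->TP switch rate ~ configured 0.59
  expect_lt(
    abs(mean(gp_fn_tp) - cfg$switch_probs$general_physician[["fn_tp"]]),
    4 * mc(gp_fn_tp) + 1e-3
  )
  # referencing the CAD raises pooled sensitivity in essentially every replicate
  expect_true(mean(post_minus_pre > 0) > 0.95)
})
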