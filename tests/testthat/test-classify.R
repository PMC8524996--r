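make_images <- function(n_mal, n_nor) {
  tibble::tibble(
    image_id = sprintf("img%03d", seq_len(n_mal + n_nor)),
    label = c(rep("malignant", n_mal), rep("normal", n_nor)),
    vendor = "V"
  )
}

make_lesions <- function(images) {
  mal <- images$image_id[images$label == "malignant"]
  n <- length(mal)
  tibble::tibble(
    image_id = mal,
    x_min = 100 + 300 * seq_len(n), y_min = 200,
    x_max = 180 + 300 * seq_len(n), y_max = 280,
    size_mm = 16, size_bin = "11-20", laterality = "right",
    location = "upper", overlap_structure = "none"
  )
}

test_that("case states follow the TP/FN/TN/FP definitions", {
  imgs <- make_images(1, 1)
  les <- make_lesions(imgs)
  mal <- imgs[1, ]
  nor <- imgs[2, ]
  lesion_box <- les[1, c("x_min", "y_min", "x_max", "y_max")]
  set.seed(5)
  good <- perturbed_box(lesion_box, 0.35)
  # malignant + one matching box -> TP, no FP lesions
  out <- classify_case(mal, good, lesion = lesion_box)
  expect_equal(out$state, "TP")
  expect_equal(out$fp_lesion_count, 0L)
  # malignant + two low-IoU boxes -> FN with 2 FP lesions
  bad <- dplyr::bind_rows(
    perturbed_box(lesion_box, 0.1), perturbed_box(lesion_box, 0.2)
  )
  out <- classify_case(mal, bad, lesion = lesion_box)
  expect_equal(out$state, "FN")
  expect_equal(out$fp_lesion_count, 2L)
  # normal image: no boxes -> TN; two boxes -> FP with both counted
  out <- classify_case(nor, NULL)
  expect_equal(out$state, "TN")
  expect_equal(out$fp_lesion_count, 0L)
  out <- classify_case(nor, bbox(c(0, 500), c(0, 500), c(50, 560), c(50, 560)))
  expect_equal(out$state, "FP")
  expect_equal(out$fp_lesion_count, 2L)
  # box with a foreign image id is rejected
  foreign <- dplyr::mutate(good, image_id = "elsewhere")
  expect_error(classify_case(mal, foreign, lesion = lesion_box), "elsewhere")
})

test_that("a TP case with extra non-matching boxes stays TP, extras count as FP lesions", {
  imgs <- make_images(1, 0)
  les <- make_lesions(imgs)
  lesion_box <- les[1, c("x_min", "y_min", "x_max", "y_max")]
  set.seed(9)
  boxes <- perturbed_box(lesion_box, 0.6)
  base <- classify_case(imgs[1, ], boxes, lesion = lesion_box)
  expect_equal(base$state, "TP")
  # metamorphic: adding a disjoint (IoU 0) box never changes the state,
  # only the FP lesion count
  boxes2 <- dplyr::bind_rows(boxes, bbox(1500, 1500, 1600, 1600))
  with_extra <- classify_case(imgs[1, ], boxes2, lesion = lesion_box)
  expect_equal(with_extra$state, "TP")
  expect_equal(with_extra$fp_lesion_count, base$fp_lesion_count + 1L)
})

test_that("classify_study handles empty and perfect annotation sets over 312 images", {
  imgs <- make_images(59, 253)
  les <- make_lesions(imgs)
  # no annotations: 253 TN + 59 FN
  out <- classify_study(imgs, les, NULL)
  expect_equal(sum(out$state == "TN"), 253)
  expect_equal(sum(out$state == "FN"), 59)
  expect_equal(mfpi(out), 0)
  # perfect reader: annotations equal to the truth boxes
  perfect <- les[c("image_id", "x_min", "y_min", "x_max", "y_max")]
  out <- classify_study(imgs, les, perfect)
  expect_equal(sum(out$state == "TP"), 59)
  expect_equal(sum(out$state == "TN"), 253)
  expect_equal(out$matched_iou[out$state == "TP"], rep(1, 59))
  # unknown image id is reported
  stray <- dplyr::mutate(perfect[1, ], image_id = "nope")
  expect_error(classify_study(imgs, les, stray), "nope")
})

test_that("state depends only on the matched partition; counts are conserved per arm", {
  set.seed(31)
  b <- simulate_study(small_config(), seed = 404)
  out <- classify_bundle(b)
  n_mal <- sum(b$images$label == "malignant")
  n_nor <- sum(b$images$label == "normal")
  tallies <- out |>
    dplyr::group_by(source, reader_id, arm) |>
    dplyr::summarise(
      pos = sum(state %in% c("TP", "FN")),
      neg = sum(state %in% c("TN", "FP")),
      mal_ok = all((state %in% c("TP", "FN")) == (label == "malignant")),
      tn_zero = all(fp_lesion_count[state == "TN"] == 0),
      fp_pos = all(fp_lesion_count[state == "FP"] >= 1),
      .groups = "drop"
    )
  expect_true(all(tallies$pos == n_mal))
  expect_true(all(tallies$neg == n_nor))
  expect_true(all(tallies$mal_ok))
  expect_true(all(tallies$tn_zero))
  expect_true(all(tallies$fp_pos))
})

test_that("mFPI is the FP-lesion total over all images and behaves under permutation/concatenation", {
  out <- tibble::tibble(
    image_id = sprintf("i%03d", 1:312),
    state = c(rep("FP", 10), rep("TN", 243), rep("TP", 39), rep("FN", 20)),
    fp_lesion_count = c(rep(1L, 10), rep(0L, 243), c(rep(2L, 3), rep(0L, 36)), rep(0L, 20))
  )
  expect_equal(sum(out$fp_lesion_count), 16)
  expect_equal(mfpi(out), 16 / 312)
  set.seed(13)
  expect_equal(mfpi(out[sample(nrow(out)), ]), mfpi(out))
  # concatenation: pooled mFPI is the size-weighted average
  a <- out[1:100, ]
  b <- out[101:312, ]
  expect_equal(
    mfpi(out),
    (mfpi(a) * nrow(a) + mfpi(b) * nrow(b)) / (nrow(a) + nrow(b))
  )
  expect_error(mfpi(out[0, ]), "empty")
})

test_that("classified CAD sensitivity tracks the configured detection rate", {
  # Monte-Carlo over replicated truth + CAD generation, classified
  # end-to-end through IoU matching
  cfg <- study_config()
  reps <- 200
  sens <- numeric(reps)
  set.seed(607)
  for (r in seq_len(reps)) {
    truth <- generate_truth(cfg)
    cad <- generate_cad(truth, cfg)
    out <- classify_study(truth$images, truth$lesions, cad)
    sens[r] <- mean(out$state[out$label == "malignant"] == "TP")
  }
  mc_se <- sd(sens) / sqrt(reps)
  expect_lt(abs(mean(sens) - cfg$cad_sensitivity), 4 * mc_se + 1e-3)
})
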