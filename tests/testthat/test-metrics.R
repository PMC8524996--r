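test_that("confusion tallies states exactly and matches a brute-force recount", {
  out <- tibble::tibble(
    state = c(rep("TP", 59), rep("TN", 253))
  )
  cc <- confusion(out)
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
    list(tp = 59L, fn = 0L, tn = 253L, fp = 0L),
    ignore_attr = TRUE
  )
  set.seed(77)
  mixed <- tibble::tibble(
    state = sample(c("TP", "FN", "TN", "FP"), 500, replace = TRUE)
  )
  cc <- confusion(mixed)
  recount <- table(factor(mixed$state, levels = c("TP", "FN", "TN", "FP")))
  expect_equal(
    c(cc$tp, cc$fn, cc$tn, cc$fp),
    as.integer(recount)
  )
  expect_equal(cc$tp + cc$fn + cc$tn + cc$fp, nrow(mixed))
})

test_that("the five metric formulas evaluate correctly, with undefined flags", {
  ms <- metric_set(list(tp = 39, fn = 20, tn = 243, fp = 10))
  expect_equal(ms$sensitivity, 39 / 59)
  expect_equal(ms$specificity, 243 / 253)
  expect_equal(ms$accuracy, 282 / 312)
  expect_equal(ms$ppv, 39 / 49)
  expect_equal(ms$npv, 243 / 263)
  expect_equal(round_half_up(ms$sensitivity, 3), 0.661)
  expect_equal(round_half_up(ms$specificity, 3), 0.960)
  expect_equal(round_half_up(ms$accuracy, 3), 0.904)
  expect_equal(round_half_up(ms$ppv, 3), 0.796)
  expect_equal(round_half_up(ms$npv, 3), 0.924)
  # zero denominators flag, not zero
  ms <- metric_set(list(tp = 0, fn = 0, tn = 10, fp = 0))
  expect_true(is.na(ms$sensitivity))
  expect_true(is.na(ms$ppv))
  expect_equal(ms$specificity, 1)
  # all-correct
  ms <- metric_set(list(tp = 5, fn = 0, tn = 7, fp = 0))
  expect_equal(
    c(ms$sensitivity, ms$specificity, ms$accuracy, ms$ppv, ms$npv),
    rep(1, 5)
  )
  expect_error(metric_set(list(tp = 0, fn = 0, tn = 0, fp = 0)), "zero cases")
})

test_that("accuracy identity holds on random outcome lists", {
  set.seed(123)
  for (rep in 1:25) {
    out <- tibble::tibble(
      state = sample(c("TP", "FN", "TN", "FP"), sample(5:100, 1), replace = TRUE)
    )
    cc <- confusion(out)
    ms <- metric_set(cc)
    expect_equal(ms$accuracy, (cc$tp + cc$tn) / nrow(out))
  }
})

test_that("pooling sums confusion counts across readers (micro-average)", {
  set.seed(42)
  b <- simulate_study(small_config(), seed = 77)
  out <- classify_bundle(b)
  reader_out <- out[out$source == "reader", ]
  pm <- pooled_metrics(reader_out, b$readers[c("reader_id", "group")])
  # pooled counts equal summed per-reader counts: check sensitivity of one group
  g <- "general_physician"
  ids <- b$readers$reader_id[b$readers$group == g]
  sub <- reader_out[reader_out$reader_id %in% ids & reader_out$arm == "pre_cad", ]
  cc <- confusion(sub)
  expect_equal(
    pm$pooled$sensitivity[pm$pooled$group == g & pm$pooled$arm == "pre_cad"],
    cc$tp / (cc$tp + cc$fn)
  )
  # two identical readers pool to each reader's own metrics
  one <- reader_out[reader_out$reader_id == ids[1], ]
  two <- dplyr::mutate(one, reader_id = "copy")
  both <- dplyr::bind_rows(one, two)
  pm2 <- pooled_metrics(
    both, tibble::tibble(reader_id = c(ids[1], "copy"), group = "g")
  )
  per <- pm2$per_reader[pm2$per_reader$arm == "pre_cad", ]
  pooled <- pm2$pooled[pm2$pooled$group == "g" & pm2$pooled$arm == "pre_cad", ]
  expect_equal(pooled$sensitivity, per$sensitivity[1])
  expect_equal(pooled$accuracy, per$accuracy[1])
  # mismatched image sets are rejected
  broken <- dplyr::bind_rows(one, two[-1, ])
  expect_error(
    pooled_metrics(broken, tibble::tibble(
      reader_id = c(ids[1], "copy"), group = "g"
    )),
    "same image set"
  )
})

test_that("naive ratio report divides panels and rounds half-up to two decimals", {
  pre <- study_table2_overall$pre
  post <- study_table2_overall$post
  rr <- ratio_report(pre, post)
  expect_equal(rr$ratio[rr$metric == "sensitivity"], 1.22)
  expect_equal(rr$ratio[rr$metric == "accuracy"], 1.03)
  expect_equal(rr$ratio[rr$metric == "npv"], 1.02)
  # identical arms give 1.00 everywhere
  rr <- ratio_report(pre, pre)
  expect_equal(rr$ratio, rep(1, 5))
  # undefined metrics propagate
  pre2 <- pre
  pre2$ppv <- NA_real_
  rr <- ratio_report(pre2, post)
  expect_true(is.na(rr$ratio[rr$metric == "ppv"]))
  expect_false(anyNA(rr$ratio[rr$metric != "ppv"]))
})

test_that("the eligibility cascade conserves candidates and orders exclusions", {
  cand <- tibble::tibble(
    is_metastasis = c(rep(TRUE, 8), rep(FALSE, 114)),
    size_mm = c(rep(20, 8), rep(35, 44), rep(20, 70)),
    is_nodular = c(rep(TRUE, 52), rep(FALSE, 4), rep(TRUE, 66)),
    visible_on_radiograph = c(rep(TRUE, 56), rep(FALSE, 7), rep(TRUE, 59))
  )
  res <- eligibility_filter(cand)
  expect_equal(res$report$collected, 122)
  expect_equal(res$report$excluded_metastasis, 8)
  expect_equal(res$report$excluded_over_30mm, 44)
  expect_equal(res$report$excluded_non_nodular, 4)
  expect_equal(res$report$excluded_not_visible, 7)
  expect_equal(res$report$remaining, 59)
  expect_equal(nrow(res$retained), 59)
  # conservation
  with(res$report, expect_equal(
    collected,
    excluded_metastasis + excluded_over_30mm + excluded_non_nodular +
      excluded_not_visible + remaining
  ))
  # a candidate failing several criteria counts once, at the first stage
  multi <- tibble::tibble(
    is_metastasis = TRUE, size_mm = 40, is_nodular = FALSE,
    visible_on_radiograph = FALSE
  )
  res <- eligibility_filter(multi)
  expect_equal(res$report$excluded_metastasis, 1)
  expect_equal(res$report$excluded_over_30mm, 0)
  # a 35 mm mass is excluded at the size stage
  res <- eligibility_filter(tibble::tibble(
    is_metastasis = FALSE, size_mm = 35, is_nodular = TRUE,
    visible_on_radiograph = TRUE
  ))
  expect_equal(res$report$excluded_over_30mm, 1)
  # empty input: all zero
  res <- eligibility_filter(cand[0, ])
  expect_equal(res$report$collected, 0)
  expect_equal(res$report$remaining, 0)
  # missing attributes are a validation error
  expect_error(eligibility_filter(cand[, -2]), "size_mm")
})

test_that("cohort summary reproduces bin percentages and vendor fractions", {
  images <- tibble::tibble(
    image_id = sprintf("i%03d", 1:312),
    label = c(rep("malignant", 59), rep("normal", 253)),
    vendor = c(
      rep("FUJIFILM", 6), rep("KONICA", 31), rep("Philips", 22), # malignant
      rep("FUJIFILM", 83), rep("KONICA", 82), rep("Philips", 88) # normal
    )
  )
  lesions <- tibble::tibble(
    image_id = images$image_id[1:59],
    size_mm = c(rep(8, 7), rep(15, 33), rep(25, 19)),
    size_bin = c(rep("<=10", 7), rep("11-20", 33), rep("21-30", 19)),
    laterality = c(rep("right", 39), rep("left", 20)),
    location = c(rep("upper", 23), rep("middle", 31), rep("lower", 5)),
    overlap_structure = c(
      rep("heart", 2), rep("clavicle", 6), rep("diaphragm", 1),
      rep("hilar_vessels", 3), rep("none", 47)
    )
  )
  cs <- cohort_summary(images, lesions)
  expect_equal(cs$size_bin$n, c(7, 33, 19))
  expect_equal(cs$size_bin$pct, c(12, 56, 32))
  expect_equal(cs$laterality$pct, c(66, 34))
  expect_equal(cs$location$pct, c(39, 53, 8))
  expect_equal(
    cs$vendor$pct_malignant[cs$vendor$vendor == "FUJIFILM"], 7
  )
  expect_equal(
    cs$vendor$pct_malignant[cs$vendor$vendor == "KONICA"], 27
  )
  expect_equal(
    cs$vendor$pct_malignant[cs$vendor$vendor == "Philips"], 20
  )
  # percentages over an attribute sum to 100 +/- 1 (integer rounding slack)
  for (tab in cs[c("size_bin", "laterality", "location", "overlap")]) {
    expect_lte(abs(sum(tab$pct) - 100), 1)
  }
  # empty cohort: zero counts, no percentages
  cs0 <- cohort_summary(images[0, ], lesions[0, ])
  expect_equal(cs0$size_bin$n, c(0, 0, 0))
  expect_true(all(is.na(cs0$size_bin$pct)))
})
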