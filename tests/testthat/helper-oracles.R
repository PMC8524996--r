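`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across the suite. These deliberately use
# different algorithms from the package code paths they check.

# IoU by lattice rasterization: overlay an n-by-n grid of cell centers on
# [lo, hi]^2 and count covered cells. The per-axis center counts are
# computed arithmetically (the lattice is regular), which keeps the oracle
# exact for any n without materializing the grid.
raster_iou <- function(a, b, lo, hi, n) {
  h <- (hi - lo) / n
  count1d <- function(mn, mx) {
    # centers at lo + (k + 0.5) h for k = 0 .. n-1; count those in [mn, mx]
    kmin <- max(ceiling((mn - lo) / h - 0.5), 0)
    kmax <- min(floor((mx - lo) / h - 0.5), n - 1)
    max(0, kmax - kmin + 1)
  }
  cells <- function(box) {
    count1d(box$x_min, box$x_max) * count1d(box$y_min, box$y_max)
  }
  ixl <- max(a$x_min, b$x_min)
  ixu <- min(a$x_max, b$x_max)
  iyl <- max(a$y_min, b$y_min)
  iyu <- min(a$y_max, b$y_max)
  inter <- if (ixl < ixu && iyl < iyu) count1d(ixl, ixu) * count1d(iyl, iyu) else 0
  union <- cells(a) + cells(b) - inter
  inter / union
}

# random valid boxes in [lo, hi]^2 with side lengths in [min_side, max_side]
random_boxes <- function(n, lo = 0, hi = 100, min_side = 5, max_side = 40) {
  w <- runif(n, min_side, max_side)
  h <- runif(n, min_side, max_side)
  x <- runif(n, lo, hi - w)
  y <- runif(n, lo, hi - h)
  bbox(x, y, x + w, y + h)
}

# brute-force one-to-one matcher: enumerates every assignment of
# annotations to lesions with all pairs above threshold; returns the best
# (max pair count, then max total IoU)
brute_force_match <- function(iou, thr) {
  na <- nrow(iou)
  nl <- ncol(iou)
  best <- list(count = 0L, total = 0)
  recurse <- function(a, used_l, count, total) {
    if (a > na) {
      if (count > best$count ||
        (count == best$count && total > best$total + 1e-12)) {
        best <<- list(count = count, total = total)
      }
      return(invisible(NULL))
    }
    recurse(a + 1L, used_l, count, total)
    for (l in seq_len(nl)) {
      if (!(l %in% used_l) && iou[a, l] >= thr) {
        recurse(a + 1L, c(used_l, l), count + 1L, total + iou[a, l])
      }
    }
  }
  recurse(1L, integer(0), 0L, 0)
  best
}

# clustered two-arm binary data with exchangeable within-cluster
# correlation `a^2` built by a shared-component mixture: each observation
# copies a cluster-level draw with probability `a`, else is independent.
# Marginal P(y = 1 | arm) is exactly p0 / p1.
gen_clustered_binary <- function(n_clusters, n_per_arm, p0, p1, a = sqrt(0.2)) {
  rows <- lapply(seq_len(n_clusters), function(i) {
    u <- runif(1)
    arm <- rep(c(0L, 1L), each = n_per_arm)
    p <- ifelse(arm == 1L, p1, p0)
    common <- as.integer(u < p)
    use_common <- runif(length(arm)) < a
    y <- ifelse(use_common, common, as.integer(runif(length(arm)) < p))
    tibble::tibble(
      reader_id = sprintf("cl%03d", i),
      image_id = seq_along(arm),
      arm = arm, y = y
    )
  })
  dplyr::bind_rows(rows)
}

# resample until neither arm is degenerate (all 0 / all 1)
gen_clustered_nondegenerate <- function(n_clusters, n_per_arm, p0, p1,
                                        a = sqrt(0.2), max_tries = 50) {
  for (k in seq_len(max_tries)) {
    d <- gen_clustered_binary(n_clusters, n_per_arm, p0, p1, a)
    m <- tapply(d$y, d$arm, mean)
    if (all(m > 0 & m < 1)) return(d)
  }
  stop("could not generate non-degenerate data")
}

# a tiny complete study for fast unit tests
small_config <- function(...) {
  study_config(
    n_malignant = 12L, n_normal = 30L, n_readers_per_group = 2L, ...
  )
}

# Table 1/2/3 values of the emulated study, used by several tests
study_table2_overall <- list(
  pre = list(
    sensitivity = 0.49, specificity = 0.96, accuracy = 0.87,
    ppv = 0.75, npv = 0.89
  ),
  post = list(
    sensitivity = 0.60, specificity = 0.97, accuracy = 0.90,
    ppv = 0.81, npv = 0.91
  )
)

# group-total transition counts (changed, unchanged) per tracked cell
study_table3_totals <- list(
  general_physician = c(
    cadTP_FN_c = 68, cadTP_FN_u = 48, cadTN_FP_c = 29, cadTN_FP_u = 52,
    cadFN_TP_c = 0, cadFN_TP_u = 16, cadFP_TN_c = 14, cadFP_TN_u = 81
  ),
  radiologist = c(
    cadTP_FN_c = 49, cadTP_FN_u = 52, cadTN_FP_c = 24, cadTN_FP_u = 58,
    cadFN_TP_c = 1, cadFN_TP_u = 20, cadFP_TN_c = 21, cadFP_TN_u = 74
  )
)

# wrap group totals as transition_table objects for switch_rates()
table3_as_tables <- function() {
  lapply(names(study_table3_totals), function(g) {
    v <- study_table3_totals[[g]]
    structure(
      list(
        reader_id = g,
        cells = tibble::tibble(
          cad_state = c("TP", "TN", "FN", "FP"),
          before_state = c("FN", "FP", "TP", "TN"),
          changed = as.integer(v[c(1, 3, 5, 7)]),
          unchanged = as.integer(v[c(2, 4, 6, 8)])
        ),
        concordant = NA_integer_,
        n_images = NA_integer_
      ),
      class = "transition_table"
    )
  })
}
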