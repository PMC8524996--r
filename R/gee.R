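#' Build clustered binary outcome records for one metric
#'
#' Converts per-case reader outcomes into the record layout the marginal
#' model consumes: one row per (reader, arm, eligible case) with a binary
#' "correct" indicator. The eligible subset and coding depend on the
#' metric:
#'
#' * `sensitivity` — malignant cases; y = 1 iff TP,
#' * `specificity` — normal cases; y = 1 iff TN,
#' * `accuracy` — all cases; y = 1 iff TP or TN,
#' * `ppv` — cases the reader called positive (at least one box) in that
#'   arm; y = 1 iff TP,
#' * `npv` — cases called negative in that arm; y = 1 iff TN.
#'
#' Note that for PPV/NPV the eligible subset differs between arms, because
#' referring to the CAD changes which cases a reader calls positive.
#'
#' @param outcomes Reader case outcomes: tibble with `reader_id`, `arm`
#'   (`"pre_cad"`/`"post_cad"`), `image_id`, `state`, `fp_lesion_count`.
#' @param metric One of `"sensitivity"`, `"specificity"`, `"accuracy"`,
#'   `"ppv"`, `"npv"`.
#' @return A tibble `reader_id`, `image_id`, `arm` (0 = without CAD,
#'   1 = with CAD), `y`.
#' @export
build_outcome_records <- function(outcomes,
                                  metric = c(
                                    "sensitivity", "specificity",
                                    "accuracy", "ppv", "npv"
                                  )) {
  metric <- match.arg(metric)
  stopifnot(all(c("reader_id", "arm", "image_id", "state") %in% names(outcomes)))
  df <- outcomes[outcomes$arm %in% c("pre_cad", "post_cad"), ]
  called_positive <- df$state %in% c("TP", "FP") | df$fp_lesion_count > 0
  keep <- switch(metric,
    sensitivity = df$state %in% c("TP", "FN"),
    specificity = df$state %in% c("TN", "FP"),
    accuracy = rep(TRUE, nrow(df)),
    ppv = called_positive,
    npv = !called_positive
  )
  df <- df[keep, ]
  for (a in c("pre_cad", "post_cad")) {
    if (!any(df$arm == a)) {
      stop(sprintf("metric %s has an empty case subset in arm %s", metric, a),
        call. = FALSE
      )
    }
  }
  y <- switch(metric,
    sensitivity = as.integer(df$state == "TP"),
    specificity = as.integer(df$state == "TN"),
    accuracy = as.integer(df$state %in% c("TP", "TN")),
    ppv = as.integer(df$state == "TP"),
    npv = as.integer(df$state == "TN")
  )
  tibble::tibble(
    reader_id = df$reader_id,
    image_id = df$image_id,
    arm = as.integer(df$arm == "post_cad"),
    y = y
  )
}

#' Specification of the marginal model fit
#'
#' The mean model is fixed: `log mu = beta0 + beta1 * arm` with binary
#' variance `mu (1 - mu)`, so `exp(beta1)` is the with-CAD / without-CAD
#' ratio of the metric. The working correlation and the clustering unit are
#' configurable; robust (sandwich) standard errors keep inference valid if
#' the working correlation is misspecified.
#'
#' @param working_correlation `"exchangeable"` (default) or
#'   `"independence"`.
#' @param cluster_by `"reader"` (default: every case outcome of one reader,
#'   both arms, forms one cluster) or `"reader_image"` (the two arms of one
#'   reader-image pair form one cluster).
#' @param max_iterations Fisher-scoring iteration cap (default 100).
#' @param tolerance Relative change in coefficients declaring convergence
#'   (default 1e-8).
#' @return An object of class `gee_spec`.
#' @export
gee_spec <- function(working_correlation = c("exchangeable", "independence"),
                     cluster_by = c("reader", "reader_image"),
                     max_iterations = 100L, tolerance = 1e-8) {
  stopifnot(tolerance > 0, max_iterations >= 1)
  structure(
    list(
      working_correlation = match.arg(working_correlation),
      cluster_by = match.arg(cluster_by),
      max_iterations = as.integer(max_iterations),
      tolerance = tolerance
    ),
    class = "gee_spec"
  )
}

#' Fit the log-link marginal model by generalized estimating equations
#'
#' Solves the estimating equations
#' \deqn{\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0}
#' for the mean model \eqn{\log \mu = \beta_0 + \beta_1 \cdot arm} by
#' iteratively reweighted Fisher scoring, with \eqn{V_i} built from binary
#' variance \eqn{\mu(1-\mu)} and the working correlation (exchangeable
#' \eqn{\alpha} re-estimated each iteration by the moment estimator on
#' standardized residual cross-products). The covariance of
#' \eqn{\hat\beta} is the sandwich \eqn{A^{-1} B A^{-1}}. Fitted means are
#' clamped to `(1e-10, 1 - 1e-10)` during iteration, as the log link does
#' not constrain them.
#'
#' @param records Output of [build_outcome_records()]: tibble with
#'   `reader_id`, `image_id`, `arm` (0/1) and `y` (0/1).
#' @param spec A [gee_spec()].
#' @return An object of class `gee_fit` with elements `beta` (length 2, log
#'   scale), `robust_cov`, `model_cov`, `ratio` (`exp(beta[2])`),
#'   `ci_lower`, `ci_upper`, `p_value` (two-sided Wald at the 5% two-sided
#'   level the CI matches), `alpha_hat`, `converged`, `n_iter`,
#'   `n_clusters`, `n_obs` and the `spec`.
#' @examples
#' rec <- tibble::tibble(
#'   reader_id = rep(c("a", "b"), each = 8),
#'   image_id = rep(1:8, 2),
#'   arm = rep(c(0L, 1L), 8),
#'   y = rep(c(0L, 1L, 1L, 1L), 4)
#' )
#' fit_gee(rec, gee_spec("independence"))
#' @export
fit_gee <- function(records, spec = gee_spec()) {
  stopifnot(inherits(spec, "gee_spec"))
  stopifnot(all(c("reader_id", "arm", "y") %in% names(records)))
  y <- as.numeric(records$y)
  arm <- as.numeric(records$arm)
  if (!all(y %in% c(0, 1)) || !all(arm %in% c(0, 1))) {
    stop("y and arm must be binary 0/1", call. = FALSE)
  }
  if (!any(arm == 0) || !any(arm == 1)) {
    stop("both arm values must be present", call. = FALSE)
  }
  for (a in c(0, 1)) {
    m <- mean(y[arm == a])
    if (m == 0 || m == 1) {
      stop(sprintf(
        "outcome is all-%d in arm %d: ratio not estimable (separation)",
        as.integer(m), as.integer(a)
      ), call. = FALSE)
    }
  }
  cluster <- switch(spec$cluster_by,
    reader = as.character(records$reader_id),
    reader_image = paste(records$reader_id, records$image_id, sep = "\r")
  )
  cl <- split(seq_along(y), cluster)
  if (length(cl) < 2) stop("need at least 2 clusters", call. = FALSE)
  X <- cbind(1, arm)
  p <- 2L
  eps <- 1e-10
  beta <- c(log(mean(y[arm == 0])), log(mean(y[arm == 1]) / mean(y[arm == 0])))
  alpha <- 0
  exch <- spec$working_correlation == "exchangeable"
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(spec$max_iterations)) {
    eta <- as.vector(X %*% beta)
    mu <- pmin(pmax(exp(eta), eps), 1 - eps)
    s <- sqrt(mu * (1 - mu))
    r_std <- (y - mu) / s
    if (exch) alpha <- exch_alpha(r_std, cl, p)
    A <- matrix(0, p, p)
    g <- numeric(p)
    for (idx in cl) {
      n_i <- length(idx)
      # D_i = dmu/dbeta = mu * x (log link); work with the standardized
      # design Ds = diag(1/s) D so that V^-1 D = diag(1/s) R^-1 Ds
      Ds <- (mu[idx] / s[idx]) * X[idx, , drop = FALSE]
      rs <- r_std[idx]
      if (exch && n_i > 1) {
        c_i <- alpha / (1 + (n_i - 1) * alpha)
        RiD <- (Ds - c_i * matrix(colSums(Ds), n_i, p, byrow = TRUE)) / (1 - alpha)
        Rir <- (rs - c_i * sum(rs)) / (1 - alpha)
      } else {
        RiD <- Ds
        Rir <- rs
      }
      A <- A + crossprod(Ds, RiD)
      g <- g + crossprod(Ds, Rir)[, 1]
    }
    delta <- solve(A, g)
    beta_new <- beta + delta
    rel <- max(abs(delta)) / max(1, max(abs(beta_new)))
    beta <- beta_new
    if (rel < spec$tolerance) {
      converged <- TRUE
      break
    }
  }
  # sandwich at the solution
  eta <- as.vector(X %*% beta)
  mu <- pmin(pmax(exp(eta), eps), 1 - eps)
  s <- sqrt(mu * (1 - mu))
  r_std <- (y - mu) / s
  if (exch) alpha <- exch_alpha(r_std, cl, p)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (idx in cl) {
    n_i <- length(idx)
    Ds <- (mu[idx] / s[idx]) * X[idx, , drop = FALSE]
    rs <- r_std[idx]
    if (exch && n_i > 1) {
      c_i <- alpha / (1 + (n_i - 1) * alpha)
      RiD <- (Ds - c_i * matrix(colSums(Ds), n_i, p, byrow = TRUE)) / (1 - alpha)
      Rir <- (rs - c_i * sum(rs)) / (1 - alpha)
    } else {
      RiD <- Ds
      Rir <- rs
    }
    A <- A + crossprod(Ds, RiD)
    u_i <- crossprod(Ds, Rir)[, 1]
    B <- B + tcrossprod(u_i)
  }
  A_inv <- solve(A)
  robust <- A_inv %*% B %*% A_inv
  robust <- (robust + t(robust)) / 2
  se <- sqrt(robust[2, 2])
  b1 <- unname(beta[2])
  z <- b1 / se
  fit <- structure(
    list(
      beta = stats::setNames(beta, c("(Intercept)", "arm")),
      robust_cov = robust,
      model_cov = A_inv,
      ratio = exp(b1),
      ci_lower = exp(b1 - stats::qnorm(0.975) * se),
      ci_upper = exp(b1 + stats::qnorm(0.975) * se),
      p_value = 2 * stats::pnorm(-abs(z)),
      alpha_hat = if (exch) alpha else NA_real_,
      converged = converged,
      n_iter = iter,
      n_clusters = length(cl),
      n_obs = length(y),
      spec = spec
    ),
    class = "gee_fit"
  )
  if (!converged) {
    warning("GEE did not converge within max_iterations", call. = FALSE)
  }
  fit
}

# moment estimator of the exchangeable correlation: average standardized
# residual cross-product over within-cluster pairs, with the usual p
# degrees-of-freedom correction; phi is fixed at 1 (binary variance).
exch_alpha <- function(r_std, cl, p) {
  num <- 0
  n_pairs <- 0
  for (idx in cl) {
    n_i <- length(idx)
    if (n_i < 2) next
    s_i <- sum(r_std[idx])
    num <- num + (s_i^2 - sum(r_std[idx]^2)) / 2
    n_pairs <- n_pairs + n_i * (n_i - 1) / 2
  }
  if (n_pairs <= p) return(0)
  a <- num / (n_pairs - p)
  max_n <- max(lengths(cl))
  # keep R(alpha) positive definite
  min(max(a, -1 / (max_n - 1) + 1e-6), 1 - 1e-6)
}

#' @export
print.gee_fit <- function(x, ...) {
  ci <- ratio_ci(x)
  cat(sprintf(
    "<gee_fit> log-link GEE, %s working correlation, %d clusters, %d obs\n",
    x$spec$working_correlation, x$n_clusters, x$n_obs
  ))
  cat(sprintf(
    "  ratio %.3f  95%% CI (%.3f, %.3f)  p %s\n",
    ci$ratio, ci$lower, ci$upper, ci$p_display
  ))
  if (!is.na(x$alpha_hat)) cat(sprintf("  alpha_hat %.3f\n", x$alpha_hat))
  invisible(x)
}

#' Ratio, Wald confidence interval and p-value of a fit
#'
#' The 95% interval is `exp(beta1 -/+ 1.959964 * se)` with `se` the robust
#' standard error; the p-value is the two-sided normal tail of `beta1/se`.
#' For display, values round half-up to two decimals and p-values below
#' 0.001 render as `"< 0.001"`.
#'
#' @param fit A [fit_gee()] result (must have converged).
#' @return A list with `ratio`, `lower`, `upper`, `p_value`, `p_display`
#'   and `degenerate` (`TRUE` when the robust se is zero).
#' @export
ratio_ci <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  se <- sqrt(fit$robust_cov[2, 2])
  list(
    ratio = fit$ratio,
    lower = fit$ci_lower,
    upper = fit$ci_upper,
    p_value = fit$p_value,
    p_display = if (fit$p_value < 0.001) "< 0.001" else {
      sprintf("%.3f", round_half_up(fit$p_value, 3))
    },
    degenerate = se == 0
  )
}

#' GEE ratio panel over several metrics
#'
#' Fits the marginal model once per metric and assembles the reporting
#' table: pooled without-CAD and with-CAD proportions (micro-averaged over
#' readers), the GEE ratio with robust 95% CI and the two-sided p-value.
#'
#' @param outcomes Reader case outcomes (as for [build_outcome_records()]).
#' @param metrics Metrics to fit (default all five).
#' @param spec A [gee_spec()].
#' @return A tibble `metric`, `pre`, `post`, `ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`, `p_display`, `alpha_hat`, `converged`.
#' @export
gee_ratio_panel <- function(outcomes, metrics = metric_names,
                            spec = gee_spec()) {
  rows <- lapply(metrics, function(m) {
    rec <- build_outcome_records(outcomes, m)
    fit <- fit_gee(rec, spec)
    ci <- ratio_ci(fit)
    tibble::tibble(
      metric = m,
      pre = mean(rec$y[rec$arm == 0]),
      post = mean(rec$y[rec$arm == 1]),
      ratio = ci$ratio,
      ci_lower = ci$lower,
      ci_upper = ci$upper,
      p_value = ci$p_value,
      p_display = ci$p_display,
      alpha_hat = fit$alpha_hat,
      converged = fit$converged
    )
  })
  dplyr::bind_rows(rows)
}
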