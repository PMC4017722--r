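#' Simulate an activity study with noisy, possibly correlated predictors
#'
#' Generates a training and a testing set of compounds with true activities
#' log-uniform over a configurable span of orders of magnitude, plus `m`
#' prediction systems whose log10 estimate is truth + per-system bias +
#' Gaussian noise, with a controllable cross-system noise correlation. This
#' reproduces the statistical situation fusion analysis assumes: "accurate"
#' systems (small `noise_sd`) and "diverse" systems (low `noise_corr`) can
#' be dialed in independently.
#'
#' Defaults mirror the packaged study's scale: 25 training and 133 testing
#' inhibitors, activities spanning 4.6 orders of magnitude from about
#' 2.3 nM up, and two systems with noise of 1 log10 unit — which puts the
#' individual test correlations near the 0.7–0.8 range of real
#' pharmacophore models on this kind of data.
#'
#' @param n_train,n_test Compound counts.
#' @param span_orders Breadth of the true activity range, log10 units.
#' @param m Number of prediction systems.
#' @param noise_sd Per-system noise standard deviation(s), log10 units;
#'   recycled to length `m`.
#' @param bias Per-system systematic offset(s), log10 units; recycled.
#' @param noise_corr `m x m` noise correlation matrix (unit diagonal,
#'   symmetric, positive semidefinite); default identity (independent
#'   noise). A scalar is taken as the common off-diagonal value.
#' @param seed Integer seed; identical configurations produce identical
#'   tables.
#' @return A list with elements `train` and `test`, each a wide activity
#'   tibble (`id`, `ic50_nM`, system columns `S1`..`Sm`) with disjoint ids,
#'   plus the configuration in the `"config"` attribute.
#' @examples
#' sim <- simulate_study(m = 2, noise_sd = 0.8, seed = 42)
#' evaluate_systems(sim$test)
#' @export
simulate_study <- function(n_train = 25, n_test = 133, span_orders = 4.6,
                           m = 2, noise_sd = 1, bias = 0,
                           noise_corr = NULL, seed = 1) {
  if (n_train < 0 || n_test < 0 || span_orders < 0 || m < 1) {
    abort("counts must be non-negative and m >= 1",
          class = "qsarfuse_argument_error")
  }
  noise_sd <- rep_len(noise_sd, m)
  bias <- rep_len(bias, m)
  if (any(noise_sd < 0)) {
    abort("noise_sd must be non-negative", class = "qsarfuse_argument_error")
  }
  if (is.null(noise_corr)) noise_corr <- diag(m)
  if (is.matrix(noise_corr)) {
    R <- noise_corr
  } else if (length(noise_corr) == 1) {
    R <- matrix(noise_corr, m, m)
    diag(R) <- 1
  } else {
    abort("noise_corr must be a matrix or a scalar",
          class = "qsarfuse_argument_error")
  }
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8)) {
    abort("noise_corr must be symmetric with unit diagonal",
          class = "qsarfuse_argument_error")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("noise_corr must be positive semidefinite",
          class = "qsarfuse_argument_error")
  }
  Sigma <- diag(noise_sd, m) %*% R %*% diag(noise_sd, m)

  set.seed(seed)
  # floor near the most potent inhibitor of the packaged study (~2.3 nM)
  log_min <- log10(2.3)
  draw_set <- function(n, prefix) {
    truth <- runif(n, log_min, log_min + span_orders)
    eps <- if (n == 0) {
      matrix(numeric(0), 0, m)
    } else {
      matrix(MASS::mvrnorm(n, mu = rep(0, m), Sigma = Sigma), nrow = n)
    }
    pred <- 10^(truth + outer(rep(1, n), bias) + eps)
    colnames(pred) <- paste0("S", seq_len(m))
    out <- dplyr::bind_cols(
      tibble(id = sprintf("%s%04d", prefix, seq_len(n)), ic50_nM = 10^truth),
      as_tibble(pred)
    )
    structure(out, systems = paste0("S", seq_len(m)))
  }
  train <- draw_set(n_train, "TRN")
  test <- draw_set(n_test, "TST")
  structure(list(train = train, test = test),
            config = list(n_train = n_train, n_test = n_test,
                          span_orders = span_orders, m = m,
                          noise_sd = noise_sd, bias = bias,
                          noise_corr = R, seed = seed))
}

#' Recover the noise scale of a prediction system
#'
#' Sample standard deviation of the log10 residuals (predicted minus true
#' activity); on simulated data this estimates the generating `noise_sd`.
#'
#' @param data Wide activity table with the truth and system columns.
#' @param system System column name.
#' @param truth Experimental-activity column name.
#' @return The residual standard deviation, log10 units.
#' @seealso [recover_bias()] for the systematic offset.
#' @export
recover_noise_sd <- function(data, system, truth = "ic50_nM") {
  res <- log_residuals(data, system, truth)
  sd(res)
}

#' Recover the systematic bias of a prediction system
#'
#' Mean of the log10 residuals; on simulated data this estimates the
#' generating `bias`.
#'
#' @inheritParams recover_noise_sd
#' @return The mean residual, log10 units.
#' @export
recover_bias <- function(data, system, truth = "ic50_nM") {
  res <- log_residuals(data, system, truth)
  mean(res)
}

log_residuals <- function(data, system, truth) {
  if (!system %in% names(data) || !truth %in% names(data)) {
    abort("system or truth column not found",
          class = "qsarfuse_coverage_error")
  }
  if (nrow(data) < 2) {
    abort("need at least 2 compounds", class = "qsarfuse_argument_error")
  }
  to_log_activity(data[[system]]) - to_log_activity(data[[truth]])
}
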