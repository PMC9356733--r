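#' Batch design for harmonization
#'
#' @param batch site / batch label per subject.
#' @param diagnosis group label per subject (`case` / `control` or any
#'   2-level factor); the biological covariate whose effect is preserved.
#' @param age optional age per subject; retained as a covariate only when
#'   `retain_age = TRUE` (the default design treats diagnosis as the only
#'   biological variable of interest).
#' @param retain_age logical; protect the age effect as well.
#' @return object of class `batch_design`.
#' @export
batch_design <- function(batch, diagnosis, age = NULL, retain_age = FALSE) {
  batch <- factor(batch)
  diagnosis <- factor(diagnosis)
  n <- length(batch)
  if (length(diagnosis) != n) stop("batch and diagnosis lengths differ")
  if (retain_age && is.null(age)) stop("retain_age = TRUE requires age")
  if (any(table(batch) < 2))
    stop("every batch must contain at least 2 subjects")
  single_group <- tapply(diagnosis, batch, function(d) length(unique(d)) == 1)
  if (nlevels(batch) > 1 && nlevels(diagnosis) > 1 && any(single_group))
    warning("batch(es) with a single diagnosis group: ",
            paste(names(single_group)[single_group], collapse = ", "),
            " (diagnosis partially confounded with site)")
  structure(list(batch = batch, diagnosis = diagnosis, age = age,
                 retain_age = retain_age),
            class = "batch_design")
}

#' Parametric empirical-Bayes batch adjustment (ComBat)
#'
#' Removes additive and multiplicative batch (site) effects from a
#' feature x subject matrix while preserving the diagnosis effect (and
#' optionally age).  Standard parametric ComBat: (1) least-squares fit of
#' grand mean, covariate effects and per-batch location; (2) standardize
#' features; (3) empirical-Bayes shrinkage of per-batch, per-feature
#' location (normal prior) and scale (inverse-gamma prior) toward pooled
#' batch hyperparameters estimated by method of moments, solved by
#' iterated conditional modes to tolerance 1e-4 (max 100 iterations);
#' (4) remove the shrunken batch effects and restore grand mean +
#' covariate effects.
#'
#' Constant (zero-variance) features are passed through untouched with a
#' warning; a single batch returns the input unchanged with a warning.
#'
#' @param dat numeric matrix, features x subjects, no missing values.
#' @param design a [batch_design()].
#' @param eb use empirical-Bayes shrinkage (`TRUE`, default) or raw batch
#'   estimates.
#' @return adjusted matrix of the same dimensions, with attribute
#'   `"combat"` holding the shrunken batch estimates
#'   (`gamma_hat`, `gamma_star`, `delta_hat`, `delta_star`, `gamma_bar`).
#' @export
combat_adjust <- function(dat, design, eb = TRUE) {
  stopifnot(inherits(design, "batch_design"))
  dat <- as.matrix(dat)
  if (anyNA(dat)) stop("data contains missing values")
  batch <- design$batch
  if (ncol(dat) != length(batch))
    stop("ncol(dat) must equal the number of subjects in the design")
  if (nlevels(batch) < 2) {
    warning("single batch: nothing to harmonize, returning input")
    return(dat)
  }

  const <- apply(dat, 1, function(x) stats::var(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant feature(s) passed through unadjusted")
    out <- dat
    out[!const, ] <- combat_adjust(dat[!const, , drop = FALSE], design, eb)
    return(out)
  }

  n_array <- ncol(dat)
  batches <- levels(batch)
  n_batch <- length(batches)
  n_per <- as.vector(table(batch))

  # design: batch one-hot (no intercept) + covariates; a single-level
  # diagnosis contributes no covariate column (pure batch correction)
  X_batch <- stats::model.matrix(~ batch - 1)
  X_cov <- if (nlevels(design$diagnosis) > 1)
    stats::model.matrix(~ design$diagnosis)[, -1, drop = FALSE]
  else matrix(0, n_array, 0)
  if (design$retain_age) X_cov <- cbind(X_cov, age = as.numeric(design$age))
  X <- cbind(X_batch, X_cov)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient ",
         "(covariate confounded with batch)")

  beta_hat <- solve(crossprod(X), crossprod(X, t(dat)))   # p x features
  grand_mean <- crossprod(n_per / n_array,
                          beta_hat[seq_len(n_batch), , drop = FALSE])
  stand_mean <- crossprod(grand_mean, t(rep(1, n_array)))
  if (ncol(X_cov) > 0) {
    cov_effect <- t(X_cov %*% beta_hat[-seq_len(n_batch), , drop = FALSE])
    stand_mean <- stand_mean + cov_effect
  }
  var_pooled <- rowSums((dat - t(X %*% beta_hat))^2) / n_array
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(0, n_batch, nrow(dat))
  delta_hat <- matrix(0, n_batch, nrow(dat))
  for (b in seq_len(n_batch)) {
    cols <- batch == batches[b]
    gamma_hat[b, ] <- rowMeans(s_data[, cols, drop = FALSE])
    # MLE (n_b denominator) variance, consistent with var_pooled's
    # denominator -- this makes covariate-free adjustment exactly idempotent
    delta_hat[b, ] <- rowMeans(
      (s_data[, cols, drop = FALSE] - gamma_hat[b, ])^2)
  }

  if (eb) {
    gamma_bar <- rowMeans(gamma_hat)
    t2 <- apply(gamma_hat, 1, stats::var)
    a_prior <- apply(delta_hat, 1, function(d) {
      m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
    })
    b_prior <- apply(delta_hat, 1, function(d) {
      m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
    })
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (b in seq_len(n_batch)) {
      sol <- eb_solve(s_data[, batch == batches[b], drop = FALSE],
                      gamma_hat[b, ], delta_hat[b, ],
                      gamma_bar[b], t2[b], a_prior[b], b_prior[b])
      gamma_star[b, ] <- sol$gamma
      delta_star[b, ] <- sol$delta
    }
  } else {
    gamma_bar <- rowMeans(gamma_hat)
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  bayes_data <- s_data
  for (b in seq_len(n_batch)) {
    cols <- batch == batches[b]
    bayes_data[, cols] <- (s_data[, cols, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta_star[b, ])
  }
  out <- bayes_data * sqrt(var_pooled) + stand_mean
  dimnames(out) <- dimnames(dat)
  attr(out, "combat") <- list(gamma_hat = gamma_hat, gamma_star = gamma_star,
                              delta_hat = delta_hat, delta_star = delta_star,
                              gamma_bar = gamma_bar)
  out
}

# iterated conditional solution of the EB posterior for one batch:
# normal prior on location, inverse-gamma prior on scale
eb_solve <- function(sdat, g_hat, d_hat, g_bar, t2, a, b,
                     conv = 1e-4, max_iter = 100L) {
  n <- ncol(sdat)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((sdat - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_old, delta = d_old)
}
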