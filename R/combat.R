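#' Reference-batch empirical-Bayes batch correction
#'
#' Parametric empirical-Bayes location/scale batch adjustment (the ComBat
#' model) in its reference-batch variant: per gene, all samples are
#' standardized with the reference batch's mean and (population) variance;
#' per-batch per-gene location (gamma) and scale (delta^2) estimates of the
#' non-reference batches are shrunk toward batch-level priors (normal prior
#' on locations, inverse-gamma prior on scales, hyperparameters by method of
#' moments) via the usual iterative conditional solution; adjusted values are
#' destandardized back to the reference scale. The reference batch is
#' returned numerically unchanged, so a model locked on reference-scale data
#' stays valid when new cohorts are aligned to it.
#'
#' @param x an `expr_matrix` with `state == "ranked"`, at least 2 batches,
#'   every batch with at least 2 samples.
#' @param reference_batch batch label to anchor to.
#' @param reference_samples optional character vector of sample ids within
#'   the reference batch used to estimate the standardization parameters
#'   (e.g. a tissue-restricted subset of a pan-cancer reference). Default:
#'   all reference-batch samples.
#' @return a list with `matrix` (an `expr_matrix`, `state == "corrected"`)
#'   and `model` (a `batch_model`: grand parameters, per-batch estimates,
#'   EB hyperparameters and shrunken posteriors).
#' @export
combat_correct <- function(x, reference_batch, reference_samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$state != "ranked")
    stop("combat_correct expects state 'ranked', got '", x$state, "'")
  if (anyNA(x$values))
    stop("missing values present; run impute_missing() first")
  batches <- unique(x$batch)
  if (length(batches) < 2L)
    stop("batch correction needs at least 2 batches, got ", length(batches))
  sizes <- table(x$batch)
  if (any(sizes < 2L))
    stop("batch(es) with a single sample (variance undefined): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (!reference_batch %in% batches)
    stop("reference batch '", reference_batch, "' not present")

  v <- x$values
  ref_cols <- colnames(v)[x$batch == reference_batch]
  est_cols <- if (is.null(reference_samples)) ref_cols else {
    bad <- setdiff(reference_samples, ref_cols)
    if (length(bad))
      stop("reference_samples not in the reference batch: ",
           paste(bad, collapse = ", "))
    reference_samples
  }
  if (length(est_cols) < 2L) stop("need >= 2 reference samples")

  ref <- v[, est_cols, drop = FALSE]
  grand_mean <- rowMeans(ref)
  # population variance (1/n), matching the standard reference-batch pooling
  pooled_var <- rowSums((ref - grand_mean)^2) / length(est_cols)
  if (any(pooled_var <= 0))
    stop("gene(s) with zero variance in the reference batch: ",
         paste(rownames(v)[pooled_var <= 0], collapse = ", "))

  z <- (v - grand_mean) / sqrt(pooled_var)

  non_ref <- setdiff(batches, reference_batch)
  gamma_hat <- delta_hat <- gamma_star <- delta_star <-
    matrix(NA_real_, length(non_ref), nrow(v),
           dimnames = list(non_ref, rownames(v)))
  hyper <- data.frame(batch = non_ref, n = NA_integer_, gamma_bar = NA_real_,
                      tau2 = NA_real_, a_prior = NA_real_, b_prior = NA_real_)

  out <- v
  for (i in seq_along(non_ref)) {
    b <- non_ref[i]
    cols <- which(x$batch == b)
    zb <- z[, cols, drop = FALSE]
    n_b <- length(cols)
    g_hat <- rowMeans(zb)
    d_hat <- rowSums((zb - g_hat)^2) / (n_b - 1L)

    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_pr <- (2 * s2 + m^2) / s2
    b_pr <- (m * s2 + m^3) / s2

    sol <- eb_iterate(zb, g_hat, d_hat, g_bar, t2, a_pr, b_pr)
    gamma_hat[i, ] <- g_hat; delta_hat[i, ] <- d_hat
    gamma_star[i, ] <- sol$gamma; delta_star[i, ] <- sol$delta
    hyper[i, -1L] <- list(n_b, g_bar, t2, a_pr, b_pr)

    out[, cols] <- (z[, cols] - sol$gamma) / sqrt(sol$delta) *
      sqrt(pooled_var) + grand_mean
  }
  # reference batch untouched by construction (out initialized from v)

  model <- structure(list(
    reference_batch = reference_batch,
    reference_samples = est_cols,
    grand_mean = grand_mean,
    pooled_var = pooled_var,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    hyper = hyper), class = "batch_model")

  list(matrix = expression_matrix(out, x$batch, state = "corrected"),
       model = model)
}

# Iterative conditional solution for the parametric EB posteriors of one
# batch: normal prior on gamma, inverse-gamma(a_pr, b_pr) prior on delta^2.
eb_iterate <- function(zb, g_hat, d_hat, g_bar, t2, a_pr, b_pr,
                       conv = 1e-4, max_iter = 1000L) {
  n <- ncol(zb)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((zb - g_new)^2)
    d_new <- (0.5 * sum2 + b_pr) / (n / 2 + a_pr - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new; d_old <- d_new
    if (is.finite(change) && change < conv) break
  }
  list(gamma = g_old, delta = d_old)
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: reference '%s' (%d samples), %d adjusted batch(es), %d genes\n",
              x$reference_batch, length(x$reference_samples),
              nrow(x$gamma_star), length(x$grand_mean)))
  invisible(x)
}
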