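#' Depth weights and source covariance
#'
#' Column norms of the gain matrix are the sensitivity weights
#' `w_j = ||L[, j]||`; the source covariance prior is
#' `R = diag(w_j^(-2 * exponent))`.  With `exponent = 1` the effective
#' whitened columns `L R^(1/2)` have unit norm (the depth-weighting
#' parameter p = 1 convention); `exponent = 0.25` reproduces the
#' `diag(w^(-1/2))` reading.  Exponent 0 disables depth weighting.
#'
#' Columns of barely-visible (deep) sources otherwise receive an unbounded
#' variance boost that lets reconstruction noise accumulate there; following
#' the standard minimum-norm convention the prior's dynamic range is capped
#' at `limit^2` (largest over smallest diagonal entry).
#'
#' @param L a `leadfield` or plain M x N matrix.
#' @param exponent depth-weighting exponent (dimensionless), default 1.
#' @param limit cap on the amplitude dynamic range of the prior (default
#'   10, i.e. variance ratio at most 100); `Inf` disables the cap.
#' @return list with `w` (column norms) and `R` (length-N diagonal of the
#'   source covariance).
#' @export
depth_weights <- function(L, exponent = 1, limit = 10) {
  m <- if (inherits(L, "leadfield")) L$matrix else L
  w <- sqrt(colSums(m^2))
  if (any(w == 0))
    stop("zero leadfield column(s): ", paste(which(w == 0)[1:3], collapse = ", "))
  R <- w^(-2 * exponent)
  if (is.finite(limit)) R <- pmin(R, limit^2 * min(R))
  list(w = w, R = R)
}

#' Noise covariance from baseline epochs
#'
#' Empirical covariance over all baseline samples (epochs x time pooled)
#' with diagonal loading `loading * mean(diag)` added to guarantee positive
#' definiteness.
#'
#' @param baseline numeric array epochs x sensors x time, or a samples x
#'   sensors matrix.
#' @param loading diagonal loading factor (dimensionless), default 0.1.
#' @return object of class `noise_covariance`: `matrix`, `rank`, `loading`.
#' @export
estimate_noise_cov <- function(baseline, loading = 0.1) {
  if (is.array(baseline) && length(dim(baseline)) == 3) {
    d <- dim(baseline)
    samples <- matrix(aperm(baseline, c(1, 3, 2)), d[1] * d[3], d[2])
  } else samples <- as.matrix(baseline)
  if (nrow(samples) < 2) stop("need at least 2 baseline samples")
  S <- stats::cov(samples) * (nrow(samples) - 1) / nrow(samples)
  r <- qr(S)$rank
  if (loading > 0) {
    md <- mean(diag(S))
    if (md == 0) md <- 1
    S <- S + diag(loading * md, ncol(S))
  }
  structure(list(matrix = S, rank = r, loading = loading),
            class = "noise_covariance")
}

# Symmetric inverse square root with rank truncation.
whitener_from_cov <- function(Sigma, rank_tol = 1e-10) {
  e <- eigen(Sigma, symmetric = TRUE)
  keep <- e$values > rank_tol * max(e$values)
  d <- ifelse(keep, 1 / sqrt(pmax(e$values, 0)), 0)
  list(W = e$vectors %*% (d * t(e$vectors)), rank = sum(keep))
}

#' Regularization parameter from an assumed SNR
#'
#' The conventional mapping `lambda^2 = 1 / snr^2`, to be used together with
#' the trace-normalized whitened gain (see [make_inverse_operator()]).
#'
#' @param snr_assumed assumed amplitude SNR, > 0.
#' @return lambda^2 (dimensionless).
#' @export
select_lambda2 <- function(snr_assumed) {
  stopifnot(snr_assumed > 0)
  1 / snr_assumed^2
}

#' Regularized minimum-norm inverse operator
#'
#' Builds the whitened, depth-weighted, regularized operator
#' \deqn{\bar M = R \bar L^\top (\bar L R \bar L^\top + \lambda^2 I)^{-1},
#'   \qquad \bar L = \Sigma^{-1/2} L.}
#' With `R = I` and `lambda2 = 0` this is the minimum-norm pseudoinverse.
#' When `scale_R = TRUE` the source covariance is rescaled so that
#' `trace(L R L^T)/M = 1` in whitened units, making `lambda2 = 1/snr^2`
#' dimensionally meaningful; the rescaling does not change the `lambda2 = 0`
#' solution.
#'
#' @param L a `leadfield` or M x N matrix.
#' @param R length-N diagonal source covariance (e.g. from
#'   [depth_weights()]), or `NULL` for identity.
#' @param Sigma a `noise_covariance`, M x M matrix, or `NULL` for identity.
#' @param lambda2 regularization parameter, >= 0.
#' @param scale_R trace-normalize the whitened gain (default `TRUE`).
#' @return object of class `inverse_operator` with `operator` (N x M, acts
#'   on whitened data), `whitener`, `R`, `lambda2`, `sensor_names`.
#' @export
make_inverse_operator <- function(L, R = NULL, Sigma = NULL, lambda2 = 0,
                                  scale_R = TRUE) {
  sensor_names <- if (inherits(L, "leadfield")) L$sensor_names else NULL
  source_space <- if (inherits(L, "leadfield")) L$source_space else NULL
  m <- if (inherits(L, "leadfield")) L$matrix else as.matrix(L)
  M <- nrow(m); N <- ncol(m)
  if (is.null(R)) R <- rep(1, N)
  if (length(R) != N) stop("R must have one entry per source")
  Sig <- if (is.null(Sigma)) diag(M)
         else if (inherits(Sigma, "noise_covariance")) Sigma$matrix
         else as.matrix(Sigma)
  wh <- whitener_from_cov(Sig)
  Lbar <- wh$W %*% m
  if (scale_R) {
    tr <- sum(Lbar^2 %*% R) / M          # trace(Lbar R Lbar^T) / M
    if (tr > 0) R <- R / tr
  }
  LRLt <- Lbar %*% (R * t(Lbar))
  G <- LRLt + diag(lambda2, M)
  Minv <- tryCatch(solve(G), error = function(e) {
    # rank-deficient at lambda2 = 0: fall back to pseudo-solve
    e2 <- eigen(G, symmetric = TRUE)
    keep <- e2$values > 1e-12 * max(e2$values)
    e2$vectors %*% (ifelse(keep, 1 / e2$values, 0) * t(e2$vectors))
  })
  op <- (R * t(Lbar)) %*% Minv
  structure(list(operator = op, whitener = wh$W, whitener_rank = wh$rank,
                 Sigma = Sig, R = R, lambda2 = lambda2,
                 sensor_names = sensor_names, source_space = source_space,
                 dspm_norms = NULL),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("inverse_operator: %d sources x %d sensors, lambda2 = %.4g%s\n",
              nrow(x$operator), ncol(x$operator), x$lambda2,
              if (!is.null(x$dspm_norms)) ", dSPM norms attached" else ""))
  invisible(x)
}

#' Apply an inverse operator to sensor data
#'
#' `x = Mbar Sigma^(-1/2) b`; linear in `b`.  If both the operator and `b`
#' carry sensor names, the ordering is checked.
#'
#' @param op an [make_inverse_operator()] result.
#' @param b length-M sensor vector (optionally named).
#' @return object of class `source_estimate` with `strengths` (A.m),
#'   optional `dspm`, `peak_index`.
#' @export
apply_inverse <- function(op, b) {
  if (!is.null(names(b)) && !is.null(op$sensor_names) &&
      !identical(names(b), op$sensor_names))
    stop("sensor name/order mismatch between operator and data")
  x <- as.numeric(op$operator %*% (op$whitener %*% as.numeric(b)))
  est <- structure(list(strengths = x, dspm = NULL,
                        peak_index = which.max(abs(x))),
                   class = "source_estimate")
  if (!is.null(op$dspm_norms)) {
    est$dspm <- x / op$dspm_norms
    est$peak_index <- which.max(abs(est$dspm))
  }
  est
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("source_estimate: %d sources, peak |x| = %.4g at %d%s\n",
              length(x$strengths), max(abs(x$strengths)), x$peak_index,
              if (!is.null(x$dspm)) " (dSPM attached)" else ""))
  invisible(x)
}

#' dSPM noise normalization
#'
#' Per-source noise standard deviations from the diagonal of
#' `R* = M Sigma M^T` (with `M` the unwhitened operator); the normalized
#' estimate `x*_j = x_j / sqrt(R*_jj)` behaves like a z-score when the noise
#' covariance is well estimated.
#'
#' @param op an `inverse_operator` built with a valid noise covariance.
#' @param x optional `source_estimate` to normalize.
#' @return if `x` is given, the estimate with `dspm` filled; otherwise the
#'   operator with `dspm_norms` attached.
#' @export
dspm_normalize <- function(op, x = NULL) {
  Mfull <- op$operator %*% op$whitener
  norms <- sqrt(rowSums((Mfull %*% op$Sigma) * Mfull))
  if (any(norms == 0)) stop("zero dSPM variance for some sources")
  op$dspm_norms <- norms
  if (is.null(x)) return(op)
  x$dspm <- x$strengths / norms
  x$peak_index <- which.max(abs(x$dspm))
  x
}
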