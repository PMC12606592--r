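#' Simulate the sensor signal of a single dipole
#'
#' Direct (column-wise) forward solution for one dipole: primary field plus
#' volume currents via the Geselowitz formula, integrated over each sensor's
#' flux quadrature.
#'
#' @param head a [head_model()].
#' @param sensors a [sensor_array()].
#' @param dipole_position location (m), inside the conductor.
#' @param dipole_moment moment (A.m); default 10 nA.m along +z.
#' @param config a [solver_config()].
#' @param normalize return the unit-norm signal vector (default `FALSE`).
#' @param ... passed to [direct_column()].
#' @return length-M sensor vector.
#' @export
simulate_dipole_signal <- function(head, sensors, dipole_position,
                                   dipole_moment = c(0, 0, 1e-8),
                                   config = solver_config(),
                                   normalize = FALSE, ...) {
  b <- direct_column(head, dipole_position, dipole_moment, sensors, config, ...)
  if (normalize) b / sqrt(sum(b^2)) else b
}

#' Cortical noise model
#'
#' Draws `K` dipoles uniformly over the faces of a cortical mid-surface
#' (area-weighted, without replacement when possible), oriented along the
#' face normals, and stores their direct forward fields as the columns of a
#' noise leadfield.  Sensor noise is then simulated as random superpositions
#' of these cortical sources.
#'
#' @param head a [head_model()].
#' @param sensors a [sensor_array()].
#' @param mid_surface a [triangle_mesh()] carrying the noise dipoles.
#' @param K number of noise dipoles (reference protocol: 2000).
#' @param seed integer seed for the dipole draw.
#' @param config a [solver_config()].
#' @param source_sigma compartment conductivity at the dipoles.
#' @return object of class `noise_model`: `L` (M x K), `positions`,
#'   `normals`, `faces`, `seed`.
#' @export
build_noise_model <- function(head, sensors, mid_surface, K = 2000, seed = 1,
                              config = solver_config(), source_sigma = NULL) {
  if (K < 2) stop("K must be >= 2")
  nf <- nrow(mid_surface$faces)
  if (K > nf) stop("K exceeds the number of candidate faces")
  faces <- local({
    set.seed(seed)
    sample.int(nf, K, replace = FALSE, prob = mid_surface$face_areas)
  })
  pos <- mid_surface$face_centers[faces, , drop = FALSE]
  nrm <- mid_surface$face_normals[faces, , drop = FALSE]
  if (is.null(source_sigma))
    source_sigma <- head$layers[[length(head$layers)]]$sigma_in
  head <- precompute_nearfield(head, config)
  L <- direct_forward(head, sensors, pos, nrm, source_sigma, config)
  structure(list(L = L, positions = pos, normals = nrm, faces = faces,
                 seed = seed), class = "noise_model")
}

#' Draw a unit noise vector from a noise model
#'
#' `eps = L X / ||L X||` with `X` i.i.d. standard normal dipole strengths.
#'
#' @param model a [build_noise_model()] result.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param zero_index optional dipole indices whose strengths are forced to
#'   zero (used by error maps so noise never feeds the probed source).
#' @return unit-norm length-M vector.
#' @export
sample_noise <- function(model, seed = NULL, zero_index = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (try in 1:10) {
    X <- stats::rnorm(ncol(model$L))
    if (!is.null(zero_index)) X[zero_index] <- 0
    eps <- as.numeric(model$L %*% X)
    n <- sqrt(sum(eps^2))
    if (n > 0) return(eps / n)
  }
  stop("degenerate noise draw")
}

#' Mix a signal and a noise vector to a target SNR
#'
#' Convex mixing `s(eta) = (1 - eta) eps + eta b` of unit-norm noise and
#' signal vectors, with `eta` found by bisection so that
#' `SNR(eta) = std(s(eta)) / std((1 - eta) eps)` hits `snr_target` to 0.1%.
#' At `eta = 0` the ratio is 1, so targets below 1 are unreachable.
#'
#' @param b unit-norm signal vector.
#' @param eps unit-norm noise vector.
#' @param snr_target target SNR, >= 1.
#' @param tol relative tolerance on the achieved SNR.
#' @return list with `signal`, `eta`, `achieved_snr`.
#' @export
mix_to_snr <- function(b, eps, snr_target, tol = 1e-3) {
  if (snr_target < 1)
    stop("snr_target < 1 is unreachable with this parameterization")
  snr_of <- function(eta)
    stats::sd((1 - eta) * eps + eta * b) / stats::sd((1 - eta) * eps)
  if (snr_target == 1 || snr_of(0) >= snr_target) {
    eta <- 0
  } else {
    lo <- 0; hi <- 1 - 1e-9
    eta <- NA_real_
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      v <- snr_of(mid)
      if (abs(v - snr_target) <= tol * snr_target) { eta <- mid; break }
      if (v < snr_target) lo <- mid else hi <- mid
    }
    if (is.na(eta)) eta <- (lo + hi) / 2
  }
  sig <- (1 - eta) * eps + eta * b
  list(signal = sig, eta = eta, achieved_snr = snr_of(eta))
}

#' Localize a source estimate against a known position
#'
#' Peak: position of the largest-|strength| source.  Region: all sources
#' with `|x| >= threshold * max|x|`.  Centroid: unweighted (or area-weighted)
#' arithmetic mean of the region positions.
#'
#' @param x a `source_estimate`, or numeric vector of strengths.
#' @param source_space the matching `source_space`.
#' @param true_position ground-truth location (m), or `NULL`.
#' @param threshold activation threshold fraction in (0, 1], default 0.75.
#' @param area_weighted weight the centroid by per-source areas.
#' @param use_dspm localize on the dSPM values when present.
#' @return object of class `localization_result`: `peak_position`,
#'   `centroid_position`, `region` (indices), `peak_distance`,
#'   `centroid_distance` (m, `NA` without `true_position`).
#' @export
localize <- function(x, source_space, true_position = NULL, threshold = 0.75,
                     area_weighted = FALSE, use_dspm = FALSE) {
  s <- if (inherits(x, "source_estimate")) {
    if (use_dspm) { if (is.null(x$dspm)) stop("no dSPM values"); x$dspm }
    else x$strengths
  } else as.numeric(x)
  if (all(s == 0)) stop("all-zero source estimate")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  a <- abs(s)
  peak <- which.max(a)
  region <- which(a >= threshold * a[peak])
  pos <- source_space$positions
  w <- if (area_weighted) source_space$areas[region] else rep(1, length(region))
  centroid <- colSums(pos[region, , drop = FALSE] * w) / sum(w)
  dist_to <- function(p) if (is.null(true_position)) NA_real_
                         else sqrt(sum((p - true_position)^2))
  structure(list(peak_position = pos[peak, ], centroid_position = centroid,
                 peak_index = peak, region = region, threshold = threshold,
                 peak_distance = dist_to(pos[peak, ]),
                 centroid_distance = dist_to(centroid)),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf(
    "localization: peak at (%.1f, %.1f, %.1f) mm, centroid (%.1f, %.1f, %.1f) mm\n",
    x$peak_position[1] * 1e3, x$peak_position[2] * 1e3, x$peak_position[3] * 1e3,
    x$centroid_position[1] * 1e3, x$centroid_position[2] * 1e3,
    x$centroid_position[3] * 1e3))
  if (!is.na(x$peak_distance))
    cat(sprintf("  distances: peak %.2f mm, centroid %.2f mm (threshold %g%%)\n",
                x$peak_distance * 1e3, x$centroid_distance * 1e3,
                100 * x$threshold))
  invisible(x)
}

#' Tag a target region of sulcal faces around a seed point
#'
#' Candidate faces are those with discrete mean curvature below
#' `curvature_threshold` (valleys, in the outward-normal sign convention).
#' The mask is the candidate faces within the smallest radius of
#' `seed_point` whose cumulative area reaches `area_fraction` of the total
#' candidate area.
#'
#' @param mesh a [triangle_mesh()].
#' @param seed_point position (m) on or near the mesh.
#' @param curvature_threshold mean-curvature cutoff (1/m).
#' @param area_fraction fraction of the candidate area to include, in (0, 1].
#' @return logical face mask (length = number of faces).
#' @export
tag_target_region <- function(mesh, seed_point, curvature_threshold = 0,
                              area_fraction = 0.4) {
  H <- mesh_mean_curvature(mesh)
  cand <- H < curvature_threshold
  if (!any(cand)) stop("no candidate (sulcal) faces under the threshold")
  d <- sqrt(rowSums(t(t(mesh$face_centers) - seed_point)^2))
  total <- sum(mesh$face_areas[cand])
  ord <- order(d)
  ord <- ord[cand[ord]]
  cum <- cumsum(mesh$face_areas[ord])
  ncut <- which(cum >= area_fraction * total)[1]
  mask <- rep(FALSE, nrow(mesh$faces))
  mask[ord[seq_len(ncut)]] <- TRUE
  mask
}

#' ROC curve and AUC for source localization as binary classification
#'
#' Sweeps the activation threshold from 0 to 100% of the maximum normalized
#' strength; at each threshold, target-region sources above threshold are
#' true positives and non-target sources above threshold are false
#' positives.  AUC by trapezoidal integration of TPR over FPR.
#'
#' @param strengths length-N source strengths (absolute values are used).
#' @param target_mask logical length-N mask of true-source positions; must
#'   contain both classes.
#' @param n_thresholds sweep resolution (unique strengths are always
#'   included, so the curve is exact).
#' @return object of class `roc_result`: `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(strengths, target_mask, n_thresholds = 101) {
  s <- abs(as.numeric(strengths))
  m <- as.logical(target_mask)
  if (!any(m) || all(m)) stop("target mask must contain both classes")
  if (length(s) != length(m)) stop("length mismatch")
  smax <- max(s)
  sn <- if (smax > 0) s / smax else s
  thr <- sort(unique(c(seq(0, 1, length.out = n_thresholds), sn, 1 + 1e-12)),
              decreasing = FALSE)
  P <- sum(m); Ngt <- sum(!m)
  tpr <- vapply(thr, function(t) sum(sn[m] > t) / P, 0)
  fpr <- vapply(thr, function(t) sum(sn[!m] > t) / Ngt, 0)
  ord <- order(fpr, tpr)
  fo <- c(0, fpr[ord], 1); to <- c(0, tpr[ord], 1)
  auc <- sum(diff(fo) * (utils::head(to, -1) + utils::tail(to, -1)) / 2)
  structure(list(thresholds = thr, fpr = rev(fpr), tpr = rev(tpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Localization error maps under fixed absolute noise
#'
#' For each probed dipole `j`, simulates `n_samples` noisy measurements
#' `s = (1 - lambda0) u_j + lambda0 eps` (`u_j` the unit-norm forward field
#' of dipole `j`, `eps` a unit noise draw with the `j`th strength forced to
#' zero), localizes each, and returns per-dipole means and standard
#' deviations of the centroid and peak distances.
#'
#' @param noise_model a [build_noise_model()]; its columns provide both the
#'   probed signals and the noise.
#' @param inverse_op an `inverse_operator` matched to `source_space`.
#' @param source_space the inverse model's source space.
#' @param lambda0 absolute noise level in \[0, 1).
#' @param n_samples noise draws per dipole (reference protocol: 500).
#' @param seed integer seed.
#' @param dipoles indices into the noise-model dipoles to probe (default
#'   all).
#' @param threshold centroid activation threshold, default 0.75.
#' @return data.frame with one row per probed dipole: `dipole`,
#'   `centroid_mean`, `centroid_sd`, `peak_mean`, `peak_sd` (m).
#' @export
error_map <- function(noise_model, inverse_op, source_space, lambda0 = 0.1,
                      n_samples = 500, seed = 1, dipoles = NULL,
                      threshold = 0.75) {
  if (lambda0 < 0 || lambda0 >= 1) stop("lambda0 must be in [0, 1)")
  if (is.null(dipoles)) dipoles <- seq_len(ncol(noise_model$L))
  set.seed(seed)
  out <- vector("list", length(dipoles))
  for (ii in seq_along(dipoles)) {
    j <- dipoles[ii]
    bj <- noise_model$L[, j]
    uj <- bj / sqrt(sum(bj^2))
    truth <- noise_model$positions[j, ]
    cd <- pd <- numeric(max(n_samples, 1))
    ns <- if (lambda0 == 0) 1 else n_samples
    for (s in seq_len(ns)) {
      sig <- if (lambda0 == 0) uj else {
        eps <- sample_noise(noise_model, zero_index = j)
        (1 - lambda0) * uj + lambda0 * eps
      }
      loc <- localize(apply_inverse(inverse_op, sig), source_space, truth,
                      threshold)
      cd[s] <- loc$centroid_distance; pd[s] <- loc$peak_distance
    }
    cd <- cd[seq_len(ns)]; pd <- pd[seq_len(ns)]
    out[[ii]] <- data.frame(dipole = j,
                            centroid_mean = mean(cd),
                            centroid_sd = if (ns > 1) stats::sd(cd) else 0,
                            peak_mean = mean(pd),
                            peak_sd = if (ns > 1) stats::sd(pd) else 0)
  }
  do.call(rbind, out)
}
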