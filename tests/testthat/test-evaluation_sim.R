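toy_noise_model <- function(M = 4, K = 100, seed = 17) {
  set.seed(seed)
  L <- matrix(stats::rnorm(M * K), M, K)
  structure(list(L = L, positions = matrix(stats::rnorm(3 * K), K, 3),
                 normals = matrix(1 / sqrt(3), K, 3), seed = seed),
            class = "noise_model")
}

test_that("dipole signals normalize and match the analytic oracle", {
  head <- fx_sphere1()
  arr <- fx_mags6()
  pos <- c(0.01, -0.02, 0.05)
  rad <- pos / sqrt(sum(pos^2))
  tang <- c(-rad[2], rad[1], 0); tang <- tang / sqrt(sum(tang^2)) * 1e-8

  b0 <- simulate_dipole_signal(head, arr, pos, c(0, 0, 0))
  expect_true(all(b0 == 0))

  bn <- simulate_dipole_signal(head, arr, pos, tang, normalize = TRUE)
  expect_equal(sqrt(sum(bn^2)), 1, tolerance = 1e-12)

  aq <- recmeg:::array_quad(arr)
  B <- sarvas_field(pos, tang, c(0, 0, 0), aq$points)
  b_sar <- as.numeric(rowsum(rowSums(aq$wnormal * B), aq$sensor))
  b <- simulate_dipole_signal(head, arr, pos, tang)
  expect_lt(sqrt(sum((b - b_sar)^2) / sum(b_sar^2)), 0.03)
})

test_that("noise models are reproducible area-weighted dipole draws", {
  head <- fx_sphere1()
  arr <- fx_mags6()
  mid <- build_icosphere(0.055, 2)
  nm1 <- build_noise_model(head, arr, mid, K = 12, seed = 3)
  nm2 <- build_noise_model(head, arr, mid, K = 12, seed = 3)
  expect_identical(nm1$faces, nm2$faces)
  expect_identical(nm1$L, nm2$L)
  expect_equal(dim(nm1$L), c(6L, 12L))

  # each column is the forward field of its dipole (solver-tolerance match)
  j <- 5
  bj <- simulate_dipole_signal(head, arr, nm1$positions[j, ], nm1$normals[j, ])
  expect_lt(sqrt(sum((nm1$L[, j] - bj)^2) / sum(bj^2)), 1e-2)

  expect_error(build_noise_model(head, arr, mid, K = 1e6), "exceeds")
  expect_error(build_noise_model(head, arr, mid, K = 1), ">= 2")
})

test_that("noise draws are unit vectors with the model covariance", {
  nm <- toy_noise_model()
  e1 <- sample_noise(nm, seed = 5)
  expect_equal(sqrt(sum(e1^2)), 1, tolerance = 1e-12)
  expect_identical(sample_noise(nm, seed = 5), e1)

  # Monte-Carlo covariance is proportional to L L^T
  set.seed(77)
  draws <- vapply(1:10000, function(i) sample_noise(nm), numeric(4))
  C <- draws %*% t(draws) / ncol(draws)
  ref <- nm$L %*% t(nm$L)
  ref <- ref / sum(diag(ref))          # unit trace, like C
  expect_lt(norm(C - ref, "F") / norm(ref, "F"), 0.1)

  # forced-zero indices do not excite the corresponding column
  nm2 <- toy_noise_model(M = 3, K = 3, seed = 2)
  nm2$L <- diag(3)
  ez <- sample_noise(nm2, seed = 9, zero_index = 2)
  expect_equal(ez[2], 0)
})

test_that("SNR mixing hits its target by bisection", {
  # orthogonal, equal-spread signal and noise: closed-form mixing root
  eps <- c(1, -1, 1, -1) / 2
  b <- c(1, 1, -1, -1) / 2
  for (S in c(81, 27, 9, 3, 2, 1.5)) {
    mx <- mix_to_snr(b, eps, S)
    expect_lt(abs(mx$achieved_snr - S) / S, 0.01)
    root <- sqrt(S^2 - 1) / (1 + sqrt(S^2 - 1))
    expect_lt(abs(mx$eta - root) / root, 1e-2)
  }
  # target 1 is the pure-noise endpoint
  m1 <- mix_to_snr(b, eps, 1)
  expect_identical(m1$eta, 0)
  expect_equal(m1$signal, eps)
  expect_error(mix_to_snr(b, eps, 0.5), "unreachable")

  # general random unit vectors still mix to target
  set.seed(19)
  b2 <- stats::rnorm(20); b2 <- b2 / sqrt(sum(b2^2))
  e2 <- stats::rnorm(20); e2 <- e2 / sqrt(sum(e2^2))
  for (S in c(81, 1.5)) {
    mx <- mix_to_snr(b2, e2, S)
    expect_lt(abs(mx$achieved_snr - S) / S, 0.01)
  }
})

test_that("localization: peak, thresholded region, centroid", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)) * 1e-2
  ss <- source_space(pos, matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE))

  # singleton region: centroid = peak = the only active source
  x <- c(0, 0, 2, 0)
  loc <- localize(x, ss, true_position = pos[3, ])
  expect_equal(loc$peak_position, pos[3, ])
  expect_equal(loc$centroid_position, pos[3, ])
  expect_equal(loc$peak_distance, 0)

  # two equal sources: centroid at the midpoint
  x2 <- c(1, 1, 0, 0)
  loc2 <- localize(x2, ss, true_position = pos[1, ], threshold = 0.9)
  expect_equal(loc2$centroid_position, (pos[1, ] + pos[2, ]) / 2)

  # region membership equals a brute-force threshold scan (signs ignored)
  set.seed(20)
  s <- stats::rnorm(4)
  for (thr in c(0.25, 0.5, 0.75, 1)) {
    loc3 <- localize(s, ss, threshold = thr)
    brute <- which(abs(s) >= thr * max(abs(s)))
    expect_identical(sort(loc3$region), brute)
  }
  expect_error(localize(c(0, 0, 0, 0), ss), "zero")
  expect_error(localize(x, ss, threshold = 0), "threshold")
})

test_that("target-region tagging follows curvature and area fraction", {
  r <- 0.06
  sphere <- build_icosphere(r, 3)
  H <- mesh_mean_curvature(sphere)
  expect_true(all(abs(H - 1 / r) / (1 / r) < 0.05))
  # on a sphere nothing is sulcal under a 0 threshold
  expect_error(tag_target_region(sphere, c(0, 0, r), 0), "candidate")

  cp <- build_cortex_phantom(0.06, 0.006, 6, subdivisions = 3, seed = 5)
  seed_pt <- cp$wm$face_centers[which.max(cp$wm$face_centers[, 3]), ]
  m40 <- tag_target_region(cp$wm, seed_pt, 0, 0.4)
  m100 <- tag_target_region(cp$wm, seed_pt, 0, 1)
  cand <- mesh_mean_curvature(cp$wm) < 0
  expect_identical(m100, cand)
  expect_true(all(which(m40) %in% which(cand)))

  # mask area is non-decreasing in the requested fraction
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(f)
    sum(cp$wm$face_areas[tag_target_region(cp$wm, seed_pt, 0, f)]), 0)
  expect_true(all(diff(areas) >= 0))
  expect_gte(areas[1], 0.2 * sum(cp$wm$face_areas[cand]))
})

test_that("ROC analysis matches brute-force classification", {
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc,
               1)
  # constant strengths: chance level
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))$auc,
               0.5)

  # exhaustive threshold enumeration oracle
  brute_auc <- function(s, m) {
    s <- abs(s) / max(abs(s))
    thr <- sort(unique(c(0, s, 1 + 1e-9)))
    tpr <- vapply(thr, function(t) mean(s[m] > t), 0)
    fpr <- vapply(thr, function(t) mean(s[!m] > t), 0)
    o <- order(fpr, tpr)
    fo <- c(0, fpr[o], 1); to <- c(0, tpr[o], 1)
    sum(diff(fo) * (head(to, -1) + tail(to, -1)) / 2)
  }
  s <- c(0.9, 0.4, 0.6, 0.1)
  m <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(s, m)$auc, brute_auc(s, m), tolerance = 1e-12)

  set.seed(22)
  for (i in 1:5) {
    s <- stats::runif(10)
    m <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    if (!any(m) || all(m)) next
    r <- roc_auc(s, m)
    expect_equal(r$auc, brute_auc(s, m), tolerance = 1e-12)
    # AUC invariant under strictly monotone transforms of the strengths
    expect_equal(roc_auc(s^3, m)$auc, r$auc, tolerance = 1e-12)
    # the curve is monotone
    expect_true(all(diff(r$fpr) >= -1e-12))
    expect_true(all(diff(r$tpr) >= -1e-12))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "classes")
})

test_that("error maps degrade gracefully with the noise level", {
  nm <- toy_noise_model(M = 8, K = 30, seed = 23)
  # make an exactly solvable toy: sources on a line, identity-ish inverse
  ss <- source_space(nm$positions, nm$normals)
  op <- make_inverse_operator(nm$L, lambda2 = 0.01)

  em0 <- error_map(nm, op, ss, lambda0 = 0, dipoles = 1:5)
  expect_true(all(em0$centroid_sd == 0))
  expect_true(all(em0$peak_sd == 0))

  em1 <- error_map(nm, op, ss, lambda0 = 0.3, n_samples = 20, seed = 4,
                   dipoles = 1:5)
  em2 <- error_map(nm, op, ss, lambda0 = 0.3, n_samples = 20, seed = 4,
                   dipoles = 1:5)
  expect_identical(em1, em2)
  expect_error(error_map(nm, op, ss, lambda0 = 1), "lambda0")
})
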