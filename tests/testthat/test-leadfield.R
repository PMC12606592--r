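row_cross_test <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

test_that("Sarvas field: silence, linearity, and symmetry", {
  ctr <- c(0, 0, 0)
  pos <- c(0.02, 0.01, 0.05)
  pts <- rbind(c(0, 0.05, 0.12), c(0.1, 0.02, 0.08), c(-0.07, 0.09, 0.03))

  # radial dipole is magnetically silent
  B <- sarvas_field(pos, pos / sqrt(sum(pos^2)) * 1e-8, ctr, pts)
  expect_lt(max(abs(B)), 1e-25)

  # linear and odd in the moment
  tang <- c(-pos[2], pos[1], 0) * 1e-7
  expect_equal(sarvas_field(pos, -tang, ctr, pts),
               -sarvas_field(pos, tang, ctr, pts), tolerance = 1e-14)
  expect_equal(sarvas_field(pos, 3 * tang, ctr, pts),
               3 * sarvas_field(pos, tang, ctr, pts), tolerance = 1e-14)

  # invariance under a common translation of all geometry
  sh <- c(0.01, -0.02, 0.004)
  expect_equal(sarvas_field(pos + sh, tang, ctr + sh, t(t(pts) + sh)),
               sarvas_field(pos, tang, ctr, pts), tolerance = 1e-12)
})

test_that("Sarvas matches the numerical volume-current solution", {
  # independent route: dipole-driven charge solve + Geselowitz surface
  # integral on a homogeneous sphere, evaluated at raw field points.  The
  # tangential components carry the O(h) collocation error of the surface
  # potential, so the vector-level check asserts agreement at the mesh's
  # accuracy and improvement under refinement; the sensor-level projection
  # (radial pickup normals) is tested tightly below.
  raw_B_error <- function(sub) {
    head <- precompute_nearfield(head_model(list(
      conductivity_layer(build_icosphere(0.08, sub), 0.33, 0, "brain"))))
    sigma <- 0.33
    pos <- c(0.015, -0.01, 0.045)
    mom <- c(2e-9, 1e-8, -3e-9)
    pts <- rbind(c(0, 0.02, 0.12), c(0.09, -0.03, 0.05), c(-0.06, 0.08, 0.04))
    nf <- recmeg:::head_nearfield(head, solver_config())
    rhs <- recmeg:::cpp_dipole_rhs(head$face_centers, head$face_normals,
                                   head$contrast, head$face_areas,
                                   nf$va, nf$vb, nf$vc, rbind(pos),
                                   rbind(mom), sigma, nf$radius)
    sol <- solve_charges(head, rhs[, 1], rhs = TRUE,
                         config = solver_config(gmres_rel_tol = 1e-6))
    phi <- potential_from_charges(head, sol$rho, head$face_centers) +
      as.numeric(recmeg:::cpp_dipole_phi(rbind(pos), rbind(mom), sigma,
                                         head$face_centers, head$face_areas,
                                         nf$va, nf$vb, nf$vc, nf$radius))
    W <- recmeg:::cpp_geselowitz_weights(head$face_centers, head$face_normals,
                                         head$face_areas, head$sigma_jump, pts)
    Bv <- cbind(W$x %*% phi, W$y %*% phi, W$z %*% phi)
    Bnum <- recmeg:::dipole_primary_B(pos, mom, pts) + Bv
    Bana <- sarvas_field(pos, mom, c(0, 0, 0), pts)
    norm(Bnum - Bana, "F") / norm(Bana, "F")
  }
  e2 <- raw_B_error(2)
  e3 <- raw_B_error(3)
  expect_lt(e3, 0.15)
  expect_lt(e3, e2)
})

test_that("direct columns obey the spherical-conductor oracle", {
  head <- fx_sphere1()
  arr <- fx_mags6()
  R <- 0.08
  pos <- c(0.02, 0.01, 0.052)          # ~0.7 R
  rad <- pos / sqrt(sum(pos^2))
  tang <- c(-rad[2], rad[1], 0)
  tang <- tang / sqrt(sum(tang^2)) * 1e-8

  b_dir <- direct_column(head, pos, tang, arr)
  aq <- recmeg:::array_quad(arr)
  B <- sarvas_field(pos, tang, c(0, 0, 0), aq$points)
  b_sar <- as.numeric(rowsum(rowSums(aq$wnormal * B), aq$sensor))
  expect_lt(sqrt(sum((b_dir - b_sar)^2) / sum(b_sar^2)), 0.03)

  # radial dipole of equal strength is silent relative to the tangential one
  b_rad <- direct_column(head, pos, rad * 1e-8, arr)
  expect_lt(max(abs(b_rad)), 0.02 * max(abs(b_sar)))

  # zero moment, zero column
  expect_true(all(direct_column(head, pos, c(0, 0, 0), arr) == 0))

  # dipole outside the conductor is rejected
  expect_error(direct_column(head, c(0, 0, 0.2), tang, arr), "outside")
})

test_that("reciprocal rows are deterministic, linear, and maskable", {
  head <- fx_sphere1()
  arr <- fx_mags6()
  ss <- fx_sources(30)
  s1 <- arr$sensors[[1]]
  r1 <- reciprocal_row(head, s1, ss)
  r2 <- reciprocal_row(head, s1, ss)
  expect_identical(r1$row, r2$row)

  # reversing the loop current negates the row
  s_rev <- s1
  s_rev$elements$dIdt <- -s_rev$elements$dIdt
  r_rev <- reciprocal_row(head, s_rev, ss)
  expect_equal(r_rev$row, -r1$row, tolerance = 1e-10)

  # ROI mask zeroes distant sources and keeps near ones
  r_roi <- reciprocal_row(head, s1, ss, roi_radius = 0.12)
  ctr <- s1$loops[[1]]$center
  d <- sqrt(rowSums(t(t(ss$positions) - ctr)^2))
  expect_true(all(r_roi$row[d > 0.12] == 0))
  expect_equal(r_roi$row[d <= 0.12], r1$row[d <= 0.12])
})

test_that("reciprocal and direct assembly agree on a 3-sphere phantom", {
  head <- precompute_nearfield(
    build_sphere_head(c(0.09, 0.085, 0.08), c(0.25, 0.01, 0.275), k = 4,
                      names = c("skin", "skull", "brain")))
  arr <- build_helmet_array(5, shell_radius = 0.12, kinds = "magnetometer")
  ss <- fx_sources(60, rmax = 0.065, seed = 21)
  lf_r <- assemble_leadfield(head, arr, ss, "reciprocal")
  lf_d <- assemble_leadfield(head, arr, ss, "direct")
  expect_lt(norm(lf_r$matrix - lf_d$matrix, "F") / norm(lf_d$matrix, "F"),
            0.05)
  expect_identical(lf_r$n_solves, 5L)
  expect_identical(lf_d$n_solves, 60L)
  expect_identical(lf_r$method, "reciprocal")

  # per-row/column unit bookkeeping
  expect_true(all(lf_r$units == "T"))
})

test_that("analytic assembly matches the direct method on a homogeneous sphere", {
  head <- fx_sphere1()
  arr <- fx_mags6()
  set.seed(31)
  n <- 25
  u <- matrix(stats::rnorm(3 * n), ncol = 3); u <- u / sqrt(rowSums(u^2))
  pos <- u * 0.055
  # tangential orientations (spherical symmetry makes radial parts silent)
  ori <- row_cross_test(u, matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE))
  ori <- ori / sqrt(rowSums(ori^2))
  ss <- source_space(pos, ori)
  lf_a <- assemble_leadfield(head, arr, ss, "analytic")
  lf_d <- assemble_leadfield(head, arr, ss, "direct")
  expect_lt(norm(lf_a$matrix - lf_d$matrix, "F") / norm(lf_a$matrix, "F"),
            0.03)
})

test_that("duplicated sensors produce identical rows", {
  head <- fx_sphere1()
  m1 <- magnetometer(c(0, 0, 0.12), c(0, 0, 1), name = "A")
  m2 <- magnetometer(c(0, 0, 0.12), c(0, 0, 1), name = "B")
  arr <- sensor_array(list(m1, m2))
  ss <- fx_sources(15)
  lf <- assemble_leadfield(head, arr, ss, "reciprocal")
  expect_equal(lf$matrix[1, ], lf$matrix[2, ], tolerance = 1e-8)
  expect_equal(qr(lf$matrix)$rank, 1L)
})

test_that("leadfield column norms decay with source depth", {
  head <- fx_sphere1()
  arr <- fx_mags6()
  radii <- c(0.07, 0.055, 0.04, 0.025)
  pos <- t(vapply(radii, function(r) c(0, r / sqrt(2), r / sqrt(2)),
                  numeric(3)))
  ori <- matrix(rep(c(1, 0, 0), 4), ncol = 3, byrow = TRUE)
  lf <- assemble_leadfield(head, arr, source_space(pos, ori), "direct")
  w <- sqrt(colSums(lf$matrix^2))
  expect_true(all(diff(w) < 0))
})

test_that("leadfield containers round-trip and detect tampering", {
  m <- matrix(stats::rnorm(12), 3, 4)
  lf <- structure(list(matrix = m, sensor_names = c("a", "b", "c"),
                       units = rep("T", 3), method = "direct",
                       config = unclass(solver_config()),
                       source_space = NULL),
                  class = "leadfield")
  p <- tempfile()
  write_leadfield(lf, p)
  lf2 <- read_leadfield(p)
  expect_identical(lf2$matrix, m)
  expect_identical(lf2$sensor_names, lf$sensor_names)
  # corrupt one byte: hash validation must fail
  raw <- readBin(p, "raw", file.size(p))
  raw[5] <- as.raw(bitwXor(as.integer(raw[5]), 255L))
  writeBin(raw, p)
  expect_error(read_leadfield(p), "hash")
  unlink(c(p, paste0(p, ".json")))
})
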