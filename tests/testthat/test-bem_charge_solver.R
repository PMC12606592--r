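test_that("right-hand side assembly projects the incident field", {
  head <- fx_sphere1()
  F <- head$total_faces
  # zero contrast kills the RHS
  h0 <- head_model(list(conductivity_layer(build_icosphere(0.08, 1),
                                           0.3, 0.3, "x")))
  E <- matrix(stats::rnorm(3 * h0$total_faces), ncol = 3)
  expect_true(all(assemble_rhs(h0, E) == 0))

  # tangential incident field (normal projection removed) gives zero
  Et <- matrix(stats::rnorm(3 * F), ncol = 3)
  Et <- Et - head$face_normals * rowSums(Et * head$face_normals)
  expect_lt(max(abs(assemble_rhs(head, Et))), 1e-12 * max(abs(Et)))

  # exact linearity
  E1 <- matrix(stats::rnorm(3 * F), ncol = 3)
  expect_identical(assemble_rhs(head, 2 * E1), 2 * assemble_rhs(head, E1))
  expect_error(assemble_rhs(head, E1[1:5, ]), "total_faces")
})

test_that("operator matches an independent dense assembly", {
  head <- fx_sphere2()   # 360 faces across two shells
  A_cpp <- recmeg:::bem_dense_operator(head)
  A_r <- oracle_dense_operator(head)
  expect_lt(max(abs(A_cpp - A_r)), 1e-12)
  # matrix-free matvec agrees with the dense matrix
  set.seed(3)
  for (i in 1:3) {
    x <- stats::rnorm(head$total_faces)
    expect_equal(apply_operator(head, x), as.numeric(A_cpp %*% x),
                 tolerance = 1e-12)
  }
})

test_that("operator degenerate cases", {
  head <- fx_sphere1()
  expect_true(all(apply_operator(head, numeric(head$total_faces)) == 0))

  # single isolated face: no interaction term, operator is the identity
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0)),
                       rbind(c(1, 2, 3)))
  h1 <- head_model(list(conductivity_layer(tri, 0.3, 0, "t")))
  expect_equal(apply_operator(h1, 2.5), 2.5, tolerance = 1e-15)
})

test_that("GMRES solves the charge equation to tolerance", {
  head <- fx_sphere2()
  arr <- fx_mags6()
  Einc <- primary_E(arr$sensors[[1]]$elements, head$face_centers)

  sol <- solve_charges(head, Einc)
  expect_lte(utils::tail(sol$residual_history, 1), 1e-4)
  expect_true(all(diff(sol$residual_history) <= 1e-15))

  # matches the dense direct solve
  A <- recmeg:::bem_dense_operator(head)
  rho_dense <- recmeg:::project_neutral(head, solve(A, assemble_rhs(head, Einc)))
  expect_lt(sqrt(sum((sol$rho - rho_dense)^2) / sum(rho_dense^2)), 1e-3)

  # per-interface charge neutrality
  for (nm in head$layer_names) {
    i <- layer_faces(head, nm)
    q <- head$face_areas[i] * sol$rho[i]
    expect_lt(abs(sum(q)) / sum(abs(q)), 1e-3)
  }

  # zero field and zero contrast both give the zero solution
  s0 <- solve_charges(head, 0 * Einc)
  expect_identical(s0$iterations, 0L)
  expect_true(all(s0$rho == 0))
  h0 <- precompute_nearfield(head_model(list(
    conductivity_layer(build_icosphere(0.08, 2), 0.3, 0.3, "u"))))
  su <- solve_charges(h0, matrix(1, h0$total_faces, 3))
  expect_true(all(su$rho == 0))
})

test_that("charge solves are linear in the incident field", {
  head <- fx_sphere2()
  F <- head$total_faces
  set.seed(4)
  E1 <- matrix(stats::rnorm(3 * F), ncol = 3)
  E2 <- matrix(stats::rnorm(3 * F), ncol = 3)
  r12 <- solve_charges(head, 0.3 * E1 + 1.7 * E2)$rho
  r1 <- solve_charges(head, E1)$rho
  r2 <- solve_charges(head, E2)$rho
  expect_lt(sqrt(sum((r12 - 0.3 * r1 - 1.7 * r2)^2) / sum(r12^2)), 5e-4)
})

test_that("non-convergence raises an error carrying the residual history", {
  head <- fx_sphere2()
  arr <- fx_mags6()
  Einc <- primary_E(arr$sensors[[1]]$elements, head$face_centers)
  cfg <- solver_config(gmres_rel_tol = 1e-12, max_iterations = 2)
  err <- tryCatch(solve_charges(head, Einc, cfg), error = function(e) e)
  expect_s3_class(err, "recmeg_gmres_error")
  expect_length(err$residual_history, 2L)
})

test_that("single-layer potential recovers the charged-sphere closed form", {
  head <- fx_sphere1()
  F <- head$total_faces
  expect_true(all(potential_from_charges(head, numeric(F),
                                         rbind(c(0, 0, 0.2))) == 0))
  # uniformly charged sphere: phi(r) = (total area * g) / (2 pi r) outside
  g0 <- 4.2
  d <- 0.2
  phi <- potential_from_charges(head, rep(g0, F), rbind(c(0, 0, d)))
  A_tot <- sum(head$face_areas)
  expect_equal(phi, A_tot * g0 / (2 * pi * d), tolerance = 1e-3)

  # neutral distribution decays faster than a monopole
  set.seed(5)
  g <- stats::rnorm(F)
  g <- g - sum(g * head$face_areas) / sum(head$face_areas)
  p1 <- potential_from_charges(head, g, rbind(c(0, 0, 0.3)))
  p2 <- potential_from_charges(head, g, rbind(c(0, 0, 0.6)))
  expect_lt(abs(p2) / abs(p1), 0.5 * 0.9)   # clearly beyond 1/d
})

test_that("total field reduces to the incident field without charges", {
  head <- fx_sphere1()
  pts <- rbind(c(0.01, 0, 0), c(0, 0.02, 0.01))
  Ei <- matrix(c(1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  expect_identical(E_total_at_points(head, numeric(head$total_faces), Ei, pts),
                   Ei)
})

test_that("interior field of a sphere in a uniform field matches the closed form", {
  si <- 0.275; so <- 0.1
  head <- precompute_nearfield(head_model(list(
    conductivity_layer(build_icosphere(0.08, 4), si, so, "s"))))
  F <- head$total_faces
  E0 <- matrix(rep(c(0, 0, 1), each = F), ncol = 3)
  sol <- solve_charges(head, E0)
  pts <- rbind(c(0, 0, 0), c(0.02, 0.01, -0.015), c(-0.03, 0.02, 0.01))
  Et <- E_total_at_points(head, sol$rho,
                          matrix(rep(c(0, 0, 1), each = 3), ncol = 3), pts)
  pred <- 3 * so / (si + 2 * so)
  expect_equal(Et[, 3], rep(pred, 3), tolerance = 0.02)
  expect_lt(max(abs(Et[, 1:2])), 0.02 * pred)

  # divergence-free interior: central-difference divergence probe
  h <- 1e-3
  probe <- rbind(c(h, 0, 0), c(-h, 0, 0), c(0, h, 0), c(0, -h, 0),
                 c(0, 0, h), c(0, 0, -h))
  Ein <- matrix(rep(c(0, 0, 1), each = 6), ncol = 3)
  Ep <- E_total_at_points(head, sol$rho, Ein, probe)
  div <- (Ep[1, 1] - Ep[2, 1] + Ep[3, 2] - Ep[4, 2] + Ep[5, 3] - Ep[6, 3]) /
    (2 * h)
  expect_lt(abs(div) * h / max(abs(Ep)), 1e-6)
})

test_that("normal E from charge equals the field side limit", {
  head <- fx_sphere2_fine()
  arr <- fx_mags6()
  Einc <- primary_E(arr$sensors[[2]]$elements, head$face_centers)
  sol <- solve_charges(head, Einc)

  # coefficient from the conductivity pair (WM/GM values): -0.8456
  hw <- head_model(list(
    conductivity_layer(build_icosphere(0.06, 1), 0.126, 0.275, "wm")))
  coef <- unique(normal_E_from_charge(hw, rep(1, hw$total_faces), "wm",
                                      "outside")) / 2
  expect_equal(coef, 0.126 / (0.126 - 0.275), tolerance = 1e-12)
  expect_equal(round(coef, 4), -0.8456)

  # side-limit oracle: offset evaluation along the normal on the inner shell
  idx <- layer_faces(head, "brain")
  nE <- normal_E_from_charge(head, sol$rho, "brain", "outside")
  off <- head$face_centers[idx, ] +
    0.1 * sqrt(mean(head$face_areas)) * head$face_normals[idx, ]
  Eo <- E_total_at_points(head, sol$rho,
                          primary_E(arr$sensors[[2]]$elements, off), off)
  nEo <- rowSums(Eo * head$face_normals[idx, ])
  expect_lt(sqrt(sum((nE - nEo)^2) / sum(nEo^2)), 0.03)

  # inside limit obeys current continuity: sigma_in nE_in = sigma_out nE_out
  nEi <- normal_E_from_charge(head, sol$rho, "brain", "inside")
  expect_equal(0.275 * nEi, 0.25 * nE, tolerance = 1e-12)

  expect_error(normal_E_from_charge(hw, rep(1, 20), "nope"), "unknown")
  h0 <- head_model(list(conductivity_layer(build_icosphere(0.08, 1),
                                           0.3, 0.3, "u")))
  expect_error(normal_E_from_charge(h0, rep(1, h0$total_faces), "u"),
               "zero-contrast")
})

test_that("solver configuration is validated", {
  expect_error(solver_config(gmres_rel_tol = 2), "gmres_rel_tol")
  expect_error(solver_config(max_iterations = 0), "max_iterations")
  expect_error(solver_config(backend = "fast_summation"), "backend")
})
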