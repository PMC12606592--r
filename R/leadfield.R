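#' Sarvas closed-form field of a dipole in a spherical conductor
#'
#' Magnetic field outside a spherically symmetric conductor produced by a
#' current dipole inside it.  Independent of the (radial) conductivity
#' profile; radial dipoles are magnetically silent.  Serves as the analytic
#' oracle for the numerical forward solvers.
#'
#' @param dipole_position dipole location (m), relative to global origin.
#' @param dipole_moment dipole moment vector (A.m).
#' @param sphere_center conductor center (m).
#' @param points P x 3 field points, strictly outside the conductor.
#' @return P x 3 matrix of B (T).
#' @export
sarvas_field <- function(dipole_position, dipole_moment, sphere_center,
                         points) {
  points <- rbind(points)
  r0 <- dipole_position - sphere_center
  q <- dipole_moment
  out <- matrix(0, nrow(points), 3)
  qxr0 <- cross3(q, r0)
  for (i in seq_len(nrow(points))) {
    r <- points[i, ] - sphere_center
    a <- r - r0
    an <- sqrt(sum(a^2)); rn <- sqrt(sum(r^2))
    Fv <- an * (rn * an + rn^2 - sum(r0 * r))
    if (abs(Fv) < 1e-300) stop("degenerate geometry (F = 0) in Sarvas formula")
    gradF <- (an^2 / rn + sum(a * r) / an + 2 * an + 2 * rn) * r -
      (an + 2 * rn + sum(a * r) / an) * r0
    out[i, ] <- 1e-7 / Fv^2 * (Fv * qxr0 - sum(qxr0 * r) * gradF)
  }
  out
}

# point-in-mesh test by summed solid angle (van Oosterom & Strackee)
point_in_mesh <- function(mesh, p) {
  v <- mesh$vertices; f <- mesh$faces
  a <- t(t(v[f[, 1], , drop = FALSE]) - p)
  b <- t(t(v[f[, 2], , drop = FALSE]) - p)
  c3 <- t(t(v[f[, 3], , drop = FALSE]) - p)
  la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c3^2))
  num <- rowSums(a * row_cross(b, c3))
  den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * c3) * lb +
    rowSums(b * c3) * la
  abs(sum(2 * atan2(num, den))) > 2 * pi
}

# Global flux-combination weights for a sensor array: for each quadrature
# point, weight * loop normal * per-kind scale, plus the owning sensor index.
array_quad <- function(sensors) {
  pts <- list(); wn <- list(); idx <- list()
  for (i in seq_along(sensors$sensors)) {
    s <- sensors$sensors[[i]]
    scale <- if (s$kind == "magnetometer") 1 / s$area
             else 1 / (s$area * s$baseline)
    sgn <- ifelse(s$quad_loop == 1, 1, -1)
    nrm <- do.call(rbind, lapply(s$quad_loop, function(l) s$loops[[l]]$normal))
    pts[[i]] <- s$quad_points
    wn[[i]] <- nrm * (s$quad_weights * sgn * scale)
    idx[[i]] <- rep(i, nrow(s$quad_points))
  }
  list(points = do.call(rbind, pts), wnormal = do.call(rbind, wn),
       sensor = unlist(idx))
}

dipole_primary_B <- function(dip_pos, dip_mom, points) {
  # (mu0/4pi) m x (r - r0) / |r - r0|^3, P x 3
  d <- t(t(points) - dip_pos)
  r3 <- (sqrt(rowSums(d^2)))^3
  m <- matrix(dip_mom, nrow(points), 3, byrow = TRUE)
  1e-7 * row_cross(m, d) / r3
}

#' One reciprocal leadfield row
#'
#' Drives a single sensor as an induction coil (unit dI/dt, gradiometer
#' loops in opposition), solves the charge equation for the whole head, and
#' reads the leadfield row as the projection of the total E-field onto the
#' source orientations.  Two read-outs are available: the charge shortcut
#' (normal E just outside a contrast-carrying cortical surface, no secondary
#' field evaluation) and the general total-field path valid for arbitrary
#' source positions and orientations.
#'
#' @param head a [head_model()].
#' @param sensor a `sensor`.
#' @param source_space a `source_space`.
#' @param config a [solver_config()].
#' @param path `"charge"` (requires `cortical_surface` with one source per
#'   face) or `"field"`.
#' @param cortical_surface layer name carrying the source space (charge path).
#' @param roi_radius field-path evaluation mask: sources farther than this
#'   from the sensor centroid are assigned 0 without evaluation (the induced
#'   E-field decays as inverse distance squared, so a 7 cm radius captures
#'   the non-negligible entries); default `Inf` (no mask).
#' @return list with `row` (length N, sensor units per unit dipole moment)
#'   and `solution` (the `charge_solution`).
#' @export
reciprocal_row <- function(head, sensor, source_space,
                           config = solver_config(),
                           path = c("field", "charge"),
                           cortical_surface = NULL, roi_radius = Inf) {
  path <- match.arg(path)
  # With coil current I(t) = I0 cos(wt), dI/dt = -I0 w sin(wt); the in-phase
  # reciprocal field is therefore minus the field chain computed at
  # dI/dt = +1, hence the negative scale.
  scale <- if (sensor$kind == "magnetometer") -1 / sensor$area
           else -1 / (sensor$area * sensor$baseline)
  Einc <- primary_E(sensor$elements, head$face_centers)
  sol <- solve_charges(head, Einc, config)
  if (path == "charge") {
    if (is.null(cortical_surface))
      stop("charge path requires cortical_surface")
    nE <- normal_E_from_charge(head, sol$rho, cortical_surface, "outside")
    if (length(nE) != nrow(source_space$positions))
      stop("charge path needs one source per cortical face")
    row <- nE[source_space$parent_face] * scale
  } else {
    keep <- if (is.finite(roi_radius)) {
      centroid <- colMeans(do.call(rbind, lapply(sensor$loops, `[[`, "center")))
      sqrt(rowSums(t(t(source_space$positions) - centroid)^2)) <= roi_radius
    } else rep(TRUE, nrow(source_space$positions))
    row <- numeric(nrow(source_space$positions))
    if (any(keep)) {
      pts <- source_space$positions[keep, , drop = FALSE]
      Ei_src <- primary_E(sensor$elements, pts)
      Etot <- E_total_at_points(head, sol$rho, Ei_src, pts, config)
      row[keep] <- rowSums(Etot * source_space$normals[keep, , drop = FALSE]) *
        scale
    }
  }
  list(row = row, solution = sol)
}

# Batched direct (column-wise) forward: sensor outputs for N unit dipoles.
# One dense LU when the model is small enough, otherwise per-dipole GMRES.
direct_forward <- function(head, sensors, dip_pos, dip_mom, source_sigma,
                           config = solver_config()) {
  dip_pos <- rbind(dip_pos); dip_mom <- rbind(dip_mom)
  N <- nrow(dip_pos)
  sig <- rep_len(source_sigma, N)
  nf <- head_nearfield(head, config)
  rhs <- cpp_dipole_rhs(head$face_centers, head$face_normals, head$contrast,
                        head$face_areas, nf$va, nf$vb, nf$vc,
                        dip_pos, dip_mom, sig, nf$radius)
  if (head$total_faces <= config$dense_threshold) {
    A <- bem_dense_operator(head, config)
    G <- solve(A, rhs)
    rm(A)
    G <- apply(G, 2, function(g) project_neutral(head, g))
  } else {
    G <- matrix(0, head$total_faces, N)
    for (d in seq_len(N))
      G[, d] <- solve_charges(head, rhs[, d], config, rhs = TRUE)$rho
  }
  # total surface potential: single layer of charges + primary dipole term
  S <- cpp_single_layer_dense(head$face_centers, head$face_areas, nf$va, nf$vb, nf$vc, head$face_centers, nf$radius)
  Phi <- S %*% G + cpp_dipole_phi(dip_pos, dip_mom, sig, head$face_centers,
                                  head$face_areas, nf$va, nf$vb, nf$vc,
                                  nf$radius)
  rm(S)
  aq <- array_quad(sensors)
  W <- cpp_geselowitz_weights(head$face_centers, head$face_normals,
                              head$face_areas, head$sigma_jump, aq$points)
  Bx <- W$x %*% Phi; By <- W$y %*% Phi; Bz <- W$z %*% Phi
  rm(W)
  for (d in seq_len(N)) {
    B0 <- dipole_primary_B(dip_pos[d, ], dip_mom[d, ], aq$points)
    Bx[, d] <- Bx[, d] + B0[, 1]
    By[, d] <- By[, d] + B0[, 2]
    Bz[, d] <- Bz[, d] + B0[, 3]
  }
  contrib <- aq$wnormal[, 1] * Bx + aq$wnormal[, 2] * By + aq$wnormal[, 3] * Bz
  out <- rowsum(contrib, aq$sensor)
  out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' One direct leadfield column
#'
#' Classical dipole-to-sensor forward: primary dipole field plus the
#' volume-current contribution from the Geselowitz surface formula, with the
#' interface potentials obtained from the dipole-driven charge solution;
#' sensor outputs by flux quadrature.
#'
#' @param head a [head_model()].
#' @param dipole_position dipole location (m), strictly inside the conductor.
#' @param dipole_moment dipole moment (A.m).
#' @param sensors a [sensor_array()].
#' @param config a [solver_config()].
#' @param source_sigma conductivity of the compartment containing the dipole
#'   (S/m); default: innermost layer's `sigma_in`.
#' @param min_quad_distance minimum allowed distance from the dipole to any
#'   sensor flux point (m), default 5 mm.
#' @return length-M numeric vector of sensor outputs.
#' @export
direct_column <- function(head, dipole_position, dipole_moment, sensors,
                          config = solver_config(), source_sigma = NULL,
                          min_quad_distance = 5e-3) {
  inner <- head$layers[[length(head$layers)]]
  if (is.null(source_sigma)) source_sigma <- inner$sigma_in
  if (!point_in_mesh(head$layers[[1]]$mesh, dipole_position))
    stop("dipole lies outside the conductor")
  aq <- array_quad(sensors)
  dmin <- sqrt(min(rowSums(t(t(aq$points) - dipole_position)^2)))
  if (dmin < min_quad_distance)
    stop("dipole too close to sensor flux points")
  as.numeric(direct_forward(head, sensors, dipole_position, dipole_moment,
                            source_sigma, config))
}

#' Assemble the gain (leadfield) matrix
#'
#' `method = "reciprocal"` fills the matrix row-wise with one charge solve
#' per sensor (M solves); `"direct"` fills it column-wise with one
#' dipole-driven solve per source (N solves); `"analytic"` uses the Sarvas
#' closed form (homogeneous spherical conductor centered at the origin).
#' Rows are stored for unit dipole moment (1 A.m) and unit dI/dt;
#' magnetometer rows are in T, gradiometer rows in T/m.
#'
#' @param head a [head_model()] (ignored for `"analytic"`).
#' @param sensors a [sensor_array()].
#' @param source_space a `source_space`.
#' @param method `"reciprocal"`, `"direct"` or `"analytic"`.
#' @param config a [solver_config()].
#' @param cortical_surface layer name for the reciprocal charge shortcut;
#'   when `NULL` the general total-field path is used.
#' @param source_sigma compartment conductivity at the sources (direct
#'   method); defaults to the layer just outside `cortical_surface` if
#'   given, else the innermost `sigma_in`.
#' @param progress print per-row/column progress.
#' @return object of class `leadfield`: `matrix` (M x N), `sensor_names`,
#'   `units`, `method`, `n_solves`, `source_space`, `config`.
#' @export
assemble_leadfield <- function(head, sensors, source_space,
                               method = c("reciprocal", "direct", "analytic"),
                               config = solver_config(),
                               cortical_surface = NULL, source_sigma = NULL,
                               progress = FALSE) {
  method <- match.arg(method)
  M <- length(sensors$sensors)
  N <- nrow(source_space$positions)
  units <- vapply(sensors$sensors, function(s)
    if (s$kind == "magnetometer") "T" else "T/m", "")
  n_solves <- 0L
  if (method == "reciprocal") {
    head <- precompute_nearfield(head, config)
    L <- matrix(0, M, N)
    path <- if (is.null(cortical_surface)) "field" else "charge"
    for (i in seq_len(M)) {
      rr <- tryCatch(
        reciprocal_row(head, sensors$sensors[[i]], source_space, config,
                       path = path, cortical_surface = cortical_surface),
        error = function(e)
          stop("reciprocal row failed for sensor ",
               sensors$names[i], ": ", conditionMessage(e)))
      L[i, ] <- rr$row
      n_solves <- n_solves + 1L
      if (progress)
        message(sprintf("row %d/%d (%s): %d GMRES iterations", i, M,
                        sensors$names[i], rr$solution$iterations))
    }
  } else if (method == "direct") {
    head <- precompute_nearfield(head, config)
    if (is.null(source_sigma)) {
      source_sigma <- if (!is.null(cortical_surface))
        head$layers[[match(cortical_surface, head$layer_names)]]$sigma_out
      else head$layers[[length(head$layers)]]$sigma_in
    }
    L <- direct_forward(head, sensors, source_space$positions,
                        source_space$normals, source_sigma, config)
    n_solves <- N
  } else {
    aq <- array_quad(sensors)
    L <- matrix(0, M, N)
    for (j in seq_len(N)) {
      B <- sarvas_field(source_space$positions[j, ], source_space$normals[j, ],
                        c(0, 0, 0), aq$points)
      L[, j] <- rowsum(rowSums(aq$wnormal * B), aq$sensor)
    }
  }
  structure(list(matrix = L, sensor_names = sensors$names, units = units,
                 method = method, n_solves = n_solves,
                 source_space = source_space,
                 config = unclass(config)),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("leadfield (%s): %d sensors x %d sources, %d solves\n",
              x$method, nrow(x$matrix), ncol(x$matrix), x$n_solves))
  invisible(x)
}
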