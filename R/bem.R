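#' Solver configuration for the charge-based BEM
#'
#' @param gmres_rel_tol GMRES relative residual tolerance (default 1e-4).
#' @param matvec_precision required agreement between matvec backends.
#' @param neighbor_radius_factor near-field correction radius as a multiple
#'   of sqrt(mean face area); default 2.
#' @param max_iterations GMRES iteration cap (restart-free), default 60.
#' @param backend `"direct"` (dense pairwise summation) — the fast-summation
#'   slot is a pluggable matvec contract, not implemented here.
#' @param dense_threshold face count up to which batched column-wise assembly
#'   may use one dense LU factorization instead of per-dipole GMRES.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(gmres_rel_tol = 1e-4, matvec_precision = 1e-4,
                          neighbor_radius_factor = 2, max_iterations = 60,
                          backend = c("direct", "fast_summation"),
                          dense_threshold = 9000) {
  stopifnot(gmres_rel_tol > 0, gmres_rel_tol < 1, max_iterations >= 1)
  backend <- match.arg(backend)
  if (backend == "fast_summation")
    stop("no fast-summation backend is configured; use backend = 'direct'")
  structure(list(gmres_rel_tol = gmres_rel_tol,
                 matvec_precision = matvec_precision,
                 neighbor_radius_factor = neighbor_radius_factor,
                 max_iterations = max_iterations,
                 backend = backend,
                 dense_threshold = dense_threshold),
            class = "solver_config")
}

# Cached near-field geometry for a head model: face corner coordinates for
# the subdivision quadrature and the neighbor radius.
head_nearfield <- function(head, config) {
  if (!is.null(head$.nearfield) &&
      identical(head$.nearfield$factor, config$neighbor_radius_factor))
    return(head$.nearfield)
  co <- lapply(head$layers, function(l) mesh_corners(l$mesh))
  list(va = do.call(rbind, lapply(co, `[[`, "a")),
       vb = do.call(rbind, lapply(co, `[[`, "b")),
       vc = do.call(rbind, lapply(co, `[[`, "c")),
       radius = config$neighbor_radius_factor * sqrt(mean(head$face_areas)),
       factor = config$neighbor_radius_factor)
}

#' Attach cached near-field geometry to a head model
#'
#' Precomputes the subdivision quadrature used for near-field corrections so
#' repeated solves on the same model do not rebuild it.
#' @param head a [head_model()].
#' @param config a [solver_config()].
#' @return the head model with a `.nearfield` cache attached.
#' @export
precompute_nearfield <- function(head, config = solver_config()) {
  head$.nearfield <- head_nearfield(head, config)
  head
}

#' Right-hand side of the charge equation
#'
#' In the solver's charge units (g = rho / (2 eps0), V/m) the collocation
#' right-hand side at face n is `K_n * n_n . E_inc(r_n)`.
#'
#' @param head a [head_model()].
#' @param E_incident F x 3 incident field at the face centers (V/m).
#' @return length-F numeric vector.
#' @export
assemble_rhs <- function(head, E_incident) {
  E_incident <- as.matrix(E_incident)
  if (nrow(E_incident) != head$total_faces || ncol(E_incident) != 3)
    stop("E_incident must be total_faces x 3")
  head$contrast * rowSums(head$face_normals * E_incident)
}

#' Apply the charge-interaction operator
#'
#' Computes `(I - D) g` where `D g |_n = K_n n_n . sum_{m != n} A_m g_m
#' (r_n - r_m) / (2 pi |r_n - r_m|^3)`, with faces inside the neighbor
#' radius integrated by subdivided quadrature.  This is the matrix-free
#' matvec used by GMRES.
#'
#' @param head a [head_model()].
#' @param rho per-face charge density in solver units (g = rho / 2 eps0).
#' @param config a [solver_config()].
#' @return length-F numeric vector.
#' @export
apply_operator <- function(head, rho, config = solver_config()) {
  if (length(rho) != head$total_faces) stop("rho length mismatch")
  nf <- head_nearfield(head, config)
  as.numeric(
    cpp_bem_matvec(head$face_centers, head$face_normals, head$face_areas,
                   head$contrast, nf$va, nf$vb, nf$vc, rho, nf$radius))
}

# Dense operator matrix (I - D); used by the dense-solve path and as an
# oracle against the matrix-free matvec.
bem_dense_operator <- function(head, config = solver_config()) {
  nf <- head_nearfield(head, config)
  cpp_bem_dense(head$face_centers, head$face_normals, head$face_areas,
                head$contrast, nf$va, nf$vb, nf$vc, nf$radius)
}

#' Solve for the induced surface charge
#'
#' Restart-free GMRES on the charge integral equation, with the first-order
#' approximation (the right-hand side itself) as initial iterate.  The
#' relative residual history is recorded; failure to reach
#' `config$gmres_rel_tol` within `config$max_iterations` is an error carrying
#' the history.
#'
#' @param head a [head_model()].
#' @param E_incident F x 3 incident E-field at face centers, or a
#'   precomputed right-hand-side vector of length F (`rhs = TRUE`).
#' @param config a [solver_config()].
#' @param rhs set `TRUE` when `E_incident` is already the assembled RHS.
#' @param enforce_neutrality project out the net charge of every closed
#'   interface after the solve (default `TRUE`).  The continuum solution
#'   carries zero total charge per interface; the collocation discretization
#'   leaves a spurious monopole component which has no effect on interior
#'   fields (shell theorem) but pollutes exterior potentials.
#' @return object of class `charge_solution`: `rho` (solver charge units,
#'   g = rho/(2 eps0), V/m), `residual_history`, `iterations`.
#' @export
solve_charges <- function(head, E_incident, config = solver_config(),
                          rhs = FALSE, enforce_neutrality = TRUE) {
  b <- if (rhs) as.numeric(E_incident) else assemble_rhs(head, E_incident)
  nf <- head_nearfield(head, config)
  matvec <- function(x)
    as.numeric(
      cpp_bem_matvec(head$face_centers, head$face_normals, head$face_areas,
                     head$contrast, nf$va, nf$vb, nf$vc, x, nf$radius))
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0)
    return(structure(list(rho = b, residual_history = numeric(0),
                          iterations = 0L), class = "charge_solution"))
  out <- gmres(matvec, b, x0 = b, tol = config$gmres_rel_tol,
               maxit = config$max_iterations)
  if (!out$converged) {
    cond <- structure(class = c("recmeg_gmres_error", "error", "condition"),
                      list(message = sprintf(
                        "GMRES did not reach %g in %d iterations (final %g)",
                        config$gmres_rel_tol, config$max_iterations,
                        utils::tail(out$res, 1)),
                        call = sys.call(), residual_history = out$res))
    stop(cond)
  }
  rho <- out$x
  if (enforce_neutrality) rho <- project_neutral(head, rho)
  structure(list(rho = rho, residual_history = out$res,
                 iterations = length(out$res)),
            class = "charge_solution")
}

# Remove the area-weighted mean charge of each (closed) interface.
project_neutral <- function(head, rho) {
  for (i in seq_along(head$layers)) {
    f <- which(head$face_layer == i)
    a <- head$face_areas[f]
    rho[f] <- rho[f] - sum(a * rho[f]) / sum(a)
  }
  rho
}

#' @export
print.charge_solution <- function(x, ...) {
  cat(sprintf("charge_solution: %d faces, %d iterations, final residual %.3g\n",
              length(x$rho), x$iterations,
              if (length(x$residual_history)) utils::tail(x$residual_history, 1)
              else 0))
  invisible(x)
}

# Restart-free GMRES with Arnoldi + Givens rotations.  Returns relative
# residuals (non-increasing by construction).
gmres <- function(matvec, b, x0, tol, maxit) {
  bnorm <- sqrt(sum(b^2))
  r0 <- b - matvec(x0)
  beta <- sqrt(sum(r0^2))
  if (beta / bnorm <= tol)
    return(list(x = x0, res = beta / bnorm, converged = TRUE))
  n <- length(b)
  V <- matrix(0, n, maxit + 1)
  H <- matrix(0, maxit + 1, maxit)
  cs <- sn <- numeric(maxit)
  g <- numeric(maxit + 1)
  V[, 1] <- r0 / beta
  g[1] <- beta
  res <- numeric(0)
  k_used <- 0
  for (k in seq_len(maxit)) {
    w <- matvec(V[, k])
    for (i in seq_len(k)) {            # modified Gram-Schmidt
      H[i, k] <- sum(w * V[, i])
      w <- w - H[i, k] * V[, i]
    }
    H[k + 1, k] <- sqrt(sum(w^2))
    if (H[k + 1, k] > 1e-300) V[, k + 1] <- w / H[k + 1, k]
    for (i in seq_len(k - 1)) {        # previous Givens rotations
      t <- cs[i] * H[i, k] + sn[i] * H[i + 1, k]
      H[i + 1, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1, k]
      H[i, k] <- t
    }
    d <- sqrt(H[k, k]^2 + H[k + 1, k]^2)
    cs[k] <- H[k, k] / d; sn[k] <- H[k + 1, k] / d
    H[k, k] <- d; H[k + 1, k] <- 0
    g[k + 1] <- -sn[k] * g[k]
    g[k] <- cs[k] * g[k]
    res <- c(res, abs(g[k + 1]) / bnorm)
    k_used <- k
    if (abs(g[k + 1]) / bnorm <= tol) break
  }
  y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                 g[seq_len(k_used)])
  x <- x0 + V[, seq_len(k_used), drop = FALSE] %*% y
  list(x = as.numeric(x), res = res,
       converged = utils::tail(res, 1) <= tol)
}

#' Single-layer potential of the surface charges
#'
#' `phi(r) = sum_m A_m g_m / (2 pi |r - r_m|)` (solver charge units), with
#' subdivided quadrature for faces near the evaluation point.  Evaluating at
#' a charged face's own center is near-field corrected automatically.
#'
#' @param head a [head_model()].
#' @param rho solver-unit charge density (length F).
#' @param points P x 3 evaluation points.
#' @param config a [solver_config()].
#' @return length-P potential (V).
#' @export
potential_from_charges <- function(head, rho, points,
                                   config = solver_config()) {
  nf <- head_nearfield(head, config)
  S <- cpp_single_layer_dense(head$face_centers, head$face_areas, nf$va, nf$vb, nf$vc, rbind(points), nf$radius)
  as.numeric(S %*% rho)
}

#' Total E-field at points
#'
#' `E = E_incident + E_secondary`, the secondary field being the Coulomb
#' field of the induced charges.
#'
#' @param head a [head_model()].
#' @param rho solver-unit charge density.
#' @param E_incident P x 3 incident field at `points`.
#' @param points P x 3 evaluation points (off the charged faces, or within
#'   the near-field rule).
#' @param config a [solver_config()].
#' @return P x 3 matrix of E (V/m).
#' @export
E_total_at_points <- function(head, rho, E_incident, points,
                              config = solver_config()) {
  nf <- head_nearfield(head, config)
  E_incident + cpp_coulomb_E(head$face_centers, head$face_areas, nf$va, nf$vb, nf$vc, rho, rbind(points), nf$radius)
}

#' Normal E-field on an interface directly from the charge density
#'
#' Side limits of the normal total E-field at an interface follow from the
#' jump conditions (n.E jump = rho/eps0, current continuity):
#' \deqn{n \cdot E_{out} = \frac{\sigma_-}{\sigma_- - \sigma_+} \rho/\epsilon_0, \qquad
#'       n \cdot E_{in} = \frac{\sigma_+}{\sigma_- - \sigma_+} \rho/\epsilon_0,}
#' so no secondary-field evaluation is needed.  In solver charge units
#' `rho/eps0 = 2 g`.
#'
#' @param head a [head_model()].
#' @param rho solver-unit charge density (length F, full model).
#' @param surface layer name; must have nonzero conductivity contrast.
#' @param side `"outside"` (default) or `"inside"` limit.
#' @return per-face normal E on that surface (V/m).
#' @export
normal_E_from_charge <- function(head, rho, surface,
                                 side = c("outside", "inside")) {
  side <- match.arg(side)
  i <- match(surface, head$layer_names)
  if (is.na(i)) stop("unknown layer: ", surface)
  l <- head$layers[[i]]
  if (l$sigma_in == l$sigma_out)
    stop("zero-contrast surface: normal-E shortcut undefined")
  coef <- if (side == "outside") l$sigma_in / (l$sigma_in - l$sigma_out)
          else l$sigma_out / (l$sigma_in - l$sigma_out)
  coef * 2 * rho[layer_faces(head, surface)]
}
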