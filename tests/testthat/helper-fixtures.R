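# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# single-sphere homogeneous head, 320 faces
fx_sphere1 <- function() fixture("sphere1", function() {
  precompute_nearfield(head_model(list(
    conductivity_layer(build_icosphere(0.08, 2), 0.33, 0, "brain"))))
})

# two-sphere head, 180 + 180 = 360 faces (skull-like contrast)
fx_sphere2 <- function() fixture("sphere2", function() {
  precompute_nearfield(head_model(list(
    conductivity_layer(tessellate_icosphere(0.09, 3), 0.25, 0, "skin"),
    conductivity_layer(tessellate_icosphere(0.08, 3), 0.275, 0.25, "brain"))))
})

# finer two-sphere head for side-limit / field-accuracy checks
fx_sphere2_fine <- function() fixture("sphere2_fine", function() {
  precompute_nearfield(head_model(list(
    conductivity_layer(build_icosphere(0.09, 3), 0.25, 0, "skin"),
    conductivity_layer(build_icosphere(0.08, 3), 0.275, 0.25, "brain"))))
})

# small magnetometer helmet
fx_mags6 <- function() fixture("mags6", function()
  build_helmet_array(6, shell_radius = 0.12, kinds = "magnetometer"))

# mixed triplet helmet (4 sites -> 12 sensors)
fx_triplets4 <- function() fixture("triplets4", function()
  build_helmet_array(4, shell_radius = 0.12))

# random interior source space for the single sphere
fx_sources <- function(n = 50, rmax = 0.06, seed = 11) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- u * (rmax * stats::runif(n)^(1 / 3))
  ori <- matrix(stats::rnorm(3 * n), ncol = 3)
  source_space(pos, ori / sqrt(rowSums(ori^2)))
}

# Folded-cortex phantom study: 4-layer head (skin/skull/GM/WM), WM-face
# source space, 48-magnetometer helmet, reciprocal leadfield via the charge
# shortcut, and a mid-surface noise model of direct forward fields.
fx_cortex_study <- function() fixture("cortex_study", function() {
  k <- 7
  cp <- build_cortex_phantom(base_radius = 0.06, fold_amplitude = 0.006,
                             fold_frequency = 6, seed = 42, k = k)
  head <- precompute_nearfield(head_model(list(
    conductivity_layer(tessellate_icosphere(0.09, k), 0.25, 0, "skin"),
    conductivity_layer(tessellate_icosphere(0.085, k), 0.01, 0.25, "skull"),
    conductivity_layer(cp$gm, 0.275, 0.01, "gm"),
    conductivity_layer(cp$wm, 0.126, 0.275, "wm"))))
  arr <- build_helmet_array(48, shell_radius = 0.12, kinds = "magnetometer")
  ss <- source_space_from_mesh(cp$wm, shift = 5e-4)
  lf <- assemble_leadfield(head, arr, ss, "reciprocal",
                           cortical_surface = "wm")
  mid <- triangle_mesh((cp$wm$vertices + cp$gm$vertices) / 2, cp$wm$faces)
  noise <- build_noise_model(head, arr, mid, K = 400, seed = 1,
                             source_sigma = 0.275)
  dw <- depth_weights(lf, exponent = 0.25)
  op <- make_inverse_operator(lf, dw$R, NULL, select_lambda2(3))
  list(phantom = cp, head = head, sensors = arr, sources = ss, leadfield = lf,
       mid_surface = mid, noise = noise, inverse_op = op)
})

# Independent R-level dense assembly of the charge operator, replicating the
# collocation + near-field subdivision rules; oracle for the compiled path.
oracle_dense_operator <- function(head, config = solver_config()) {
  F <- head$total_faces
  ctr <- head$face_centers; nrm <- head$face_normals; ar <- head$face_areas
  co <- lapply(head$layers, function(l) {
    m <- l$mesh
    list(a = m$vertices[m$faces[, 1], , drop = FALSE],
         b = m$vertices[m$faces[, 2], , drop = FALSE],
         c = m$vertices[m$faces[, 3], , drop = FALSE])
  })
  va <- do.call(rbind, lapply(co, `[[`, "a"))
  vb <- do.call(rbind, lapply(co, `[[`, "b"))
  vc <- do.call(rbind, lapply(co, `[[`, "c"))
  nbr <- config$neighbor_radius_factor * sqrt(mean(ar))
  sub_centroids <- function(m, k) {
    pts <- NULL
    for (i in 0:(k - 1)) for (j in 0:(k - 1 - i)) {
      bu <- (3 * i + 1) / (3 * k); cu <- (3 * j + 1) / (3 * k)
      pts <- rbind(pts, va[m, ] + (vb[m, ] - va[m, ]) * bu +
                     (vc[m, ] - va[m, ]) * cu)
      if (i + j < k - 1) {
        bd <- (3 * i + 2) / (3 * k); cd <- (3 * j + 2) / (3 * k)
        pts <- rbind(pts, va[m, ] + (vb[m, ] - va[m, ]) * bd +
                       (vc[m, ] - va[m, ]) * cd)
      }
    }
    pts
  }
  A <- diag(F)
  for (n in seq_len(F)) {
    p <- ctr[n, ]
    for (m in seq_len(F)) {
      if (m == n) next
      d <- p - ctr[m, ]
      r2 <- sum(d^2)
      if (r2 >= nbr^2) {
        kern <- d * ar[m] / (2 * pi * r2^1.5)
      } else {
        k <- if (r2 < 0.36 * ar[m]) 18L else 6L
        q <- sub_centroids(m, k)
        dq <- t(p - t(q))
        rq <- sqrt(rowSums(dq^2))
        kern <- colSums(dq / (2 * pi * rq^3)) * ar[m] / k^2
      }
      A[n, m] <- -head$contrast[n] * sum(nrm[n, ] * kern)
    }
  }
  A
}

# SVD-based closed form of the regularized minimum-norm operator (oracle):
# with A = Lbar R^(1/2) = U D V^T,  Mbar = R^(1/2) V diag(d/(d^2+lambda2)) U^T.
oracle_mne_operator <- function(Lbar, R, lambda2) {
  A <- t(t(Lbar) * sqrt(R))          # M x N
  s <- svd(A)
  filt <- s$d / (s$d^2 + lambda2)
  (sqrt(R) * s$v[, seq_along(s$d), drop = FALSE]) %*%
    (filt * t(s$u[, seq_along(s$d), drop = FALSE]))
}
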