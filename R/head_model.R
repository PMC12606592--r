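#' Conductivity layer
#'
#' One closed conducting interface: a surface mesh together with the isotropic
#' conductivities just inside (`sigma_in`) and just outside (`sigma_out`) of
#' it.  Face normals point from the inside (sigma-) toward the outside
#' (sigma+) medium.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param sigma_in conductivity just inside the surface (S/m), >= 0.
#' @param sigma_out conductivity just outside (S/m), >= 0.  The outermost
#'   surface of a head model has `sigma_out = 0` (air).
#' @param name label used to address the surface in downstream calls.
#' @return object of class `conductivity_layer`.
#' @export
conductivity_layer <- function(mesh, sigma_in, sigma_out, name) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (sigma_in < 0 || sigma_out < 0) stop("conductivities must be >= 0")
  if (sigma_in == 0 && sigma_out == 0)
    stop("sigma_in and sigma_out cannot both be zero")
  structure(list(mesh = mesh, sigma_in = sigma_in, sigma_out = sigma_out,
                 name = as.character(name)),
            class = "conductivity_layer")
}

#' Multi-layer conductor head model
#'
#' Stacks conductivity layers (outermost first) into a single face-indexed
#' model.  The per-face conductivity contrast
#' \deqn{K = (\sigma_- - \sigma_+) / (\sigma_- + \sigma_+)}
#' drives the induced surface charge; it always lies in \[-1, 1\] and equals
#' +1 on the outermost surface (air outside).  Nesting is not required:
#' surfaces only need to be closed and mutually non-intersecting.
#'
#' @param layers list of [conductivity_layer()] objects, outermost first.
#' @return object of class `head_model` with concatenated per-face geometry
#'   (`face_centers`, `face_normals`, `face_areas`), contrast `K`,
#'   conductivity jump `sigma_jump` (= sigma_in - sigma_out), per-face layer
#'   index, and `total_faces`.
#' @export
head_model <- function(layers) {
  if (!length(layers)) stop("head model needs at least one layer")
  stopifnot(all(vapply(layers, inherits, TRUE, "conductivity_layer")))
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("layer names must be unique")
  nf <- vapply(layers, function(l) nrow(l$mesh$faces), 0L)
  kval <- vapply(layers, function(l)
    (l$sigma_in - l$sigma_out) / (l$sigma_in + l$sigma_out), 0)
  structure(list(
    layers = layers,
    layer_names = nm,
    face_layer = rep(seq_along(layers), nf),
    face_centers = do.call(rbind, lapply(layers, function(l) l$mesh$face_centers)),
    face_normals = do.call(rbind, lapply(layers, function(l) l$mesh$face_normals)),
    face_areas = unlist(lapply(layers, function(l) l$mesh$face_areas)),
    contrast = rep(kval, nf),
    sigma_jump = rep(vapply(layers, function(l) l$sigma_in - l$sigma_out, 0), nf),
    total_faces = sum(nf)
  ), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("head_model: %d layers, %d faces total\n",
              length(x$layers), x$total_faces))
  for (l in x$layers)
    cat(sprintf("  %-10s sigma_in %.4g  sigma_out %.4g  faces %d\n",
                l$name, l$sigma_in, l$sigma_out, nrow(l$mesh$faces)))
  invisible(x)
}

#' Faces belonging to a named layer
#' @param head a [head_model()].
#' @param name layer name.
#' @return integer vector of global face indices.
#' @export
layer_faces <- function(head, name) {
  i <- match(name, head$layer_names)
  if (is.na(i)) stop("unknown layer: ", name)
  which(head$face_layer == i)
}

#' Nested-sphere head model
#'
#' Concentric sphere phantom with per-compartment conductivities; the default
#' three-shell configuration uses the scalp/skull/brain conductivities of the
#' standard head table (0.25, 0.01, 0.275 S/m).
#'
#' @param radii strictly decreasing sphere radii (m), outermost first.
#' @param conductivities compartment conductivity inside each surface (S/m);
#'   outside the first surface is air (0 S/m).
#' @param subdivisions icosphere subdivisions (ignored when `k` is given).
#' @param k optional k-way tessellation factor (`20 k^2` faces per sphere).
#' @param names layer labels.
#' @return a [head_model()].
#' @export
build_sphere_head <- function(radii, conductivities = c(0.25, 0.01, 0.275),
                              subdivisions = 3, k = NULL,
                              names = NULL) {
  if (length(radii) != length(conductivities))
    stop("radii and conductivities must have the same length")
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (is.null(names))
    names <- paste0("layer", seq_along(radii))
  sig_out <- c(0, conductivities[-length(conductivities)])
  layers <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    mesh <- if (is.null(k)) build_icosphere(radii[i], subdivisions)
            else tessellate_icosphere(radii[i], k)
    layers[[i]] <- conductivity_layer(mesh, conductivities[i], sig_out[i], names[i])
  }
  head_model(layers)
}

#' Folded cortex phantom
#'
#' Two nested closed surfaces standing in for the white matter (WM) and gray
#' matter (GM) interfaces, produced by radial sinusoidal modulation of a
#' sphere:
#' \deqn{r(\theta, \phi) = R (1 + a \sin(k\theta + \psi_1) \sin(k\phi + \psi_2))}
#' The phases \eqn{\psi_{1,2}} are drawn from `seed`, so a fixed seed gives
#' identical meshes.  The GM surface uses the same modulation at radius
#' `base_radius + thickness`, so the shells cannot intersect.  The folding
#' produces faces of both curvature signs (gyral crowns vs sulcal valleys).
#'
#' @param base_radius WM base radius (m).
#' @param fold_amplitude modulation amplitude (m); must be < `base_radius/4`.
#' @param fold_frequency integer angular frequency of the folding.
#' @param subdivisions icosphere subdivisions (ignored when `k` given).
#' @param seed integer seed for the fold phases.
#' @param thickness GM-WM radial separation (m), default 3 mm.
#' @param k optional k-way tessellation factor.
#' @return list with `wm` and `gm` [triangle_mesh()] surfaces.
#' @export
build_cortex_phantom <- function(base_radius = 0.06, fold_amplitude = 0.006,
                                 fold_frequency = 6, subdivisions = 3,
                                 seed = 1, thickness = 0.003, k = NULL) {
  if (fold_amplitude >= base_radius / 4)
    stop("fold_amplitude must be < base_radius/4")
  rng <- local({ set.seed(seed); stats::runif(2, 0, 2 * pi) })
  fold <- function(mesh, R) {
    v <- mesh$vertices
    r <- sqrt(rowSums(v^2))
    theta <- acos(pmin(pmax(v[, 3] / r, -1), 1))
    phi <- atan2(v[, 2], v[, 1])
    mod <- 1 + (fold_amplitude / R) *
      sin(fold_frequency * theta + rng[1]) * sin(fold_frequency * phi + rng[2])
    m2 <- triangle_mesh(v * mod, mesh$faces)
    if (any(sqrt(rowSums(m2$vertices^2)) <= 0) || any(m2$face_areas <= 0) ||
        mesh_volume(m2) <= 0)
      stop("folded surface is degenerate or self-intersecting")
    m2
  }
  base_wm <- if (is.null(k)) build_icosphere(base_radius, subdivisions)
             else tessellate_icosphere(base_radius, k)
  base_gm <- if (is.null(k)) build_icosphere(base_radius + thickness, subdivisions)
             else tessellate_icosphere(base_radius + thickness, k)
  list(wm = fold(base_wm, base_radius), gm = fold(base_gm, base_radius + thickness))
}

#' Source space from a cortical mesh
#'
#' Places one dipole per face at `face_center + shift * normal`, oriented
#' along the face normal.  The small outward shift puts the sources "just
#' outside" the generating surface, where the normal E-field of the
#' reciprocal solve is read off the surface charge.
#'
#' @param cortex a [triangle_mesh()] (typically the WM surface).
#' @param shift outward shift distance (m), >= 0; default 0.5 mm.
#' @param enclosing optional [triangle_mesh()] that must still enclose the
#'   shifted positions (checked for sphere-like surfaces by radius).
#' @return object of class `source_space` with `positions`, `normals`,
#'   `areas`, `parent_face`.
#' @export
source_space_from_mesh <- function(cortex, shift = 5e-4, enclosing = NULL) {
  stopifnot(inherits(cortex, "triangle_mesh"))
  if (shift < 0) stop("shift must be >= 0")
  pos <- cortex$face_centers + shift * cortex$face_normals
  if (!is.null(enclosing)) {
    rmax <- max(sqrt(rowSums(enclosing$vertices^2)))
    if (any(sqrt(rowSums(pos^2)) >= rmax))
      stop("shift pushes sources outside the enclosing surface")
  }
  structure(list(positions = pos,
                 normals = cortex$face_normals,
                 areas = cortex$face_areas,
                 parent_face = seq_len(nrow(cortex$faces))),
            class = "source_space")
}

#' Source space from explicit dipole positions
#'
#' @param positions N x 3 matrix of dipole positions (m).
#' @param normals N x 3 matrix of unit orientations.
#' @param areas optional per-source areas (m^2); default 0.
#' @return a `source_space`.
#' @export
source_space <- function(positions, normals, areas = NULL) {
  positions <- as.matrix(positions); normals <- as.matrix(normals)
  stopifnot(ncol(positions) == 3, all(dim(positions) == dim(normals)))
  nn <- sqrt(rowSums(normals^2))
  if (any(abs(nn - 1) > 1e-8)) normals <- normals / nn
  structure(list(positions = positions, normals = normals,
                 areas = if (is.null(areas)) rep(0, nrow(positions)) else areas,
                 parent_face = rep(NA_integer_, nrow(positions))),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d dipoles\n", nrow(x$positions)))
  invisible(x)
}
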