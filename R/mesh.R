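#' Triangulated surface mesh
#'
#' Constructs a `triangle_mesh`: a face-indexed triangulated surface with
#' per-face centers, outward unit normals and areas.  All coordinates are in
#' meters.  Collocation in the boundary element solver happens at the face
#' centers, so faces (not vertices) are the primary indexing unit throughout
#' the package.
#'
#' @param vertices numeric V x 3 matrix of vertex positions (m).
#' @param faces integer F x 3 matrix of 1-based vertex indices.  Faces must be
#'   consistently oriented; for closed surfaces the orientation must be
#'   outward (positive signed volume).
#' @return An object of class `triangle_mesh` with components `vertices`,
#'   `faces`, `face_centers`, `face_normals`, `face_areas`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cr <- row_cross(b - a, c - a)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  if (any(areas <= 0)) stop("degenerate face with zero area")
  normals <- cr / (2 * areas)
  structure(list(
    vertices = vertices, faces = faces,
    face_centers = (a + b + c) / 3,
    face_normals = normals,
    face_areas = areas
  ), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, total area %.4g m^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$face_areas)))
  invisible(x)
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Signed volume of a closed triangulated surface
#'
#' Positive for outward-oriented closed surfaces.
#' @param mesh a [triangle_mesh()].
#' @return scalar volume (m^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * row_cross(b, c))) / 6
}

#' Validate a closed surface mesh
#'
#' Checks that every edge is shared by exactly two faces (edge-manifold),
#' that all areas are positive, normals are unit length, and that the signed
#' volume is positive (outward orientation).  Problems are reported, not
#' repaired.
#'
#' @param mesh a [triangle_mesh()].
#' @param closed if `TRUE` (default) require edge-manifold closedness and
#'   outward orientation.
#' @return invisibly `TRUE`; stops with a message describing the defect.
#' @export
validate_mesh <- function(mesh, closed = TRUE) {
  n2 <- rowSums(mesh$face_normals^2)
  if (any(abs(n2 - 1) > 1e-8)) stop("non-unit face normals")
  if (closed) {
    f <- mesh$faces
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    tab <- table(key)
    if (any(tab != 2))
      stop(sprintf("mesh is not edge-manifold closed: %d defective edges",
                   sum(tab != 2)))
    if (mesh_volume(mesh) <= 0)
      stop("closed surface is not outward oriented (signed volume <= 0)")
  }
  invisible(TRUE)
}

# Canonical icosahedron of circumradius 1, outward oriented.
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(1 + p^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

#' Tessellated icosahedral sphere mesh
#'
#' Splits every icosahedron edge into `k` segments (each face into `k^2`
#' sub-triangles) and projects onto the sphere, giving `20 * k^2` faces.
#' Allows mesh densities between the power-of-four counts of
#' [build_icosphere()].
#'
#' @param radius sphere radius (m), > 0.
#' @param k edge split factor, integer >= 1.
#' @return a closed outward-oriented [triangle_mesh()].
#' @export
tessellate_icosphere <- function(radius, k) {
  if (radius <= 0) stop("radius must be positive")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  ico <- icosahedron()
  verts <- list(); faces <- list()
  idx <- new.env(hash = TRUE)
  nv <- 0L
  get_idx <- function(p) {
    key <- paste(sprintf("%.12f", p), collapse = ",")
    i <- idx[[key]]
    if (is.null(i)) {
      nv <<- nv + 1L
      verts[[nv]] <<- p
      idx[[key]] <- nv
      i <- nv
    }
    i
  }
  for (fi in seq_len(nrow(ico$faces))) {
    A <- ico$vertices[ico$faces[fi, 1], ]
    B <- ico$vertices[ico$faces[fi, 2], ]
    C <- ico$vertices[ico$faces[fi, 3], ]
    grid <- matrix(0L, k + 1, k + 1)   # grid[i+1, j+1] for i + j <= k
    for (i in 0:k) for (j in 0:(k - i)) {
      p <- (A * (k - i - j) + B * i + C * j) / k
      p <- p / sqrt(sum(p^2))
      grid[i + 1, j + 1] <- get_idx(p)
    }
    for (i in 0:(k - 1)) for (j in 0:(k - 1 - i)) {
      faces[[length(faces) + 1L]] <-
        c(grid[i + 1, j + 1], grid[i + 2, j + 1], grid[i + 1, j + 2])
      if (i + j < k - 1)
        faces[[length(faces) + 1L]] <-
          c(grid[i + 2, j + 1], grid[i + 2, j + 2], grid[i + 1, j + 2])
    }
  }
  v <- do.call(rbind, verts) * radius
  triangle_mesh(v, do.call(rbind, faces))
}

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto a sphere; face count is
#' `20 * 4^subdivisions`.
#'
#' @param radius sphere radius (m), > 0.
#' @param subdivisions integer >= 0.
#' @return a closed outward-oriented [triangle_mesh()].
#' @examples
#' m <- build_icosphere(0.09, 2)
#' nrow(m$faces)  # 320
#' @export
build_icosphere <- function(radius, subdivisions) {
  if (radius <= 0) stop("radius must be positive")
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  tessellate_icosphere(radius, 2L^as.integer(subdivisions))
}

#' Discrete mean curvature per face
#'
#' Cotangent-Laplacian mean curvature estimated at vertices (barycentric
#' vertex areas) and averaged onto faces.  Sign convention: positive where
#' the surface is convex with respect to the outward normal, so a sphere of
#' radius `r` has mean curvature `1/r` everywhere; sulcal valleys of a folded
#' surface come out negative.
#'
#' @param mesh a closed [triangle_mesh()].
#' @return numeric vector of per-face mean curvature (1/m).
#' @export
mesh_mean_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  lap <- matrix(0, nv, 3)
  varea <- numeric(nv)
  corner <- function(i, j, k) {
    # cotangent at corner i of the angle subtended by edge (j,k)
    u <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    w <- v[k, , drop = FALSE] - v[i, , drop = FALSE]
    cosv <- rowSums(u * w)
    sinv <- sqrt(rowSums(row_cross(u, w)^2))
    cosv / pmax(sinv, 1e-300)
  }
  cot1 <- corner(f[, 1], f[, 2], f[, 3])
  cot2 <- corner(f[, 2], f[, 3], f[, 1])
  cot3 <- corner(f[, 3], f[, 1], f[, 2])
  add_edge <- function(i, j, cotv) {
    # edge (i,j) opposite the corner with cotangent cotv
    d <- v[i, , drop = FALSE] - v[j, , drop = FALSE]
    contrib <- d * cotv
    for (c in 1:3) {
      lap[, c] <<- lap[, c] + tabulate_sum(i, contrib[, c], nv)
      lap[, c] <<- lap[, c] - tabulate_sum(j, contrib[, c], nv)
    }
  }
  add_edge(f[, 2], f[, 3], cot1)
  add_edge(f[, 3], f[, 1], cot2)
  add_edge(f[, 1], f[, 2], cot3)
  third <- mesh$face_areas / 3
  for (c in 1:3) varea <- varea + tabulate_sum(f[, c], third, nv)
  # vertex normals (area weighted) for the sign
  vnorm <- matrix(0, nv, 3)
  for (c in 1:3) for (d in 1:3)
    vnorm[, d] <- vnorm[, d] +
      tabulate_sum(f[, c], mesh$face_normals[, d] * mesh$face_areas, nv)
  Hn <- lap / (4 * varea)           # mean curvature normal, |Hn| = |H|
  H <- sqrt(rowSums(Hn^2)) * sign(rowSums(Hn * vnorm))
  (H[f[, 1]] + H[f[, 2]] + H[f[, 3]]) / 3
}

tabulate_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Face corner coordinate matrices (each F x 3), used by the near-field
# subdivision quadrature in the compiled kernels.
mesh_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}
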