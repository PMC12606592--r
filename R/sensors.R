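#' Discretize a closed loop into current elements
#'
#' Splits a closed polygonal loop outline into `n_elements` straight current
#' elements of equal arc length.  Each element has a center, a direction
#' vector whose length equals its arc length, and a current derivative
#' `dIdt`.  For a closed loop the element directions sum to zero and the
#' direction lengths sum to the loop perimeter.
#'
#' @param outline K x 3 matrix of loop corner positions (m); the loop closes
#'   from the last corner back to the first.  Traversal order defines the
#'   loop normal by the right-hand rule.
#' @param n_elements number of elements, >= 8.
#' @param dIdt current time-derivative carried by every element (A/s).
#' @return list with `pos` (n x 3 element centers), `s` (n x 3 directions,
#'   |s_j| = arc length), `dIdt` (length-n vector).
#' @export
discretize_loop <- function(outline, n_elements, dIdt = 1) {
  outline <- as.matrix(outline)
  if (n_elements < 8) stop("n_elements must be >= 8")
  K <- nrow(outline)
  if (K < 3) stop("outline must have at least 3 corners (closed loop)")
  nxt <- c(2:K, 1)
  seg <- outline[nxt, , drop = FALSE] - outline
  slen <- sqrt(rowSums(seg^2))
  if (any(slen == 0)) stop("outline has repeated consecutive corners")
  cum <- c(0, cumsum(slen))
  per <- cum[K + 1]
  br <- seq(0, per, length.out = n_elements + 1)
  point_at <- function(t) {
    i <- findInterval(t, cum, rightmost.closed = TRUE)
    i <- pmin(i, K)
    frac <- (t - cum[i]) / slen[i]
    outline[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac
  }
  p0 <- point_at(br[-(n_elements + 1)])
  p1 <- point_at(br[-1])
  # each element may straddle a corner; subdivide at corners for exactness
  pos <- list(); svec <- list()
  for (e in seq_len(n_elements)) {
    t0 <- br[e]; t1 <- br[e + 1]
    cuts <- c(t0, cum[cum > t0 + 1e-15 & cum < t1 - 1e-15], t1)
    for (ci in seq_len(length(cuts) - 1)) {
      a <- point_at(cuts[ci]); b <- point_at(cuts[ci + 1])
      pos[[length(pos) + 1L]] <- (a + b) / 2
      svec[[length(svec) + 1L]] <- b - a
    }
  }
  pos <- do.call(rbind, pos); svec <- do.call(rbind, svec)
  list(pos = pos, s = svec, dIdt = rep(dIdt, nrow(pos)))
}

#' Primary electric field of current elements
#'
#' Quasi-static primary (free-space) E-field of a set of current elements,
#' \deqn{E(r) = -\frac{\mu_0}{4\pi} \sum_j \frac{\partial i_j}{\partial t}
#'   \frac{s_j}{|r - p_j|}.}
#' Linear in `dIdt`; falls off as 1/r.
#'
#' @param elements element list from [discretize_loop()] (fields `pos`, `s`,
#'   `dIdt`); several loops may be concatenated with [combine_elements()].
#' @param points P x 3 evaluation points (m); must not coincide with element
#'   centers.
#' @return P x 3 matrix of E values (V.s/m per unit dI/dt).
#' @export
primary_E <- function(elements, points) {
  points <- rbind(points)
  d2 <- outer(rowSums(points^2), rep(1, nrow(elements$pos))) +
    outer(rep(1, nrow(points)), rowSums(elements$pos^2)) -
    2 * points %*% t(elements$pos)
  if (min(d2) < 1e-24) stop("evaluation point coincides with an element center")
  cpp_primary_E(elements$pos, elements$s * elements$dIdt, points)
}

#' Concatenate current-element sets
#' @param ... element lists from [discretize_loop()].
#' @return a single element list.
#' @export
combine_elements <- function(...) {
  parts <- list(...)
  list(pos = do.call(rbind, lapply(parts, `[[`, "pos")),
       s = do.call(rbind, lapply(parts, `[[`, "s")),
       dIdt = unlist(lapply(parts, `[[`, "dIdt")))
}

gauss_legendre_01 <- function(n) {
  # Golub-Welsch nodes/weights on [0, 1]
  if (n == 1) return(list(x = 0.5, w = 1))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (rev(e$values) + 1) / 2, w = rev(2 * e$vectors[1, ]^2) / 2)
}

rect_loop <- function(center, u, v, w, h) {
  # CCW corners w.r.t normal n = u x v
  corners <- rbind(center + u * w / 2 + v * h / 2,
                   center - u * w / 2 + v * h / 2,
                   center - u * w / 2 - v * h / 2,
                   center + u * w / 2 - v * h / 2)
  list(corners = corners, center = center,
       normal = cross3(u, v), u = u, v = v, w = w, h = h, area = w * h)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Tensor-grid flux quadrature for a sensor
#'
#' Gauss-Legendre tensor product points on each rectangular loop, with
#' weights summing to the loop area.  Defaults follow the simulation
#' convention of 64 observation points per magnetometer and 128 (64 per
#' coil) per planar gradiometer.
#'
#' @param sensor a sensor object.
#' @param n_points points per loop; must be a perfect square.
#' @return list with `points` (P x 3), `weights` (m^2), `loop` (loop index
#'   per point).
#' @export
flux_quadrature <- function(sensor, n_points = 64) {
  g <- sqrt(n_points)
  if (g != round(g)) stop("n_points must be a perfect square")
  gl <- gauss_legendre_01(as.integer(g))
  pts <- list(); wts <- list(); lidx <- list()
  for (li in seq_along(sensor$loops)) {
    lo <- sensor$loops[[li]]
    if (lo$area <= 0) stop("degenerate zero-area loop")
    xy <- expand.grid(a = seq_len(length(gl$x)), b = seq_len(length(gl$x)))
    p <- t(vapply(seq_len(nrow(xy)), function(r) {
      lo$center + lo$u * lo$w * (gl$x[xy$a[r]] - 0.5) +
        lo$v * lo$h * (gl$x[xy$b[r]] - 0.5)
    }, numeric(3)))
    pts[[li]] <- p
    wts[[li]] <- gl$w[xy$a] * gl$w[xy$b] * lo$area
    lidx[[li]] <- rep(li, nrow(p))
  }
  list(points = do.call(rbind, pts), weights = unlist(wts),
       loop = unlist(lidx))
}

new_sensor <- function(kind, name, loops, baseline, n_elements, n_quad) {
  elems <- vector("list", length(loops))
  for (li in seq_along(loops)) {
    drive <- if (kind == "planar_gradiometer" && li == 2) -1 else 1
    elems[[li]] <- discretize_loop(loops[[li]]$corners, n_elements, dIdt = drive)
  }
  s <- structure(list(kind = kind, name = name, loops = loops,
                      baseline = baseline,
                      elements = do.call(combine_elements, elems),
                      area = loops[[1]]$area,
                      n_elements = n_elements, n_quad = n_quad),
                 class = "sensor")
  q <- flux_quadrature(s, n_quad)
  s$quad_points <- q$points; s$quad_weights <- q$weights; s$quad_loop <- q$loop
  s
}

#' Magnetometer sensor
#'
#' Square pickup loop.  Output convention: surface-averaged normal B over the
#' loop (flux divided by loop area), in tesla.
#'
#' @param center loop center (m).
#' @param normal unit loop normal.
#' @param u in-plane unit vector (first loop axis); orthogonalized against
#'   `normal`.
#' @param side loop side length (m); default 25.8 mm, a representative
#'   whole-head-array magnetometer size.
#' @param name sensor label.
#' @param n_elements current elements for the reciprocal (induction) drive.
#' @param n_quad flux quadrature points (perfect square), default 64.
#' @return a `sensor` object.
#' @export
magnetometer <- function(center, normal, u = NULL, side = 0.0258,
                         name = "MAG", n_elements = 16, n_quad = 64) {
  fr <- sensor_frame(normal, u)
  new_sensor("magnetometer", name,
             list(rect_loop(center, fr$u, fr$v, side, side)),
             baseline = NA_real_, n_elements, n_quad)
}

#' Planar gradiometer sensor
#'
#' Figure-of-eight pair of coplanar rectangular loops wound in opposition,
#' centers separated by `baseline` along the first in-plane axis.  Output
#' convention: difference of the two loop fluxes divided by loop area and
#' baseline, in T/m.
#'
#' @param center sensor center (m); loops sit at `center +- baseline/2 * u`.
#' @param normal unit loop normal (same for both loops; the opposite winding
#'   is carried by the element currents).
#' @param u in-plane unit vector along the gradient direction.
#' @param loop_w,loop_h loop dimensions (m); defaults 12 x 26 mm.
#' @param baseline center-to-center separation (m); default 16.8 mm.
#' @param name sensor label.
#' @param n_elements current elements per loop.
#' @param n_quad flux quadrature points per loop (perfect square), default 64.
#' @return a `sensor` object.
#' @export
planar_gradiometer <- function(center, normal, u = NULL, loop_w = 0.012,
                               loop_h = 0.026, baseline = 0.0168,
                               name = "GRAD", n_elements = 16, n_quad = 64) {
  fr <- sensor_frame(normal, u)
  l1 <- rect_loop(center + fr$u * baseline / 2, fr$u, fr$v, loop_w, loop_h)
  l2 <- rect_loop(center - fr$u * baseline / 2, fr$u, fr$v, loop_w, loop_h)
  new_sensor("planar_gradiometer", name, list(l1, l2), baseline,
             n_elements, n_quad)
}

sensor_frame <- function(normal, u = NULL) {
  n <- normal / sqrt(sum(normal^2))
  if (is.null(u)) {
    ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- cross3(ref, n)
  }
  u <- u - sum(u * n) * n
  u <- u / sqrt(sum(u^2))
  list(u = u, v = cross3(n, u), n = n)
}

#' @export
print.sensor <- function(x, ...) {
  cat(sprintf("sensor %s (%s): %d loop(s), %d elements, %d quad points\n",
              x$name, x$kind, length(x$loops), nrow(x$elements$pos),
              nrow(x$quad_points)))
  invisible(x)
}

#' Sensor output from B at the flux quadrature points
#'
#' Magnetometer: flux / loop area (T).  Planar gradiometer:
#' (flux1 - flux2) / (area * baseline) (T/m); a field that is uniform across
#' both coils is rejected exactly.
#'
#' @param B_at_points P x 3 matrix of B (T) at `sensor$quad_points`.
#' @param sensor a `sensor`.
#' @return scalar sensor output.
#' @export
sensor_output_from_B <- function(B_at_points, sensor) {
  B_at_points <- rbind(B_at_points)
  if (nrow(B_at_points) != length(sensor$quad_weights))
    stop("B row count does not match quadrature point count")
  flux <- numeric(length(sensor$loops))
  for (li in seq_along(sensor$loops)) {
    sel <- sensor$quad_loop == li
    bn <- B_at_points[sel, , drop = FALSE] %*% sensor$loops[[li]]$normal
    flux[li] <- sum(sensor$quad_weights[sel] * bn)
  }
  if (sensor$kind == "magnetometer") flux[1] / sensor$area
  else (flux[1] - flux[2]) / (sensor$area * sensor$baseline)
}

#' Sensor array
#' @param sensors list of `sensor` objects with unique names.
#' @return object of class `sensor_array`.
#' @export
sensor_array <- function(sensors) {
  if (!length(sensors)) stop("empty sensor array")
  nm <- vapply(sensors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("sensor names must be unique")
  structure(list(sensors = sensors, names = nm), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  kinds <- table(vapply(x$sensors, `[[`, "", "kind"))
  cat(sprintf("sensor_array: %d sensors (%s)\n", length(x$sensors),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
  invisible(x)
}

#' Helmet-like sensor array on a spherical cap
#'
#' Spreads `n_sites` measurement sites quasi-uniformly (Fibonacci lattice)
#' over a spherical cap of the given solid-angle fraction, and places at each
#' site a magnetometer and/or two orthogonal planar gradiometers tangential
#' to the cap, mirroring the triplet layout of whole-head MEG systems
#' (102 sites x 3 sensors = 306 channels).
#'
#' @param n_sites number of measurement sites.
#' @param shell_radius helmet radius (m); must exceed the head radius.
#' @param coverage cap solid-angle fraction of the full sphere, in (0, 0.5].
#' @param kinds subset of `c("magnetometer", "gradiometer")`; "gradiometer"
#'   adds two orthogonal planar gradiometers per site.
#' @param head_radius optional head radius to validate against.
#' @param ... passed to [magnetometer()] / [planar_gradiometer()].
#' @return a [sensor_array()].
#' @export
build_helmet_array <- function(n_sites, shell_radius = 0.12, coverage = 0.4,
                               kinds = c("magnetometer", "gradiometer"),
                               head_radius = NULL, ...) {
  if (!is.null(head_radius) && shell_radius <= head_radius)
    stop("shell_radius must exceed the head radius")
  kinds <- match.arg(kinds, several.ok = TRUE)
  zmin <- 1 - 2 * coverage
  golden <- pi * (3 - sqrt(5))
  sensors <- list()
  for (i in seq_len(n_sites)) {
    z <- 1 - (i - 0.5) / n_sites * (1 - zmin)
    r <- sqrt(max(0, 1 - z^2))
    phi <- golden * i
    n <- c(r * cos(phi), r * sin(phi), z)
    center <- shell_radius * n
    fr <- sensor_frame(n)
    if ("magnetometer" %in% kinds)
      sensors[[length(sensors) + 1L]] <-
        magnetometer(center, n, fr$u, name = sprintf("MAG%03d", i), ...)
    if ("gradiometer" %in% kinds) {
      sensors[[length(sensors) + 1L]] <-
        planar_gradiometer(center, n, fr$u, name = sprintf("GRA%03d1", i), ...)
      sensors[[length(sensors) + 1L]] <-
        planar_gradiometer(center, n, fr$v, name = sprintf("GRA%03d2", i), ...)
    }
  }
  sensor_array(sensors)
}

#' Write a sensor layout file
#'
#' Tab-separated text: one row per sensor with name, kind, center,
#' orientation triad (normal and first in-plane axis), loop dimensions and
#' baseline.  [read_sensor_layout()] round-trips the array exactly.
#'
#' @param array a [sensor_array()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_sensor_layout <- function(array, path) {
  rows <- lapply(array$sensors, function(s) {
    lo <- s$loops[[1]]
    center <- if (s$kind == "magnetometer") lo$center
              else (s$loops[[1]]$center + s$loops[[2]]$center) / 2
    data.frame(name = s$name, kind = s$kind,
               cx = center[1], cy = center[2], cz = center[3],
               nx = lo$normal[1], ny = lo$normal[2], nz = lo$normal[3],
               ux = lo$u[1], uy = lo$u[2], uz = lo$u[3],
               loop_w = lo$w, loop_h = lo$h,
               baseline = ifelse(is.na(s$baseline), 0, s$baseline),
               n_elements = s$n_elements, n_quad = s$n_quad)
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sensor layout file
#' @param path path written by [write_sensor_layout()].
#' @return a [sensor_array()].
#' @export
read_sensor_layout <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(name = "character", kind = "character"))
  sensors <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    center <- c(r$cx, r$cy, r$cz)
    normal <- c(r$nx, r$ny, r$nz)
    u <- c(r$ux, r$uy, r$uz)
    if (r$kind == "magnetometer")
      magnetometer(center, normal, u, side = r$loop_w, name = r$name,
                   n_elements = r$n_elements, n_quad = r$n_quad)
    else
      planar_gradiometer(center, normal, u, loop_w = r$loop_w,
                         loop_h = r$loop_h, baseline = r$baseline,
                         name = r$name, n_elements = r$n_elements,
                         n_quad = r$n_quad)
  })
  sensor_array(sensors)
}
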