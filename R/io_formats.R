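#' Write a mesh to STL (ASCII), OFF or PLY (ASCII)
#'
#' Format is chosen from the file extension (`.stl`, `.off`, `.ply`).
#' STL stores triangle soup (vertices are duplicated per face); OFF and PLY
#' store indexed vertices and round-trip the mesh exactly.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "stl") {
    writeLines("solid recmeg", con)
    a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
    c3 <- v[f[, 3], , drop = FALSE]; n <- mesh$face_normals
    txt <- sprintf(paste0(
      "facet normal %.9g %.9g %.9g\n outer loop\n",
      "  vertex %.17g %.17g %.17g\n  vertex %.17g %.17g %.17g\n",
      "  vertex %.17g %.17g %.17g\n endloop\nendfacet"),
      n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
      b[, 1], b[, 2], b[, 3], c3[, 1], c3[, 2], c3[, 3])
    writeLines(txt, con)
    writeLines("endsolid recmeg", con)
  } else if (ext == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' Read a mesh from STL (ASCII), OFF or PLY (ASCII)
#'
#' @param path input file path; format from extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "stl") {
    vt <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vt), "\\s+"), function(x)
      as.numeric(x[2:4])))
    nf <- nrow(nums) / 3
    # merge duplicated vertices
    key <- apply(nums, 1, function(p) paste(sprintf("%.12g", p), collapse = ","))
    uk <- !duplicated(key)
    verts <- nums[uk, , drop = FALSE]
    idx <- match(key, key[uk])
    faces <- matrix(idx, ncol = 3, byrow = TRUE)
    return(triangle_mesh(verts, faces))
  }
  if (ext == "off") {
    stopifnot(trimws(lines[1]) == "OFF")
    hdr <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- hdr[1]; nf <- hdr[2]
    v <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                               as.numeric))
    f <- do.call(rbind, lapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]),
                                        "\\s+"), function(x) as.integer(x[2:4])))
    return(triangle_mesh(v, f + 1L))
  }
  if (ext == "ply") {
    end <- match("end_header", trimws(lines))
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    v <- do.call(rbind, lapply(strsplit(trimws(lines[(end + 1):(end + nv)]),
                                        "\\s+"), as.numeric))
    f <- do.call(rbind, lapply(strsplit(trimws(lines[(end + nv + 1):(end + nv + nf)]),
                                        "\\s+"), function(x) as.integer(x[2:4])))
    return(triangle_mesh(v[, 1:3, drop = FALSE], f + 1L))
  }
  stop("unsupported mesh format: ", ext)
}

#' Write a head model manifest
#'
#' Saves each layer's mesh (OFF) next to a YAML manifest listing per-layer
#' mesh path, name and conductivities.
#'
#' @param head a [head_model()].
#' @param path manifest path (`.yaml`); meshes go in the same directory.
#' @return invisibly `path`.
#' @export
write_head_manifest <- function(head, path) {
  dir <- dirname(path)
  entries <- lapply(head$layers, function(l) {
    mp <- file.path(dir, paste0(l$name, ".off"))
    write_mesh(l$mesh, mp)
    list(mesh = basename(mp), name = l$name,
         sigma_in = l$sigma_in, sigma_out = l$sigma_out)
  })
  yaml::write_yaml(list(layers = entries), path)
  invisible(path)
}

#' Read a head model manifest
#' @param path manifest path written by [write_head_manifest()].
#' @return a [head_model()].
#' @export
read_head_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  dir <- dirname(path)
  layers <- lapply(man$layers, function(e)
    conductivity_layer(read_mesh(file.path(dir, e$mesh)),
                       e$sigma_in, e$sigma_out, e$name))
  head_model(layers)
}

#' Write a per-face scalar overlay
#'
#' Plain-text mesh-scalar format consumable by standard viewers and
#' spreadsheets: one row per face with the face index, face-center
#' coordinates and the scalar value, tab-separated.
#'
#' @param mesh the [triangle_mesh()] the values live on.
#' @param values numeric vector, one value per face.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_scalar_overlay <- function(mesh, values, path) {
  if (length(values) != nrow(mesh$faces))
    stop("one value per face required")
  df <- data.frame(face = seq_along(values),
                   x = mesh$face_centers[, 1], y = mesh$face_centers[, 2],
                   z = mesh$face_centers[, 3], value = values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-face scalar overlay written by [write_scalar_overlay()]
#' @param path overlay path.
#' @return numeric vector of per-face values (face order).
#' @export
read_scalar_overlay <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  df$value[order(df$face)]
}

#' Persist a leadfield matrix
#'
#' Writes the gain matrix as a raw little-endian float64 column-major binary
#' container plus a JSON metadata sidecar (`<path>.json`) holding dimensions,
#' sensor names, units, assembly method, solver configuration and md5 hashes
#' of the matrix payload.  [read_leadfield()] validates the hash.
#'
#' @param lf a `leadfield` object from [assemble_leadfield()].
#' @param path output path for the binary payload.
#' @return invisibly `path`.
#' @export
write_leadfield <- function(lf, path) {
  writeBin(as.numeric(lf$matrix), path, size = 8, endian = "little")
  meta <- list(nrow = nrow(lf$matrix), ncol = ncol(lf$matrix),
               sensor_names = lf$sensor_names, units = lf$units,
               method = lf$method, config = lf$config,
               md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a leadfield container, validating its hash
#' @param path path written by [write_leadfield()].
#' @return a `leadfield` object (without source-space geometry).
#' @export
read_leadfield <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(unname(tools::md5sum(path)), meta$md5))
    stop("leadfield payload hash mismatch")
  m <- matrix(readBin(path, "numeric", n = meta$nrow * meta$ncol,
                      size = 8, endian = "little"),
              meta$nrow, meta$ncol)
  structure(list(matrix = m, sensor_names = meta$sensor_names,
                 units = meta$units, method = meta$method,
                 config = meta$config, source_space = NULL),
            class = "leadfield")
}
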