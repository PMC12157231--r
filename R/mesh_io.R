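# Mesh file I/O: PLY (ASCII and binary little-endian) and OBJ.
# Vertex order is semantic (it carries the template correspondence), so
# readers and writers preserve it exactly.

#' Write a mesh as PLY
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output path.
#' @param binary Write `binary_little_endian` (default) or ASCII.
#' @param colours Optional n x 3 matrix of 0-255 per-vertex RGB colours.
#' @param digits Significant digits for ASCII output (default 17: lossless
#'   double round-trip).
#' @return Invisibly, `path`.
#' @export
write_ply <- function(mesh, path, binary = TRUE, colours = NULL,
                      digits = 17) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices
  F <- mesh$faces
  has_col <- !is.null(colours)
  if (has_col) {
    colours <- as.matrix(colours)
    stopifnot(nrow(colours) == nrow(V), ncol(colours) == 3)
  }
  header <- c(
    "ply",
    sprintf("format %s 1.0",
            if (binary) "binary_little_endian" else "ascii"),
    "comment corresponded face mesh",
    sprintf("element vertex %d", nrow(V)),
    "property double x", "property double y", "property double z",
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    sprintf("element face %d", nrow(F)),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    if (has_col) {
      for (i in seq_len(nrow(V))) {
        writeBin(as.numeric(V[i, ]), con, size = 8, endian = "little")
        writeBin(as.raw(colours[i, ]), con)
      }
    } else {
      writeBin(as.numeric(t(V)), con, size = 8, endian = "little")
    }
    if (nrow(F) > 0) {
      for (i in seq_len(nrow(F))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
      }
    }
  } else {
    vt <- apply(V, 1, function(r) paste(format(r, digits = digits,
                                               scientific = FALSE,
                                               trim = TRUE),
                                        collapse = " "))
    if (has_col) {
      vt <- paste(vt, apply(colours, 1, paste, collapse = " "))
    }
    writeLines(vt, con, sep = "\n")
    if (nrow(F) > 0) {
      writeLines(paste(3L, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con,
                 sep = "\n")
    }
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' Supports ASCII and binary little-endian PLY with double or float vertex
#' coordinates and optional uchar colour properties.
#'
#' @param path PLY file path.
#' @return A `triangle_mesh`; vertex colours, when present, are attached as
#'   attribute `"colours"`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (length(first) == 0 || first != "ply") {
    stop("not a PLY file", call. = FALSE)
  }
  header <- first
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated PLY header", call. = FALSE)
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", header,
                                                  value = TRUE)[1])
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop(sprintf("unsupported PLY format '%s'", fmt), call. = FALSE)
  }
  elems <- grep("^element ", header)
  parse_count <- function(pattern) {
    ln <- grep(pattern, header, value = TRUE)
    if (length(ln) == 0) 0L else as.integer(sub(pattern, "\\1", ln[1]))
  }
  nv <- parse_count("^element vertex (\\d+)$")
  nf <- parse_count("^element face (\\d+)$")
  # vertex property types, in order
  vstart <- grep("^element vertex", header)
  vend <- if (length(elems) > 1 && any(elems > vstart)) {
    min(elems[elems > vstart])
  } else length(header)
  vprops <- grep("^property ", header[(vstart + 1):(vend - 1)], value = TRUE)
  vtypes <- sub("^property (\\S+) (\\S+)$", "\\1", vprops)
  vnames <- sub("^property (\\S+) (\\S+)$", "\\2", vprops)
  sizes <- c(double = 8L, float = 4L, uchar = 1L, char = 1L, int = 4L,
             uint = 4L, short = 2L, ushort = 2L)
  if (!all(vtypes %in% names(sizes))) {
    stop("unsupported vertex property type in PLY", call. = FALSE)
  }
  xyz <- match(c("x", "y", "z"), vnames)
  if (anyNA(xyz)) stop("PLY lacks x/y/z vertex properties", call. = FALSE)
  col_idx <- match(c("red", "green", "blue"), vnames)
  has_col <- !anyNA(col_idx)

  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = nv * length(vnames),
                 quiet = TRUE)
    M <- matrix(vals, nv, length(vnames), byrow = TRUE)
    V <- M[, xyz, drop = FALSE]
    cols <- if (has_col) M[, col_idx, drop = FALSE]
    F <- if (nf > 0) {
      fv <- scan(con, what = integer(), n = nf * 4L, quiet = TRUE)
      Fm <- matrix(fv, nf, 4L, byrow = TRUE)
      if (any(Fm[, 1] != 3L)) {
        stop("only triangular faces are supported", call. = FALSE)
      }
      Fm[, 2:4, drop = FALSE] + 1L
    } else matrix(integer(0), 0, 3)
  } else {
    V <- matrix(0, nv, 3)
    cols <- if (has_col) matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      row <- numeric(length(vnames))
      for (j in seq_along(vnames)) {
        tp <- vtypes[j]
        row[j] <- if (tp %in% c("double", "float")) {
          readBin(con, numeric(), 1, size = sizes[[tp]], endian = "little")
        } else {
          readBin(con, integer(), 1, size = sizes[[tp]], signed =
                    !(tp %in% c("uchar", "ushort")), endian = "little")
        }
      }
      V[i, ] <- row[xyz]
      if (has_col) cols[i, ] <- row[col_idx]
    }
    F <- matrix(integer(0), 0, 3)
    if (nf > 0) {
      F <- matrix(0L, nf, 3)
      for (i in seq_len(nf)) {
        cnt <- as.integer(readBin(con, integer(), 1, size = 1,
                                  signed = FALSE))
        idx <- readBin(con, integer(), cnt, size = 4, endian = "little")
        if (cnt != 3L) stop("only triangular faces are supported",
                            call. = FALSE)
        F[i, ] <- idx + 1L
      }
    }
  }
  mesh <- triangle_mesh(V, F)
  if (has_col) attr(mesh, "colours") <- cols
  mesh
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output path.
#' @param digits Significant digits (default 17: lossless round-trip).
#' @return Invisibly, `path`.
#' @export
write_obj <- function(mesh, path, digits = 17) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices
  F <- mesh$faces
  lines <- c(
    apply(V, 1, function(r) paste("v", paste(
      format(r, digits = digits, scientific = FALSE, trim = TRUE),
      collapse = " "))),
    if (nrow(F) > 0) paste("f", F[, 1], F[, 2], F[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Reads `v` and `f` records; polygonal faces are fan-triangulated and
#' texture/normal indices (`f a/b/c` syntax) are ignored.
#'
#' @param path OBJ file path.
#' @return A `triangle_mesh`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  F <- if (length(fl) > 0) {
    do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                          function(p) {
      idx <- as.integer(sub("/.*$", "", p))
      if (length(idx) < 3) stop("face with fewer than 3 vertices",
                                call. = FALSE)
      cbind(idx[1], idx[-c(1, length(idx))], idx[-(1:2)])
    }))
  } else matrix(integer(0), 0, 3)
  triangle_mesh(V, F)
}

#' Write / read a template bundle
#'
#' A template bundle is the template mesh (PLY) plus a JSON sidecar holding
#' the symmetry pairing, midline set, landmark indices and axis convention.
#'
#' @param template A [face_template].
#' @param dir Bundle directory.
#' @param name Base file name.
#' @return `read_template_bundle` returns the [face_template].
#' @export
write_template_bundle <- function(template, dir, name = "template") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mesh_path <- file.path(dir, paste0(name, ".ply"))
  write_ply(template$mesh, mesh_path, binary = FALSE)
  side <- list(symmetry_pairs = template$symmetry_pairs,
               midline_vertices = template$midline_vertices,
               landmark_indices = as.list(template$landmark_indices),
               axes = template$axes)
  jsonlite::write_json(side, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_template_bundle
#' @export
read_template_bundle <- function(dir, name = "template") {
  mesh <- read_ply(file.path(dir, paste0(name, ".ply")))
  side <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  lm <- unlist(side$landmark_indices)
  face_template(mesh, side$symmetry_pairs,
                lm[c("inner_eye_left", "inner_eye_right", "nose_tip")])
}
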