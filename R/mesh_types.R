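#' @keywords internal
#' @useDynLib palsy3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Construct a corresponded triangle mesh
#'
#' A `triangle_mesh` holds vertex coordinates in millimetres together with a
#' fixed triangulation. All meshes of one cohort share the template's vertex
#' ordering, so vertex index `i` refers to the same anatomical location on
#' every mesh; this dense correspondence is what the whole pipeline relies on.
#'
#' @param vertices Numeric matrix, one row per vertex, three columns (x, y, z
#'   in mm). The axis convention is x from left to right, y from foot to head,
#'   z from back to front.
#' @param faces Integer matrix, one row per triangle, three columns of 1-based
#'   vertex indices.
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) {
    stop("`vertices` must have three columns (x, y, z)", call. = FALSE)
  }
  if (!all(is.finite(vertices))) {
    stop("`vertices` must be finite", call. = FALSE)
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) {
      stop("`faces` must have three columns", call. = FALSE)
    }
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("`faces` reference vertex indices outside 1..n_vertices",
           call. = FALSE)
    }
  }
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh A `triangle_mesh`.
#' @return Integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Construct a symmetric face template
#'
#' The template is the bilaterally symmetric reference mesh that defines the
#' vertex ordering, the left-right symmetry pairing, and the three alignment
#' landmarks (both inner eye corners and the nose tip) used throughout the
#' pipeline.
#'
#' @param mesh A `triangle_mesh` whose vertices are mirror-symmetric about the
#'   plane x = 0.
#' @param symmetry_pairs Integer vector; `symmetry_pairs[i]` is the vertex
#'   index anatomically mirroring vertex `i`. Must be an involution.
#' @param landmark_indices Integer vector of length 3, named or ordered as
#'   (inner_eye_left, inner_eye_right, nose_tip).
#' @param symmetry_tol Tolerance (mm) for checking mirror symmetry of the
#'   template coordinates.
#' @return An object of class `face_template` with elements `mesh`,
#'   `symmetry_pairs`, `midline_vertices`, `landmark_indices` and `axes`.
#' @export
face_template <- function(mesh, symmetry_pairs, landmark_indices,
                          symmetry_tol = 1e-9) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- n_vertices(mesh)
  symmetry_pairs <- as.integer(symmetry_pairs)
  if (length(symmetry_pairs) != n) {
    stop("`symmetry_pairs` must have one entry per vertex", call. = FALSE)
  }
  if (any(symmetry_pairs < 1L | symmetry_pairs > n)) {
    stop("`symmetry_pairs` out of range", call. = FALSE)
  }
  if (!identical(symmetry_pairs[symmetry_pairs], seq_len(n))) {
    stop("`symmetry_pairs` must be an involution", call. = FALSE)
  }
  V <- mesh$vertices
  Vp <- V[symmetry_pairs, , drop = FALSE]
  err <- max(abs(Vp[, 1] + V[, 1]), abs(Vp[, 2] - V[, 2]),
             abs(Vp[, 3] - V[, 3]))
  if (err > symmetry_tol) {
    stop(sprintf(
      "template is not mirror-symmetric under the pairing (max error %.3g mm)",
      err), call. = FALSE)
  }
  landmark_indices <- as.integer(landmark_indices)
  if (length(landmark_indices) != 3L ||
      any(landmark_indices < 1L | landmark_indices > n)) {
    stop("`landmark_indices` must be three valid vertex indices",
         call. = FALSE)
  }
  names(landmark_indices) <- c("inner_eye_left", "inner_eye_right", "nose_tip")
  structure(list(
    mesh = mesh,
    symmetry_pairs = symmetry_pairs,
    midline_vertices = which(symmetry_pairs == seq_len(n)),
    landmark_indices = landmark_indices,
    axes = "x: left to right, y: foot to head, z: back to front"
  ), class = "face_template")
}

#' @export
print.face_template <- function(x, ...) {
  cat(sprintf(
    "<face_template: %d vertices (%d midline), landmarks [%s], axes %s>\n",
    n_vertices(x$mesh), length(x$midline_vertices),
    paste(x$landmark_indices, collapse = ", "), x$axes))
  invisible(x)
}

#' Construct a rigid (rotation + translation) transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (a proper
#'   rotation; reflections and scaling are rejected).
#' @param translation Numeric length-3 translation vector (mm).
#' @param tol Orthonormality tolerance.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0), tol = 1e-9) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop("`rotation` must be 3x3", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop("`rotation` is not orthonormal", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("`rotation` is a reflection (det < 0); only proper rotations allowed",
         call. = FALSE)
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L) {
    stop("`translation` must have length 3", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return A `rigid_transform` with identity rotation and zero translation.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Apply a rigid transform to points or a mesh
#'
#' @param transform A `rigid_transform`.
#' @param x A `triangle_mesh` or an n x 3 coordinate matrix.
#' @return Object of the same type as `x`, transformed by `R x + t`.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- apply_transform(transform, x$vertices)
    return(x)
  }
  V <- as.matrix(x)
  V %*% t(transform$rotation) +
    matrix(transform$translation, nrow(V), 3L, byrow = TRUE)
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform`s; the result applies `b` first, then `a`.
#' @return A `rigid_transform` equal to `a %then% b` in function composition.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform: rotation %.3f deg, translation (%s) mm>\n",
              ang, paste(sprintf("%.2f", x$translation), collapse = ", ")))
  invisible(x)
}

#' Construct a per-vertex scalar field
#'
#' Scalar fields carry one value per template vertex: non-negative distances
#' for `displacement` and `asymmetry` fields, signed values for `difference`
#' fields.
#'
#' @param values Numeric vector, one value (mm) per vertex.
#' @param kind One of `"displacement"`, `"asymmetry"`, `"difference"`.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(values, kind = c("displacement", "asymmetry",
                                          "difference")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("field values must be finite", call. = FALSE)
  if (kind != "difference" && any(values < 0)) {
    stop(sprintf("%s fields must be non-negative", kind), call. = FALSE)
  }
  structure(list(values = values, kind = kind), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field (%s): %d vertices, range [%.3f, %.3f] mm>\n",
              x$kind, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Construct an expression capture
#'
#' One subject performing one expression: the face at rest and at the peak of
#' the expression, both corresponded to the template.
#'
#' @param rest,peak `triangle_mesh` objects sharing the template topology.
#' @param expression Expression label (one of [expression_types()], or
#'   `"rest"`).
#' @param laterality Side of the palsy: `"left"`, `"right"`, or `"none"` for
#'   controls.
#' @param subject_id Subject identifier.
#' @param cohort `"patient"` or `"control"`.
#' @param meta Optional list of extra metadata (e.g. true severity for
#'   synthetic captures).
#' @return An object of class `expression_capture`.
#' @export
expression_capture <- function(rest, peak, expression, laterality, subject_id,
                               cohort = c("patient", "control"), meta = list()) {
  stopifnot(inherits(rest, "triangle_mesh"), inherits(peak, "triangle_mesh"))
  cohort <- match.arg(cohort)
  if (n_vertices(rest) != n_vertices(peak)) {
    stop("rest and peak meshes must share the vertex count", call. = FALSE)
  }
  if (!laterality %in% c("left", "right", "none")) {
    stop("`laterality` must be 'left', 'right' or 'none'", call. = FALSE)
  }
  if (cohort == "patient" && laterality == "none") {
    stop("patient captures must carry a laterality", call. = FALSE)
  }
  structure(list(rest = rest, peak = peak, expression = expression,
                 laterality = laterality, subject_id = subject_id,
                 cohort = cohort, meta = meta),
            class = "expression_capture")
}

#' @export
print.expression_capture <- function(x, ...) {
  cat(sprintf("<expression_capture: %s / %s, %s palsy, %d vertices>\n",
              x$subject_id, x$expression, x$laterality, n_vertices(x$rest)))
  invisible(x)
}

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
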