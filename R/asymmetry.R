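# Mirror-based asymmetry and displacement fields on corresponded meshes.

#' Mirror a corresponded face mesh
#'
#' Reflects the mesh about the template's sagittal plane (x = 0) and
#' re-indexes the vertices through the template's symmetry pairing, so that
#' vertex `i` of the mirror is the reflected image of the vertex anatomically
#' paired with `i`. The mirror of a perfectly symmetric mesh is therefore the
#' mesh itself, and mirroring is an exact involution.
#'
#' @param mesh `triangle_mesh` in template vertex order.
#' @param template A [face_template] supplying the symmetry pairing.
#' @return The mirrored `triangle_mesh`.
#' @export
mirror_mesh <- function(mesh, template) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(template$symmetry_pairs)) {
    stop("template carries no symmetry pairing", call. = FALSE)
  }
  if (n_vertices(mesh) != length(template$symmetry_pairs)) {
    stop("mesh vertex count does not match the template pairing", call. = FALSE)
  }
  W <- mesh$vertices[template$symmetry_pairs, , drop = FALSE]
  W[, 1] <- -W[, 1]
  mesh$vertices <- W
  mesh
}

#' Per-vertex mirror asymmetry field
#'
#' Quantifies left-right facial asymmetry: the mesh is mirrored
#' ([mirror_mesh]), the mirror is superimposed back onto the original by
#' partial Procrustes, and the field value at vertex `i` is the Euclidean
#' distance between vertex `i` of the mesh and vertex `i` of the aligned
#' mirror. For a perfectly symmetric face the field is identically zero, and
#' the field always satisfies `value(i) == value(pair(i))`: left and right
#' differ by the same absolute amount.
#'
#' @param mesh `triangle_mesh` corresponded to the template.
#' @param template A [face_template].
#' @return A [scalar_field] of kind `"asymmetry"` (mm).
#' @export
asymmetry_field <- function(mesh, template) {
  mir <- mirror_mesh(mesh, template)
  fit <- partial_procrustes(mir, mesh)
  d <- sqrt(rowSums((mesh$vertices - fit$aligned$vertices)^2))
  scalar_field(d, "asymmetry")
}

#' Per-vertex displacement field between rest and peak frames
#'
#' Euclidean distance moved by each vertex from the rest face to the
#' (already head-motion-corrected) peak face.
#'
#' @param rest `triangle_mesh` at rest.
#' @param peak_aligned `triangle_mesh` at peak expression, previously aligned
#'   to the rest frame with [landmark_rigid_align].
#' @return A [scalar_field] of kind `"displacement"` (mm).
#' @export
displacement_field <- function(rest, peak_aligned) {
  Vr <- if (inherits(rest, "triangle_mesh")) rest$vertices else as.matrix(rest)
  Vp <- if (inherits(peak_aligned, "triangle_mesh")) peak_aligned$vertices else as.matrix(peak_aligned)
  if (nrow(Vr) != nrow(Vp)) {
    stop(sprintf("correspondence error: %d vs %d vertices", nrow(Vr), nrow(Vp)),
         call. = FALSE)
  }
  scalar_field(sqrt(rowSums((Vp - Vr)^2)), "displacement")
}

#' Standardize palsy laterality to the right side
#'
#' Captures of left-sided palsy are mirrored (rest and peak frames both) so
#' that the palsy lies on the right side for the whole cohort; right-sided
#' and control captures are returned unchanged. Mirroring preserves all
#' inter-vertex distances, so asymmetry fields are unaffected, while the
#' movement deficit moves to the right half-face. The operation is idempotent
#' once the laterality flag has been updated.
#'
#' @param capture An [expression_capture].
#' @param template A [face_template].
#' @return The lateralized `expression_capture`.
#' @export
reflect_lateralize <- function(capture, template) {
  stopifnot(inherits(capture, "expression_capture"))
  if (capture$cohort == "patient" &&
      !capture$laterality %in% c("left", "right")) {
    stop("patient capture with unknown laterality", call. = FALSE)
  }
  if (identical(capture$laterality, "left")) {
    capture$rest <- mirror_mesh(capture$rest, template)
    capture$peak <- mirror_mesh(capture$peak, template)
    capture$laterality <- "right"
    capture$meta$reflected <- TRUE
  }
  capture
}
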