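# Cohort-level morphometric summaries: average movement, patient-control
# difference, and average asymmetry maps.

#' Vertex-wise mean of scalar fields
#'
#' @param fields Non-empty list of [scalar_field]s of equal length.
#' @return A [scalar_field] of the same kind holding the arithmetic mean.
#' @export
average_field <- function(fields) {
  if (length(fields) == 0L) stop("empty field list", call. = FALSE)
  lens <- vapply(fields, function(f) length(f$values), 0L)
  if (length(unique(lens)) != 1L) {
    stop("fields must have equal lengths", call. = FALSE)
  }
  vals <- Reduce(`+`, lapply(fields, `[[`, "values")) / length(fields)
  scalar_field(vals, fields[[1]]$kind)
}

#' Signed patient-minus-control difference field
#'
#' @param patients_mean,controls_mean [scalar_field]s on the same vertex set.
#' @return A [scalar_field] of kind `"difference"`; negative values mark a
#'   movement deficit of the patients.
#' @export
difference_field <- function(patients_mean, controls_mean) {
  if (length(patients_mean$values) != length(controls_mean$values)) {
    stop("field length mismatch", call. = FALSE)
  }
  scalar_field(patients_mean$values - controls_mean$values, "difference")
}

#' Per-expression cohort map set
#'
#' For every expression, computes the mean control movement field, the mean
#' patient movement field, their signed difference, and the mean patient
#' asymmetry at the peak frame. Captures are lateralized to the right and
#' passed through the full alignment chain first, so all fields live on the
#' template vertex set.
#'
#' @param cohort A [synthesize_cohort] result (or any list with `captures`
#'   and `template`).
#' @return A list of class `cohort_map_set`: per expression, a list with
#'   `control_movement`, `patient_movement`, `difference`,
#'   `patient_asymmetry` and the per-arm capture counts.
#' @export
cohort_map_set <- function(cohort) {
  template <- cohort$template
  per_expr <- list()
  for (cap in cohort$captures) {
    cap <- reflect_lateralize(cap, template)
    rest_fit <- partial_procrustes(cap$rest, template$mesh)
    peak_fit <- landmark_rigid_align(cap$peak, rest_fit$aligned,
                                     template$landmark_indices)
    disp <- displacement_field(rest_fit$aligned, peak_fit$aligned)
    e <- cap$expression
    if (is.null(per_expr[[e]])) {
      per_expr[[e]] <- list(control = list(), patient = list(),
                            asym = list())
    }
    if (cap$cohort == "control") {
      per_expr[[e]]$control <- c(per_expr[[e]]$control, list(disp))
    } else {
      per_expr[[e]]$patient <- c(per_expr[[e]]$patient, list(disp))
      per_expr[[e]]$asym <- c(per_expr[[e]]$asym,
                              list(asymmetry_field(peak_fit$aligned,
                                                   template)))
    }
  }
  out <- lapply(per_expr, function(x) {
    ctrl <- if (length(x$control)) average_field(x$control) else NULL
    pat <- if (length(x$patient)) average_field(x$patient) else NULL
    list(control_movement = ctrl,
         patient_movement = pat,
         difference = if (!is.null(ctrl) && !is.null(pat))
           difference_field(pat, ctrl) else NULL,
         patient_asymmetry = if (length(x$asym)) average_field(x$asym)
         else NULL,
         n_controls = length(x$control), n_patients = length(x$patient))
  })
  structure(out, class = "cohort_map_set")
}

#' Map field values to colours
#'
#' Linear blue-to-red palette lookup over a display range; out-of-range
#' values are clamped to the range ends.
#'
#' @param values Numeric field values.
#' @param range Display range `c(min, max)`; defaults follow the reporting
#'   convention of 0-10 mm for movement/asymmetry maps (use `c(-5, 5)` for
#'   difference maps).
#' @param palette Colour anchors interpolated linearly.
#' @return Matrix with columns `r`, `g`, `b` in 0-255.
#' @export
field_colours <- function(values, range = c(0, 10),
                          palette = c("blue", "cyan", "green", "yellow",
                                      "red")) {
  if (range[1] >= range[2]) stop("invalid range: min >= max", call. = FALSE)
  t <- pmin(1, pmax(0, (values - range[1]) / (range[2] - range[1])))
  m <- grDevices::colorRamp(palette)(t)
  colnames(m) <- c("r", "g", "b")
  round(m)
}

#' Render a scalar field on a mesh
#'
#' Writes a colour-mapped copy of the mesh as ASCII PLY with per-vertex
#' colours (readable by standard mesh viewers), and/or returns the colour
#' table for plotting.
#'
#' @param field A [scalar_field].
#' @param mesh The `triangle_mesh` to colour (usually the template mesh).
#' @param path Output PLY path, or `NULL` to skip writing.
#' @param range,palette See [field_colours].
#' @return Invisibly, a list with `colours` and `path`.
#' @export
render_map <- function(field, mesh, path = NULL,
                       range = if (field$kind == "difference") c(-5, 5)
                       else c(0, 10),
                       palette = c("blue", "cyan", "green", "yellow",
                                   "red")) {
  stopifnot(inherits(field, "scalar_field"), inherits(mesh, "triangle_mesh"))
  if (length(field$values) != n_vertices(mesh)) {
    stop("field length does not match the mesh", call. = FALSE)
  }
  cols <- field_colours(field$values, range, palette)
  if (!is.null(path)) {
    write_ply(mesh, path, binary = FALSE, colours = cols)
  }
  invisible(list(colours = cols, path = path))
}

#' Write cohort maps to a directory
#'
#' One colour PLY per expression and map row, plus a CSV of the per-vertex
#' mean values.
#'
#' @param maps A [cohort_map_set].
#' @param template The [face_template] the maps live on.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_maps <- function(maps, template, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  rows <- list()
  for (e in names(maps)) {
    m <- maps[[e]]
    for (kind in c("control_movement", "patient_movement", "difference",
                   "patient_asymmetry")) {
      f <- m[[kind]]
      if (is.null(f)) next
      p <- file.path(out_dir, sprintf("%s_%s.ply", e, kind))
      render_map(f, template$mesh, p)
      paths <- c(paths, p)
      rows[[paste(e, kind)]] <- data.frame(expression = e, map = kind,
                                           vertex = seq_along(f$values),
                                           value = f$values)
    }
  }
  csv <- file.path(out_dir, "cohort_maps.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(c(paths, csv))
}
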