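# Synthetic symmetric face template and graded unilateral-palsy cohorts.
#
# The generator emulates the structure the pipeline needs from real
# stereophotogrammetry captures: dense vertex correspondence to a symmetric
# template, smooth regional expression displacement fields in the 5-10 mm
# range, unilateral attenuation of movement tied to a clinical severity
# grade, contralateral compensation, rigid head pose and sensor noise.

#' The five voluntary expression types
#'
#' @return Character vector of the five non-rest expressions, in the order
#'   used for the network's one-hot encoding.
#' @export
expression_types <- function() {
  c("eyebrow_raising", "eye_closure", "smiling", "cheek_puffing",
    "lip_puckering")
}

# Face half-width / half-height (mm) of the synthetic template.
FACE_HALF_WIDTH <- 70
FACE_HALF_HEIGHT <- 90

# Height profile of the synthetic face: an elliptic dome with nose ridge and
# tip, brow ridge, eye sockets, lips and cheek mounds. Every feature enters
# through x^2 or |x|, so z is exactly even in x and the template is exactly
# mirror-symmetric.
face_height <- function(x, y) {
  u <- x / FACE_HALF_WIDTH
  v <- y / FACE_HALF_HEIGHT
  z <- 45 * sqrt(pmax(0, 1 - 0.9 * u^2 - 0.8 * v^2))
  z <- z + 8 * exp(-x^2 / (2 * 6^2)) * exp(-((y + 5) / 22)^2 / 2)   # nose ridge
  z <- z + 6 * exp(-(x^2 + (y + 5)^2) / (2 * 8^2))                  # nose tip
  z <- z - 4 * exp(-((abs(x) - 25)^2 + (y - 25)^2) / (2 * 9^2))     # eye sockets
  z <- z + 3 * exp(-(y - 35)^2 / (2 * 7^2)) * exp(-x^2 / (2 * 35^2)) # brow ridge
  z <- z + 3 * exp(-(y + 40)^2 / (2 * 6^2)) * exp(-x^2 / (2 * 18^2)) # lips
  z <- z + 2 * exp(-((abs(x) - 35)^2 + (y + 10)^2) / (2 * 15^2))    # cheeks
  z
}

#' Generate the symmetric face template
#'
#' Builds a face-like parametric surface sampled on a left-right symmetric
#' grid with exactly `n_vertices` vertices: full grid rows plus one centred
#' partial row absorbing the remainder. Columns come in exact `+x`/`-x`
#' pairs (plus a midline column), which yields an exact symmetry pairing and
#' bit-reproducible coordinates. Landmarks are the vertices nearest the two
#' inner eye corners and the nose tip.
#'
#' Construction is fully deterministic; `seed` is accepted for interface
#' uniformity with the other generators.
#'
#' @param n_vertices Total vertex count (default 7859).
#' @param seed Unused; present for a uniform generator interface.
#' @return A [face_template].
#' @export
make_template <- function(n_vertices = 7859, seed = NULL) {
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 10L) {
    stop("`n_vertices` must be at least 10 to triangulate a face surface",
         call. = FALSE)
  }
  # Odd column count so a midline column exists; roughly face-shaped aspect.
  C <- max(3L, as.integer(round(sqrt(n_vertices * 7 / 9))))
  if (C %% 2L == 0L) C <- C - 1L
  R <- as.integer(ceiling(n_vertices / C))
  if (R < 2L) { R <- 2L }
  extra <- R * C - n_vertices
  if (extra >= C) {  # guard tiny n where ceiling forces a sparse last row
    R <- R - 1L
    extra <- R * C - n_vertices
  }
  c_last <- C - extra
  n_full_rows <- if (c_last == C) R else R - 1L

  centre <- (C + 1L) %/% 2L
  col_x <- (seq_len(C) - centre) / (centre - 1L) * FACE_HALF_WIDTH
  row_y <- if (R > 1) (seq_len(R) - 1) / (R - 1) * 2 * FACE_HALF_HEIGHT -
    FACE_HALF_HEIGHT else 0
  # Columns of the partial last row, centred on the midline.
  last_cols <- if (c_last == C) integer(0) else {
    if (c_last %% 2L == 1L) {
      centre + seq.int(-(c_last - 1L) %/% 2L, (c_last - 1L) %/% 2L)
    } else {
      h <- c_last %/% 2L
      centre + c(seq.int(-h, -1L), seq.int(1L, h))
    }
  }

  rows_idx <- rep(seq_len(n_full_rows), each = C)
  cols_idx <- rep(seq_len(C), times = n_full_rows)
  if (c_last < C) {
    rows_idx <- c(rows_idx, rep(R, c_last))
    cols_idx <- c(cols_idx, last_cols)
  }
  x <- col_x[cols_idx]
  y <- row_y[rows_idx]
  z <- face_height(x, y)
  V <- cbind(x, y, z)

  # Symmetry pairing: mirror column within the same row.
  key <- rows_idx * (2L * C) + cols_idx
  mirror_key <- rows_idx * (2L * C) + (C + 1L - cols_idx)
  pairs <- match(mirror_key, key)
  stopifnot(!anyNA(pairs))

  # Triangulation: quad split on full rows, strip under the partial row.
  faces <- list()
  if (n_full_rows > 1L) {
    r <- rep(seq_len(n_full_rows - 1L), each = C - 1L)
    cc <- rep(seq_len(C - 1L), times = n_full_rows - 1L)
    v00 <- (r - 1L) * C + cc
    v01 <- v00 + 1L
    v10 <- v00 + C
    v11 <- v10 + 1L
    faces[[1]] <- cbind(v00, v01, v11)
    faces[[2]] <- cbind(v00, v11, v10)
  }
  if (c_last < C && c_last > 1L && n_full_rows >= 1L) {
    base <- n_full_rows * C
    below <- (n_full_rows - 1L) * C + last_cols
    p <- base + seq_len(c_last)
    k <- seq_len(c_last - 1L)
    faces[[length(faces) + 1L]] <- cbind(p[k], p[k + 1L], below[k + 1L])
    faces[[length(faces) + 1L]] <- cbind(p[k], below[k + 1L], below[k])
  }
  F <- if (length(faces)) do.call(rbind, faces) else
    matrix(c(1L, 2L, 3L), 1L, 3L)

  mesh <- triangle_mesh(V, F)

  nearest <- function(px, py) {
    which.min((x - px)^2 + (y - py)^2)
  }
  ie_right <- nearest(12, 25)            # inner eye corner, +x half
  ie_left <- pairs[ie_right]
  # Nose tip: midline vertex closest to the nose centre.
  mid <- which(pairs == seq_along(pairs))
  nose <- mid[which.min((y[mid] + 5)^2 + x[mid]^2)]
  if (length(unique(c(ie_left, ie_right, nose))) < 3L) {
    stop("`n_vertices` too small to place distinct landmarks", call. = FALSE)
  }
  face_template(mesh, pairs, c(ie_left, ie_right, nose))
}

#' Logical mask for a named face region
#'
#' @param template A [face_template].
#' @param region One of `"upper_face"` (brow and above), `"eye"`,
#'   `"lower_face"` (mouth/cheek/chin), `"right_side"`, `"left_side"`.
#' @param margin For the side masks, half-width (mm) of the midline band to
#'   exclude.
#' @return Logical vector over template vertices.
#' @export
template_region_mask <- function(template, region = c("upper_face", "eye",
                                                      "lower_face",
                                                      "right_side",
                                                      "left_side"),
                                 margin = 10) {
  region <- match.arg(region)
  V <- template$mesh$vertices
  switch(region,
    upper_face = V[, 2] > 28,
    eye = V[, 2] > 12 & V[, 2] < 38 & abs(V[, 1]) > 8,
    lower_face = V[, 2] < -20,
    right_side = V[, 1] > margin,
    left_side = V[, 1] < -margin)
}

#' Symmetric displacement basis of an expression
#'
#' Returns the per-vertex displacement vectors (mm) that a healthy,
#' perfectly symmetric face applies when performing the expression at full
#' excursion: a smooth field localized to the anatomically relevant region
#' (brow for eyebrow raising, lids for eye closure, mouth corners for
#' smiling, cheeks for puffing, lips for puckering), with peak magnitude in
#' the 5-10 mm range. The x-component is odd in x and the y/z-components are
#' even, so the field respects the left-right pairing exactly.
#'
#' @param template A [face_template].
#' @param expression `"rest"` or one of [expression_types()].
#' @return An n x 3 matrix of displacement vectors.
#' @export
expression_basis <- function(template, expression) {
  V <- template$mesh$vertices
  x <- V[, 1]; y <- V[, 2]
  n <- length(x)
  D <- matrix(0, n, 3)
  if (identical(expression, "rest")) return(D)
  if (!expression %in% expression_types()) {
    stop(sprintf("unknown expression '%s'", expression), call. = FALSE)
  }
  g2 <- function(cx, cy, sx, sy) {
    exp(-(abs(x) - cx)^2 / (2 * sx^2) - (y - cy)^2 / (2 * sy^2))
  }
  switch(expression,
    eyebrow_raising = {
      w <- exp(-(y - 35)^2 / (2 * 8^2)) * exp(-x^2 / (2 * 28^2))
      D[, 2] <- 7 * w
      D[, 3] <- 1.5 * w
    },
    eye_closure = {
      w <- g2(22, 27, 9, 7)
      D[, 2] <- -6 * w
      D[, 3] <- -1 * w
    },
    smiling = {
      w <- g2(24, -40, 10, 9)
      D[, 1] <- 6 * w * tanh(x / 10)
      D[, 2] <- 5 * w
      D[, 3] <- 1.5 * w
    },
    cheek_puffing = {
      w <- g2(33, -12, 13, 13)
      D[, 1] <- 2 * w * tanh(x / 15)
      D[, 3] <- 7 * w
    },
    lip_puckering = {
      w <- exp(-x^2 / (2 * 16^2)) * exp(-(y + 40)^2 / (2 * 7^2))
      D[, 1] <- -3 * w * tanh(x / 12)
      D[, 2] <- 0.5 * w
      D[, 3] <- 6 * w
    })
  D
}

#' Active region of an expression
#'
#' Vertices where the expression's displacement basis exceeds a fraction of
#' its peak magnitude — the region that actually moves when the expression
#' is performed. Side-resolved movement summaries are computed over this
#' region so that the static remainder of the face does not dilute them.
#'
#' @param template A [face_template].
#' @param expression One of [expression_types()].
#' @param threshold Fraction of the peak basis magnitude (default 0.2).
#' @return Logical vector over template vertices.
#' @export
expression_active_mask <- function(template, expression, threshold = 0.2) {
  mags <- sqrt(rowSums(expression_basis(template, expression)^2))
  mags > threshold * max(mags)
}

#' Side-resolved means of a per-vertex field
#'
#' Means of a scalar field over the left and right halves of an
#' expression's active region, excluding a band around the midline where
#' laterality is ambiguous.
#'
#' @param field A [scalar_field] or numeric vector on template vertices.
#' @param template A [face_template].
#' @param expression Expression whose active region to use, or `NULL` for
#'   the whole face.
#' @param margin Half-width (mm) of the excluded midline band.
#' @return A list with `left`, `right` (mean mm) and `ratio`
#'   (`right / left`).
#' @export
field_side_means <- function(field, template, expression = NULL,
                             margin = 10) {
  v <- if (inherits(field, "scalar_field")) field$values else field
  active <- if (is.null(expression)) rep(TRUE, length(v)) else
    expression_active_mask(template, expression)
  l <- mean(v[active & template_region_mask(template, "left_side", margin)])
  r <- mean(v[active & template_region_mask(template, "right_side", margin)])
  list(left = l, right = r, ratio = r / l)
}

#' Linear severity-to-movement attenuation law
#'
#' Fraction of normal movement amplitude retained on the affected side at
#' modified Sunnybrook voluntary grade `g`: `a(5) = 1` (normal), `a(1) = 0`
#' (no movement), linear in between.
#'
#' @param g Grade in `[1, 5]`.
#' @return Attenuation factor in `[0, 1]`.
#' @export
attenuation_factor <- function(g) {
  if (any(g < 1 | g > 5)) stop("grade must lie in [1, 5]", call. = FALSE)
  (g - 1) / 4
}

# Smooth 0..1 weight of the affected half-face (5 mm transition band).
side_weight <- function(x, laterality) {
  s <- switch(laterality, right = 1, left = -1,
              stop("side weight needs a left/right laterality", call. = FALSE))
  1 / (1 + exp(-s * x / 5))
}

# Smooth symmetric per-subject shape perturbation: mirrored Gaussian bumps
# in z, exactly even in x.
subject_shape_field <- function(template, seed, n_bumps = 6, amplitude = 1.2) {
  V <- template$mesh$vertices
  x <- V[, 1]; y <- V[, 2]
  with_seed(seed, {
    dz <- numeric(length(x))
    for (k in seq_len(n_bumps)) {
      cx <- stats::runif(1, 0, 0.8 * FACE_HALF_WIDTH)
      cy <- stats::runif(1, -0.8, 0.8) * FACE_HALF_HEIGHT
      sg <- stats::runif(1, 15, 30)
      a <- stats::rnorm(1, 0, amplitude)
      dz <- dz + a * (exp(-((x - cx)^2 + (y - cy)^2) / (2 * sg^2)) +
                      exp(-((x + cx)^2 + (y - cy)^2) / (2 * sg^2)))
    }
    cbind(0, 0, dz)
  })
}

# Mirror a vector field through the template pairing (x-component flips).
mirror_vector_field <- function(D, template) {
  M <- D[template$symmetry_pairs, , drop = FALSE]
  M[, 1] <- -M[, 1]
  M
}

random_pose <- function(max_deg = 5, max_trans = 10) {
  ang <- stats::runif(3, -max_deg, max_deg) * pi / 180
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rigid_transform(Rz %*% Ry %*% Rx, stats::runif(3, -max_trans, max_trans))
}

#' Synthesize one graded expression capture
#'
#' Builds the rest and peak meshes of one subject performing one expression
#' at severity grade `g`. The rest face is the template plus a symmetric
#' per-subject shape perturbation plus, for patients, a resting droop on the
#' affected side scaled by `5 - g`. The peak face adds the expression basis,
#' attenuated on the affected side by [attenuation_factor], plus a small
#' contralateral compensation (synkinesis-like overshoot: a fraction of the
#' lost movement re-appears mirrored on the healthy side). Both frames
#' receive an independent random head pose (rotations up to 5 degrees,
#' translations up to 10 mm) and isotropic Gaussian sensor noise.
#'
#' @param subject A row-list with fields `subject_id`, `cohort`,
#'   `laterality`, `shape_seed` (see [synthesize_cohort]), or any list
#'   providing them.
#' @param expression One of [expression_types()].
#' @param template A [face_template].
#' @param grade Severity grade `g` in `[1, 5]` for this expression.
#' @param seed Integer seed for pose and noise.
#' @param sensor_sd Sensor noise standard deviation (mm), default 0.1.
#' @param compensation Fraction of the attenuated deficit redirected to the
#'   contralateral side, default 0.1.
#' @param droop_per_grade Resting droop amplitude (mm) per unit of `5 - g`,
#'   default 0.35.
#' @param amplitude Subject-level symmetric scaling of expression amplitude,
#'   default 1.
#' @param cornea_dropout If `TRUE`, adds extra capture noise in the corneal
#'   region during eye closure, mimicking poor stereo reconstruction on the
#'   reflective cornea. Off by default.
#' @return An [expression_capture] with `meta$true_grade` set.
#' @export
synthesize_capture <- function(subject, expression, template, grade,
                               seed = NULL, sensor_sd = 0.1,
                               compensation = 0.1, droop_per_grade = 0.35,
                               amplitude = 1, cornea_dropout = FALSE) {
  if (length(grade) != 1L || is.na(grade) || grade < 1 || grade > 5) {
    stop("`grade` must be a single value in [1, 5]", call. = FALSE)
  }
  V0 <- template$mesh$vertices
  x <- V0[, 1]; y <- V0[, 2]
  lateral <- subject$laterality
  is_patient <- identical(subject$cohort, "patient")
  if (is_patient && !lateral %in% c("left", "right")) {
    stop("patient subjects need a left/right laterality", call. = FALSE)
  }

  shape <- subject_shape_field(template, subject$shape_seed)
  rest_v <- V0 + shape
  if (is_patient) {
    w_droop <- exp(-((abs(x) - 25)^2 + (y + 30)^2) / (2 * 18^2)) *
      side_weight(x, lateral)
    rest_v[, 2] <- rest_v[, 2] - (5 - grade) * droop_per_grade * w_droop
  }

  D <- amplitude * expression_basis(template, expression)
  if (is_patient) {
    sw <- side_weight(x, lateral)
    a <- attenuation_factor(grade)
    deficit <- D * ((1 - a) * sw)
    D <- D - deficit + compensation * mirror_vector_field(deficit, template)
  }
  peak_v <- rest_v + D

  with_seed(seed, {
    n <- nrow(V0)
    rest_v <- rest_v + matrix(stats::rnorm(3 * n, 0, sensor_sd), n, 3)
    peak_v <- peak_v + matrix(stats::rnorm(3 * n, 0, sensor_sd), n, 3)
    if (cornea_dropout && identical(expression, "eye_closure")) {
      eye <- template_region_mask(template, "eye")
      peak_v[eye, 3] <- peak_v[eye, 3] +
        stats::rnorm(sum(eye), 0, 10 * sensor_sd)
    }
    rest_v <- apply_transform(random_pose(), rest_v)
    peak_v <- apply_transform(random_pose(), peak_v)
  })

  fc <- template$mesh$faces
  expression_capture(
    rest = triangle_mesh(rest_v, fc),
    peak = triangle_mesh(peak_v, fc),
    expression = expression,
    laterality = if (is_patient) lateral else "none",
    subject_id = subject$subject_id,
    cohort = subject$cohort,
    meta = list(true_grade = grade))
}

#' Cohort specification for the synthetic generator
#'
#' @param n_patients,n_controls Subjects per arm (default 16 + 16).
#' @param rater_noise Ordinal confusion noise of the simulated grade panels
#'   (standard deviation of the discretized Gaussian; default 0.3, a low
#'   noise at which the 14-observation mode almost always recovers the true
#'   grade).
#' @param sensor_sd Sensor noise (mm).
#' @param seed Master seed; every subject, capture and panel derives its own
#'   seed from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 16, n_controls = 16, rater_noise = 0.3,
                        sensor_sd = 0.1, seed = 1) {
  if (n_patients < 1 || n_controls < 1) {
    stop("`n_patients` and `n_controls` must be at least 1", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 rater_noise = rater_noise, sensor_sd = sensor_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Draw per-expression integer severities for one patient: an overall level
# uniform on 1..4 with sporadic +/-1 deviations per expression, clamped to
# [1, 5].
draw_severities <- function() {
  s0 <- sample(1:4, 1)
  jitter <- sample(c(-1L, 0L, 1L), 5, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  pmin(5L, pmax(1L, s0 + jitter))
}

#' Synthesize a graded unilateral-palsy cohort
#'
#' Generates `(n_patients + n_controls) * 5` expression captures (five
#' voluntary expressions per subject). Patients carry a random unilateral
#' laterality and integer per-expression severities; controls are graded 5
#' (normal) on every expression. The ground-truth severities are returned for
#' parameter-recovery tests. All randomness derives from `spec$seed`, so the
#' same spec reproduces the cohort bit-identically.
#'
#' @param spec A [cohort_spec].
#' @param template A [face_template]; built with defaults when `NULL`.
#' @return A list of class `synthetic_cohort` with `captures` (list of
#'   [expression_capture]), `subjects` (data frame), `truth` (data frame of
#'   capture-level true grades) and `template`.
#' @export
synthesize_cohort <- function(spec = cohort_spec(), template = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(template)) template <- make_template()
  n_sub <- spec$n_patients + spec$n_controls
  exprs <- expression_types()

  seeds <- derive_seeds(spec$seed, 2L * n_sub + n_sub * length(exprs))
  shape_seeds <- seeds[seq_len(n_sub)]
  draw_seeds <- seeds[n_sub + seq_len(n_sub)]
  capture_seeds <- matrix(seeds[2L * n_sub + seq_len(n_sub * length(exprs))],
                          n_sub, length(exprs))

  subjects <- vector("list", n_sub)
  captures <- vector("list", n_sub * length(exprs))
  truth <- vector("list", n_sub * length(exprs))
  k <- 0L
  for (i in seq_len(n_sub)) {
    is_patient <- i <= spec$n_patients
    sub <- list(
      subject_id = sprintf("%s%02d", if (is_patient) "P" else "C",
                           if (is_patient) i else i - spec$n_patients),
      cohort = if (is_patient) "patient" else "control",
      shape_seed = shape_seeds[i])
    sev <- with_seed(draw_seeds[i], {
      lat <- sample(c("left", "right"), 1)
      list(lat = lat, g = if (is_patient) draw_severities() else
        rep(5L, length(exprs)))
    })
    sub$laterality <- if (is_patient) sev$lat else "none"
    subjects[[i]] <- data.frame(subject_id = sub$subject_id,
                                cohort = sub$cohort,
                                laterality = sub$laterality,
                                shape_seed = sub$shape_seed)
    for (j in seq_along(exprs)) {
      k <- k + 1L
      captures[[k]] <- synthesize_capture(
        sub, exprs[j], template, grade = sev$g[j],
        seed = capture_seeds[i, j], sensor_sd = spec$sensor_sd)
      truth[[k]] <- data.frame(
        capture_id = paste(sub$subject_id, exprs[j], sep = "_"),
        subject_id = sub$subject_id, cohort = sub$cohort,
        expression = exprs[j], laterality = sub$laterality,
        true_grade = sev$g[j])
    }
  }
  structure(list(captures = captures,
                 subjects = do.call(rbind, subjects),
                 truth = do.call(rbind, truth),
                 template = template,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients + %d controls, %d captures>\n",
              x$spec$n_patients, x$spec$n_controls, length(x$captures)))
  invisible(x)
}
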