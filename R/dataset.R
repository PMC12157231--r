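# Feature engineering: alignment chain, augmentation, leakage-safe split.

#' Augmentation configuration
#'
#' @param rotation_deg Maximum magnitude of the random yaw rotation (degrees,
#'   uniform in `[-rotation_deg, rotation_deg]` about the vertical axis
#'   through the rest-cloud centroid). Default 15.
#' @param noise_fraction Standard deviation of the added Gaussian coordinate
#'   noise, as a fraction of the rest cloud's size. Default 0.02.
#' @param variants Samples produced per original, the unmodified original
#'   counted as one variant. Default 6 (160 originals -> 960 samples).
#' @param scale_ref Reference scale for the noise: `"rms"` (root-mean-square
#'   vertex distance from the centroid, default) or `"bbox"` (bounding-box
#'   diagonal).
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_deg = 15, noise_fraction = 0.02,
                                variants = 6, scale_ref = c("rms", "bbox")) {
  scale_ref <- match.arg(scale_ref)
  if (rotation_deg < 0) stop("`rotation_deg` must be >= 0", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction >= 1) {
    stop("`noise_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (variants < 1) stop("`variants` must be >= 1", call. = FALSE)
  structure(list(rotation_deg = rotation_deg,
                 noise_fraction = noise_fraction,
                 variants = as.integer(variants), scale_ref = scale_ref),
            class = "augmentation_config")
}

#' Build one network sample from a capture
#'
#' Runs the alignment chain: the rest face is superimposed on the template by
#' partial Procrustes, then the peak face is rigidly aligned to the aligned
#' rest face using the three landmarks, removing head motion between the
#' frames. The two vertex sets become the sample's point-cloud pair; the
#' expression is one-hot encoded and the consensus grade is the regression
#' target.
#'
#' @param capture An [expression_capture], already lateralized to the right
#'   side with [reflect_lateralize].
#' @param template A [face_template].
#' @param consensus_grade Target grade in `[1, 5]`.
#' @return A list of class `palsy_sample` with `rest_points`, `peak_points`,
#'   `expression`, `onehot`, `target_grade` and `provenance`.
#' @export
build_sample <- function(capture, template, consensus_grade) {
  stopifnot(inherits(capture, "expression_capture"))
  if (identical(capture$laterality, "left")) {
    stop("capture must be lateralized (run reflect_lateralize first)",
         call. = FALSE)
  }
  if (consensus_grade < 1 || consensus_grade > 5) {
    stop("`consensus_grade` must lie in [1, 5]", call. = FALSE)
  }
  rest_fit <- partial_procrustes(capture$rest, template$mesh)
  peak_fit <- landmark_rigid_align(capture$peak, rest_fit$aligned,
                                   template$landmark_indices)
  exprs <- expression_types()
  idx <- match(capture$expression, exprs)
  if (is.na(idx)) {
    stop(sprintf("capture expression '%s' is not a voluntary expression",
                 capture$expression), call. = FALSE)
  }
  onehot <- numeric(length(exprs))
  onehot[idx] <- 1
  structure(list(
    rest_points = rest_fit$aligned$vertices,
    peak_points = peak_fit$aligned$vertices,
    expression = capture$expression,
    expression_index = idx,
    onehot = onehot,
    target_grade = as.numeric(consensus_grade),
    provenance = list(subject_id = capture$subject_id,
                      cohort = capture$cohort,
                      capture_id = paste(capture$subject_id,
                                         capture$expression, sep = "_"),
                      origin = "original", augmentation = NULL)),
    class = "palsy_sample")
}

#' @export
print.palsy_sample <- function(x, ...) {
  cat(sprintf("<palsy_sample: %s (%s), %d points, grade %.1f>\n",
              x$provenance$capture_id, x$provenance$origin,
              nrow(x$rest_points), x$target_grade))
  invisible(x)
}

cloud_scale <- function(points, scale_ref) {
  if (scale_ref == "bbox") {
    sqrt(sum((apply(points, 2, max) - apply(points, 2, min))^2))
  } else {
    ctr <- colMeans(points)
    sqrt(mean(rowSums(sweep(points, 2, ctr)^2)))
  }
}

yaw_rotation <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
}

#' Augment point-cloud samples
#'
#' Each original yields `variants` samples: itself plus `variants - 1` copies
#' in which both clouds are rotated by one random yaw angle (uniform within
#' the configured limit, about the vertical axis through the rest-cloud
#' centroid) and perturbed by independent Gaussian coordinate noise with
#' standard deviation `noise_fraction` times the rest cloud's size. Target
#' grades are unchanged; provenance records the augmentation parameters so
#' the split can keep variants with their original.
#'
#' @param samples List of [build_sample] outputs.
#' @param config An [augmentation_config].
#' @param seed Seed for the random angles and noise.
#' @return Flat list of `palsy_sample`s of length
#'   `length(samples) * config$variants`.
#' @export
augment_samples <- function(samples, config = augmentation_config(),
                            seed = NULL) {
  stopifnot(inherits(config, "augmentation_config"))
  seeds <- derive_seeds(seed, length(samples))
  out <- vector("list", length(samples) * config$variants)
  k <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    k <- k + 1L
    out[[k]] <- s
    if (config$variants == 1L) next
    ctr <- colMeans(s$rest_points)
    sd_noise <- config$noise_fraction * cloud_scale(s$rest_points,
                                                    config$scale_ref)
    vs <- with_seed(seeds[i], {
      lapply(seq_len(config$variants - 1L), function(v) {
        ang <- stats::runif(1, -config$rotation_deg, config$rotation_deg)
        R <- yaw_rotation(ang)
        rot <- function(P) sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, `+`)
        a <- s
        a$rest_points <- rot(s$rest_points)
        a$peak_points <- rot(s$peak_points)
        if (sd_noise > 0) {
          n <- nrow(a$rest_points)
          a$rest_points <- a$rest_points +
            matrix(stats::rnorm(3 * n, 0, sd_noise), n, 3)
          a$peak_points <- a$peak_points +
            matrix(stats::rnorm(3 * n, 0, sd_noise), n, 3)
        }
        a$provenance$origin <- "augmented"
        a$provenance$augmentation <- list(angle_deg = ang,
                                          noise_sd = sd_noise, variant = v)
        a
      })
    })
    for (a in vs) { k <- k + 1L; out[[k]] <- a }
  }
  out
}

#' Split samples into train and test partitions
#'
#' Originals are partitioned 80/20 stratified by expression and cohort, and
#' every augmented variant follows its original into the same partition, so
#' near-duplicates never straddle the split. With the default cohort (160
#' originals x 6 variants) this reproduces 768 training and 192 test
#' samples. `mode = "naive"` instead splits the flat augmented list at
#' random, for comparison.
#'
#' @param samples Flat list of (augmented) samples.
#' @param train_fraction Fraction of originals assigned to training,
#'   in (0, 1). Default 0.8.
#' @param seed Seed for the randomized assignment.
#' @param mode `"stratified"` (default, leakage-safe) or `"naive"`.
#' @return A list of class `dataset_split` with `train`, `test` and
#'   `manifest` (one row per sample).
#' @export
split_samples <- function(samples, train_fraction = 0.8, seed = NULL,
                          mode = c("stratified", "naive")) {
  mode <- match.arg(mode)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  info <- data.frame(
    idx = seq_along(samples),
    capture_id = vapply(samples, function(s) s$provenance$capture_id, ""),
    subject_id = vapply(samples, function(s) s$provenance$subject_id, ""),
    cohort = vapply(samples, function(s) s$provenance$cohort, ""),
    expression = vapply(samples, function(s) s$expression, ""),
    origin = vapply(samples, function(s) s$provenance$origin, ""),
    grade = vapply(samples, function(s) s$target_grade, 0),
    stringsAsFactors = FALSE)

  if (mode == "naive") {
    n_test <- round(length(samples) * (1 - train_fraction))
    test_idx <- with_seed(seed, sample(length(samples), n_test))
    info$partition <- ifelse(info$idx %in% test_idx, "test", "train")
  } else {
    caps <- unique(info[c("capture_id", "cohort", "expression")])
    caps$stratum <- paste(caps$expression, caps$cohort, sep = "/")
    n_test_total <- round(nrow(caps) * (1 - train_fraction))
    test_caps <- with_seed(seed, {
      strata <- split(caps$capture_id, caps$stratum)
      sizes <- vapply(strata, length, 0L)
      exact <- sizes * (1 - train_fraction)
      base <- floor(exact)
      remainder <- n_test_total - sum(base)
      extra <- rep(0L, length(strata))
      if (remainder > 0) {
        ord <- order(-(exact - base), stats::runif(length(strata)))
        extra[ord[seq_len(remainder)]] <- 1L
      }
      unlist(lapply(seq_along(strata), function(s) {
        k <- base[s] + extra[s]
        if (k > 0) sample(strata[[s]], k) else character(0)
      }), use.names = FALSE)
    })
    info$partition <- ifelse(info$capture_id %in% test_caps, "test", "train")
  }
  structure(list(train = samples[info$idx[info$partition == "train"]],
                 test = samples[info$idx[info$partition == "test"]],
                 manifest = info),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train, %d test>\n",
              length(x$train), length(x$test)))
  invisible(x)
}

#' Build the full sample set of a synthetic cohort
#'
#' Convenience chain over a synthetic cohort: simulate rater panels, take
#' consensus grades, lateralize every capture to the right, and build one
#' sample per capture.
#'
#' @param cohort A [synthesize_cohort] result.
#' @param panels Optional pre-simulated panels; simulated from the cohort
#'   spec when `NULL`.
#' @return List of `palsy_sample`s (one per capture, unaugmented).
#' @export
build_cohort_samples <- function(cohort, panels = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(panels)) panels <- simulate_cohort_panels(cohort)
  cons <- consensus_grades(panels)
  key <- paste(cons$subject_id, cons$expression, sep = "_")
  lapply(cohort$captures, function(cap) {
    cap <- reflect_lateralize(cap, cohort$template)
    id <- paste(cap$subject_id, cap$expression, sep = "_")
    g <- cons$grade[match(id, key)]
    if (is.na(g)) stop(sprintf("no consensus grade for capture %s", id),
                       call. = FALSE)
    build_sample(cap, cohort$template, g)
  })
}

#' Write / read a split manifest as CSV
#'
#' @param split A [split_samples] result (or its `manifest` data frame).
#' @param path File path.
#' @return `read_split_manifest` returns the manifest data frame.
#' @export
write_split_manifest <- function(split, path) {
  m <- if (inherits(split, "dataset_split")) split$manifest else split
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m$grade <- as.numeric(m$grade)
  m
}
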