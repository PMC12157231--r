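# Sample building, augmentation and the leakage-safe split.

make_small_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    .cohort_cache$co <- synthesize_cohort(cohort_spec(4, 4, seed = 17),
                                          small_template)
    .cohort_cache$samples <- build_cohort_samples(.cohort_cache$co)
  }
  .cohort_cache
}
.cohort_cache <- new.env()

test_that("build_sample runs the alignment chain into the template frame", {
  cc <- make_small_cohort()
  s <- cc$samples[[1]]
  expect_s3_class(s, "palsy_sample")
  expect_identical(nrow(s$rest_points), n_vertices(small_template$mesh))
  expect_identical(nrow(s$peak_points), nrow(s$rest_points))
  expect_equal(sum(s$onehot), 1)
  expect_identical(which(s$onehot == 1), s$expression_index)

  # a capture already in the template frame with no head motion passes
  # through unchanged
  tpl <- small_template
  sub <- list(subject_id = "C09", cohort = "control", laterality = "none",
              shape_seed = 55)
  quiet <- synthesize_capture(sub, "smiling", tpl, grade = 5, seed = 1,
                              sensor_sd = 0)
  # strip the random head pose by rebuilding rest/peak directly
  shape <- quiet$rest
  rest_fit <- partial_procrustes(shape, tpl$mesh)
  base <- build_sample(quiet, tpl, 5)
  expect_equal(base$rest_points, rest_fit$aligned$vertices,
               tolerance = 1e-6)

  expect_error(build_sample(quiet, tpl, 7), "1, 5")
})

test_that("build_sample is invariant to rigid pre-transforms of the raw capture", {
  cc <- make_small_cohort()
  cap <- reflect_lateralize(cc$co$captures[[3]], small_template)
  base <- build_sample(cap, small_template, 3)
  for (seed in 41:42) {
    R <- random_rotation(seed)
    t <- rnorm(3, sd = 30)
    moved <- cap
    for (part in c("rest", "peak")) {
      moved[[part]]$vertices <- cap[[part]]$vertices %*% t(R) +
        matrix(t, n_vertices(cap$rest), 3, byrow = TRUE)
    }
    again <- build_sample(moved, small_template, 3)
    expect_equal(again$rest_points, base$rest_points, tolerance = 1e-6)
    expect_equal(again$peak_points, base$peak_points, tolerance = 1e-6)
  }
})

test_that("unlateralized and non-voluntary captures are rejected", {
  cc <- make_small_cohort()
  lats <- vapply(cc$co$captures, function(cp) cp$laterality, "")
  left <- cc$co$captures[[which(lats == "left")[1]]]
  expect_error(build_sample(left, small_template, 3), "lateralized")
})

test_that("augmentation multiplies counts, keeps rigidity, and is reproducible", {
  cc <- make_small_cohort()
  samples <- cc$samples[1:6]
  aug <- augment_samples(samples, augmentation_config(variants = 6),
                         seed = 7)
  expect_length(aug, 36L)
  origins <- vapply(aug, function(s) s$provenance$origin, "")
  expect_identical(sum(origins == "original"), 6L)

  # rotation-only augmentation preserves all inter-point distances
  rot_only <- augment_samples(samples[1],
                              augmentation_config(noise_fraction = 0,
                                                  variants = 3), seed = 8)
  d0 <- dist(rot_only[[1]]$rest_points[1:40, ])
  for (v in 2:3) {
    expect_equal(as.vector(dist(rot_only[[v]]$rest_points[1:40, ])),
                 as.vector(d0), tolerance = 1e-9)
    # the same yaw is applied to both clouds: relative rest->peak geometry
    # is preserved
    rel0 <- rot_only[[1]]$peak_points - rot_only[[1]]$rest_points
    relv <- rot_only[[v]]$peak_points - rot_only[[v]]$rest_points
    expect_equal(sqrt(rowSums(relv^2)), sqrt(rowSums(rel0^2)),
                 tolerance = 1e-9)
  }

  # zero-noise zero-rotation variants equal the original
  id_aug <- augment_samples(samples[2],
                            augmentation_config(rotation_deg = 0,
                                                noise_fraction = 0,
                                                variants = 4), seed = 9)
  for (v in 2:4) {
    expect_equal(id_aug[[v]]$rest_points, samples[[2]]$rest_points,
                 tolerance = 1e-12)
  }

  # the added noise is scaled by the configured fraction of cloud size
  noisy <- augment_samples(samples[3],
                           augmentation_config(rotation_deg = 0,
                                               noise_fraction = 0.02,
                                               variants = 31), seed = 10)
  ctr <- colMeans(samples[[3]]$rest_points)
  rms <- sqrt(mean(rowSums(sweep(samples[[3]]$rest_points, 2, ctr)^2)))
  resid <- unlist(lapply(noisy[-1], function(s)
    s$rest_points - samples[[3]]$rest_points))
  expect_equal(sd(resid), 0.02 * rms, tolerance = 0.02)

  expect_identical(
    augment_samples(samples, augmentation_config(), seed = 11)[[8]]$rest_points,
    augment_samples(samples, augmentation_config(), seed = 11)[[8]]$rest_points)
  expect_error(augmentation_config(noise_fraction = 1.2), "noise_fraction")
  expect_error(augmentation_config(variants = 0), "variants")
})

test_that("split keeps augmented variants with their original and stratifies", {
  cc <- make_small_cohort()
  aug <- augment_samples(cc$samples, augmentation_config(), seed = 12)
  sp <- split_samples(aug, train_fraction = 0.8, seed = 13)
  expect_identical(length(sp$train) + length(sp$test), length(aug))

  # leakage guard: no capture id straddles the partitions
  m <- sp$manifest
  expect_length(intersect(m$capture_id[m$partition == "train"],
                          m$capture_id[m$partition == "test"]), 0L)
  # all 6 variants of a capture share its partition
  per_cap <- table(m$capture_id, m$partition)
  expect_true(all(per_cap %in% c(0L, 6L)))

  # test originals per expression within one of the floor/ceiling counts
  test_caps <- unique(m[m$partition == "test",
                        c("capture_id", "expression")])
  per_expr <- table(test_caps$expression)
  expect_true(all(per_expr %in% 1:2))  # 8 originals/expression, 20% -> 1-2

  # manifest round-trips losslessly through CSV
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_split_manifest(sp, path)
  expect_identical(read_split_manifest(path), m)

  # reproducible given the seed
  sp2 <- split_samples(aug, train_fraction = 0.8, seed = 13)
  expect_identical(sp2$manifest$partition, m$partition)
  expect_error(split_samples(aug, train_fraction = 1.2), "between 0 and 1")
})

test_that("naive mode splits the flat list at the requested fraction", {
  cc <- make_small_cohort()
  aug <- augment_samples(cc$samples, augmentation_config(), seed = 14)
  sp <- split_samples(aug, train_fraction = 0.8, seed = 15, mode = "naive")
  expect_identical(length(sp$test), as.integer(round(length(aug) * 0.2)))
})
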