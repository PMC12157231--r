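# Synthetic template and graded cohort generator.

test_that("template has the requested vertex count, exact symmetry and valid landmarks", {
  tpl <- make_template()          # default template
  expect_identical(n_vertices(tpl$mesh), 7859L)
  expect_lt(max(asymmetry_field(tpl$mesh, tpl)$values), 1e-9)

  for (n in c(200L, 300L, 1234L)) {
    t2 <- make_template(n)
    expect_identical(n_vertices(t2$mesh), n)
    # involution over all vertices
    expect_identical(t2$symmetry_pairs[t2$symmetry_pairs],
                     seq_len(n))
    V <- t2$mesh$vertices
    Vp <- V[t2$symmetry_pairs, ]
    expect_lt(max(abs(Vp[, 1] + V[, 1])), 1e-9)
    expect_lt(max(abs(Vp[, 2:3] - V[, 2:3])), 1e-9)
    # midline vertices sit exactly on the sagittal plane
    expect_true(all(V[t2$midline_vertices, 1] == 0))
    # landmarks: left/right inner eyes are a symmetry pair, nose on midline
    lm <- t2$landmark_indices
    expect_identical(t2$symmetry_pairs[lm[["inner_eye_left"]]],
                     lm[["inner_eye_right"]])
    expect_true(lm[["nose_tip"]] %in% t2$midline_vertices)
    # faces reference valid vertices
    expect_true(all(t2$mesh$faces >= 1 & t2$mesh$faces <= n))
  }

  expect_error(make_template(5), "at least")
  # construction is reproducible
  expect_identical(make_template(500)$mesh$vertices,
                   make_template(500)$mesh$vertices)
})

test_that("expression bases are symmetric, regional, and sized like real excursions", {
  tpl <- small_template
  for (e in expression_types()) {
    D <- expression_basis(tpl, e)
    # respects the left-right pairing: x odd, y/z even
    Dp <- D[tpl$symmetry_pairs, ]
    expect_lt(max(abs(Dp[, 1] + D[, 1])), 1e-9)
    expect_lt(max(abs(Dp[, 2:3] - D[, 2:3])), 1e-9)
    # moving the template by a symmetric field leaves it symmetric
    moved <- tpl$mesh
    moved$vertices <- moved$vertices + D
    expect_lt(max(asymmetry_field(moved, tpl)$values), 1e-6)
    # peak magnitude in the 5-10 mm range
    mags <- sqrt(rowSums(D^2))
    expect_gt(max(mags), 5)
    expect_lt(max(mags), 10)
  }
  expect_true(all(expression_basis(tpl, "rest") == 0))

  # smiling is a lower-face expression
  D <- expression_basis(tpl, "smiling")
  mags <- sqrt(rowSums(D^2))
  lower <- template_region_mask(tpl, "lower_face")
  expect_gt(sum(mags[lower]) / sum(mags), 0.9)
})

test_that("captures attenuate the affected side according to the grade", {
  tpl <- small_template
  sub_pat <- list(subject_id = "P01", cohort = "patient",
                  laterality = "right", shape_seed = 101)
  sub_ctl <- list(subject_id = "C01", cohort = "control",
                  laterality = "none", shape_seed = 102)

  side_ratio <- function(cap) {
    rest_fit <- partial_procrustes(cap$rest, tpl$mesh)
    peak_fit <- landmark_rigid_align(cap$peak, rest_fit$aligned,
                                     tpl$landmark_indices)
    d <- displacement_field(rest_fit$aligned, peak_fit$aligned)
    field_side_means(d, tpl, cap$expression)$ratio
  }

  ctl <- synthesize_capture(sub_ctl, "smiling", tpl, grade = 5, seed = 1)
  expect_identical(n_vertices(ctl$rest), n_vertices(tpl$mesh))
  expect_identical(n_vertices(ctl$peak), n_vertices(tpl$mesh))
  expect_equal(side_ratio(ctl), 1, tolerance = 0.15)

  g1 <- synthesize_capture(sub_pat, "smiling", tpl, grade = 1, seed = 2)
  expect_lt(side_ratio(g1), 0.15)

  expect_error(synthesize_capture(sub_pat, "smiling", tpl, grade = 0),
               "grade")
})

test_that("affected-side movement increases monotonically with grade", {
  tpl <- small_template
  mean_move <- matrix(NA_real_, 10, 5)
  for (s in 1:10) {
    sub <- list(subject_id = "P", cohort = "patient", laterality = "right",
                shape_seed = 200 + s)
    for (g in 1:5) {
      cap <- synthesize_capture(sub, "smiling", tpl, grade = g,
                                seed = 300 + 10 * s + g)
      rest_fit <- partial_procrustes(cap$rest, tpl$mesh)
      peak_fit <- landmark_rigid_align(cap$peak, rest_fit$aligned,
                                       tpl$landmark_indices)
      d <- displacement_field(rest_fit$aligned, peak_fit$aligned)
      mean_move[s, g] <- field_side_means(d, tpl, "smiling")$right
    }
  }
  avg <- colMeans(mean_move)
  expect_true(all(diff(avg) > 0))
})

test_that("control asymmetry stays below the noise ceiling; severe palsy exceeds it", {
  tpl <- small_template
  spec <- cohort_spec(6, 3, seed = 5)
  co <- synthesize_cohort(spec, tpl)
  ceiling_mm <- 5 * spec$sensor_sd
  for (i in seq_along(co$captures)) {
    cap <- reflect_lateralize(co$captures[[i]], tpl)
    rest_fit <- partial_procrustes(cap$rest, tpl$mesh)
    peak_fit <- landmark_rigid_align(cap$peak, rest_fit$aligned,
                                     tpl$landmark_indices)
    asym <- asymmetry_field(peak_fit$aligned, tpl)
    if (cap$cohort == "control") {
      expect_lt(mean(asym$values), ceiling_mm)
    } else if (cap$meta$true_grade <= 2) {
      # the deficit lives in the expression's moving region
      expect_gt(field_side_means(asym, tpl, cap$expression)$right,
                ceiling_mm)
    }
  }
})

test_that("cohort synthesis yields 5 captures per subject, retains truth, reproduces bit-identically", {
  tpl <- small_template
  co <- synthesize_cohort(cohort_spec(2, 2, seed = 9), tpl)
  expect_length(co$captures, 20L)
  expect_identical(nrow(co$truth), 20L)
  expect_true(all(co$truth$true_grade[co$truth$cohort == "control"] == 5))
  expect_true(all(co$truth$laterality[co$truth$cohort == "patient"] %in%
                    c("left", "right")))
  expect_true(all(co$truth$true_grade >= 1 & co$truth$true_grade <= 5))

  co2 <- synthesize_cohort(cohort_spec(2, 2, seed = 9), tpl)
  expect_identical(co$truth, co2$truth)
  expect_identical(co$captures[[7]]$peak$vertices,
                   co2$captures[[7]]$peak$vertices)

  co3 <- synthesize_cohort(cohort_spec(2, 2, seed = 10), tpl)
  expect_false(identical(co$captures[[7]]$peak$vertices,
                         co3$captures[[7]]$peak$vertices))
  expect_error(cohort_spec(0, 2), "at least 1")
})
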