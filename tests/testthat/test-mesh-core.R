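# Geometry engine: Procrustes superimposition, landmark alignment,
# mirroring, asymmetry and displacement fields.

test_that("partial Procrustes is exact on identity and recoverable rigid motions", {
  M <- random_mesh(60, seed = 2)

  fit0 <- partial_procrustes(M, M)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(fit0$rmsd, 1e-9)

  for (seed in 1:5) {
    R <- random_rotation(seed)
    t <- rnorm(3, sd = 50)
    moved <- M
    moved$vertices <- M$vertices %*% t(R) +
      matrix(t, n_vertices(M), 3, byrow = TRUE)
    fit <- partial_procrustes(moved, M)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(fit$aligned$vertices, M$vertices, tolerance = 1e-6)
  }
})

test_that("partial Procrustes preserves scale and is invariant to rigid pre-transforms", {
  M <- random_mesh(80, seed = 3)
  target <- random_mesh(80, seed = 4)
  fit <- partial_procrustes(M, target)

  csize <- function(V) sqrt(sum(sweep(V, 2, colMeans(V))^2))
  expect_equal(csize(fit$aligned$vertices), csize(M$vertices),
               tolerance = 1e-9)

  # pre-rotating the moving mesh must not change the aligned coordinates
  for (seed in 6:8) {
    pre <- M
    R <- random_rotation(seed)
    pre$vertices <- M$vertices %*% t(R) +
      matrix(rnorm(3, sd = 30), n_vertices(M), 3, byrow = TRUE)
    fit2 <- partial_procrustes(pre, target)
    expect_equal(fit2$aligned$vertices, fit$aligned$vertices,
                 tolerance = 1e-6)
  }
})

test_that("partial Procrustes matches a brute-force rotation grid search", {
  # 4-point toy set, rotated about the vertical axis and perturbed: the
  # oracle scans yaw angles at 0.1 degree resolution.
  P <- rbind(c(10, 0, 0), c(-5, 8, 2), c(0, -7, 5), c(-5, -1, -7))
  theta_true <- 27.3
  yaw <- function(deg) {
    th <- deg * pi / 180
    rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  }
  set.seed(42)
  moving <- P %*% t(yaw(theta_true)) +
    matrix(c(3, -2, 5), 4, 3, byrow = TRUE) + matrix(rnorm(12, sd = 0.01), 4, 3)

  grid <- seq(-180, 180, by = 0.1)
  rmsd_at <- function(deg) {
    A <- moving %*% t(yaw(-deg))   # undo candidate yaw
    Ac <- sweep(A, 2, colMeans(A))
    Pc <- sweep(P, 2, colMeans(P))
    sqrt(mean(rowSums((Ac - Pc)^2)))
  }
  grid_rmsd <- vapply(grid, rmsd_at, 0)
  theta_grid <- grid[which.min(grid_rmsd)]

  fit <- partial_procrustes(triangle_mesh(moving, matrix(c(1L, 2L, 3L), 1)),
                            triangle_mesh(P, matrix(c(1L, 2L, 3L), 1)))
  R <- fit$transform$rotation
  theta_fit <- atan2(R[1, 3], R[1, 1]) * 180 / pi
  expect_lt(abs(theta_fit - (-theta_grid)), 0.1 + 1e-9)
  expect_lte(fit$rmsd, min(grid_rmsd) + 1e-9)
})

test_that("degenerate and mismatched configurations are rejected", {
  line <- triangle_mesh(cbind(1:10, 2 * (1:10), -1:-10),
                        matrix(c(1L, 2L, 3L), 1))
  M <- random_mesh(10)
  expect_error(partial_procrustes(line, M), "degenerate")
  expect_error(partial_procrustes(random_mesh(10), random_mesh(12)),
               "correspondence")
  coincident <- triangle_mesh(matrix(1, 10, 3), matrix(c(1L, 2L, 3L), 1))
  expect_error(partial_procrustes(coincident, M), "degenerate")
})

test_that("landmark alignment removes pure head motion and matches a Horn oracle", {
  tpl <- tiny_template
  lm <- tpl$landmark_indices
  rest <- tpl$mesh

  fit_id <- landmark_rigid_align(rest, rest, lm)
  expect_equal(fit_id$transform$rotation, diag(3), tolerance = 1e-9)
  expect_lt(fit_id$landmark_rmsd, 1e-9)

  # peak = rigidly moved rest (pure head motion, no expression)
  R <- random_rotation(11); t <- c(4, -7, 12)
  peak <- rest
  peak$vertices <- rest$vertices %*% t(R) +
    matrix(t, n_vertices(rest), 3, byrow = TRUE)
  fit <- landmark_rigid_align(peak, rest, lm)
  expect_lt(max(abs(fit$aligned$vertices - rest$vertices)), 1e-6)

  # with an expression deformation on top, the landmark residual equals the
  # 3-point closed-form fit's residual
  set.seed(12)
  deformed <- rest
  deformed$vertices <- rest$vertices +
    expression_basis(tpl, "smiling") +
    matrix(rnorm(3 * n_vertices(rest), sd = 0.05), n_vertices(rest), 3)
  moved <- deformed
  moved$vertices <- deformed$vertices %*% t(R) +
    matrix(t, n_vertices(rest), 3, byrow = TRUE)
  fit2 <- landmark_rigid_align(moved, rest, lm)
  oracle <- horn_fit(moved$vertices[lm, ], rest$vertices[lm, ])
  expect_equal(fit2$landmark_rmsd, oracle$rmsd, tolerance = 1e-8)
  expect_equal(fit2$transform$rotation, oracle$R, tolerance = 1e-6)
})

test_that("collinear landmarks are rejected", {
  M <- random_mesh(30, seed = 5)
  M$vertices[1, ] <- c(0, 0, 0)
  M$vertices[2, ] <- c(1, 1, 1)
  M$vertices[3, ] <- c(2, 2, 2)
  expect_error(landmark_rigid_align(M, random_mesh(30, seed = 6), 1:3),
               "collinear")
})

test_that("mirroring is an involution that fixes the template and reflects bumps", {
  tpl <- tiny_template
  mesh <- tpl$mesh

  expect_equal(mirror_mesh(mesh, tpl)$vertices, mesh$vertices,
               tolerance = 1e-9)

  set.seed(7)
  bent <- mesh
  bent$vertices <- bent$vertices + matrix(rnorm(3 * n_vertices(mesh)),
                                          n_vertices(mesh), 3)
  expect_identical(mirror_mesh(mirror_mesh(bent, tpl), tpl)$vertices,
                   bent$vertices)

  # displacing one off-midline vertex +2 mm in x shows up on its pair,
  # reflected
  off <- setdiff(seq_len(n_vertices(mesh)), tpl$midline_vertices)[1]
  pair <- tpl$symmetry_pairs[off]
  bumped <- mesh
  bumped$vertices[off, 1] <- bumped$vertices[off, 1] + 2
  mb <- mirror_mesh(bumped, tpl)
  expect_equal(mb$vertices[pair, 1], mesh$vertices[pair, 1] - 2,
               tolerance = 1e-9)
  moved <- which(rowSums(abs(mb$vertices - mesh$vertices)) > 1e-12)
  expect_identical(moved, pair)
})

test_that("asymmetry field: zero for symmetric meshes, paired for bumps, oracle for random", {
  tpl <- tiny_template
  expect_lt(max(asymmetry_field(tpl$mesh, tpl)$values), 1e-9)

  # a single left-side bump registers only at the bump vertex and its pair,
  # with equal magnitudes
  off <- setdiff(seq_len(n_vertices(tpl$mesh)), tpl$midline_vertices)[5]
  pair <- tpl$symmetry_pairs[off]
  bumped <- tpl$mesh
  bumped$vertices[off, 3] <- bumped$vertices[off, 3] + 2
  f <- asymmetry_field(bumped, tpl)
  big <- which(f$values > 0.5)
  expect_setequal(big, c(off, pair))
  expect_equal(f$values[off], f$values[pair], tolerance = 1e-9)

  # random asymmetric mesh: matches an explicit re-implementation using the
  # independent Horn solver
  set.seed(8)
  warped <- tpl$mesh
  warped$vertices <- warped$vertices +
    matrix(rnorm(3 * n_vertices(tpl$mesh), sd = 0.8),
           n_vertices(tpl$mesh), 3)
  f2 <- asymmetry_field(warped, tpl)
  W <- warped$vertices
  Wm <- W[tpl$symmetry_pairs, ]
  Wm[, 1] <- -Wm[, 1]
  o <- horn_fit(Wm, W)
  expect_equal(f2$values, sqrt(rowSums((W - o$aligned)^2)),
               tolerance = 1e-6)
})

test_that("asymmetry is pairing-symmetric and rigid-motion invariant", {
  tpl <- tiny_template
  set.seed(9)
  warped <- tpl$mesh
  warped$vertices <- warped$vertices +
    matrix(rnorm(3 * n_vertices(tpl$mesh), sd = 0.6),
           n_vertices(tpl$mesh), 3)
  f <- asymmetry_field(warped, tpl)
  expect_equal(f$values, f$values[tpl$symmetry_pairs], tolerance = 1e-6)

  fm <- asymmetry_field(mirror_mesh(warped, tpl), tpl)
  expect_equal(fm$values, f$values, tolerance = 1e-6)

  for (seed in 13:15) {
    moved <- warped
    moved$vertices <- warped$vertices %*% t(random_rotation(seed)) +
      matrix(rnorm(3, sd = 40), n_vertices(warped), 3, byrow = TRUE)
    expect_equal(asymmetry_field(moved, tpl)$values, f$values,
                 tolerance = 1e-6)
  }
})

test_that("displacement field equals per-vertex norms (loop oracle) and edge cases", {
  tpl <- tiny_template
  rest <- tpl$mesh
  expect_true(all(displacement_field(rest, rest)$values == 0))

  shifted <- rest
  shifted$vertices[17, ] <- shifted$vertices[17, ] + c(0, 3, 0)
  f <- displacement_field(rest, shifted)
  expect_equal(f$values[17], 3)
  expect_equal(sum(f$values != 0), 1L)

  set.seed(10)
  peak <- rest
  peak$vertices <- peak$vertices + matrix(rnorm(3 * n_vertices(rest)),
                                          n_vertices(rest), 3)
  f2 <- displacement_field(rest, peak)
  oracle <- vapply(seq_len(n_vertices(rest)), function(i)
    sqrt(sum((peak$vertices[i, ] - rest$vertices[i, ])^2)), 0)
  expect_equal(f2$values, oracle, tolerance = 1e-12)
})

test_that("reflect_lateralize standardizes left palsy to the right and is idempotent", {
  tpl <- small_template
  spec <- cohort_spec(4, 1, seed = 33)
  co <- synthesize_cohort(spec, tpl)
  lats <- vapply(co$captures, function(cp) cp$laterality, "")
  left <- co$captures[[which(lats == "left")[1]]]
  right <- co$captures[[which(lats == "right")[1]]]

  expect_identical(reflect_lateralize(right, tpl), right)

  fixed <- reflect_lateralize(left, tpl)
  expect_identical(fixed$laterality, "right")
  # asymmetry is reflection-invariant
  expect_equal(asymmetry_field(fixed$peak, tpl)$values,
               asymmetry_field(left$peak, tpl)$values, tolerance = 1e-6)
  # applying twice equals applying once
  expect_identical(reflect_lateralize(fixed, tpl), fixed)

  # deficit lands on the right half after reflection: align and compare side
  # means of the displacement field
  rest_fit <- partial_procrustes(fixed$rest, tpl$mesh)
  peak_fit <- landmark_rigid_align(fixed$peak, rest_fit$aligned,
                                   tpl$landmark_indices)
  disp <- displacement_field(rest_fit$aligned, peak_fit$aligned)
  rs <- template_region_mask(tpl, "right_side")
  ls <- template_region_mask(tpl, "left_side")
  g <- left$meta$true_grade
  if (g <= 3) {
    expect_lt(mean(disp$values[rs]), mean(disp$values[ls]))
  }

  unknown <- left
  unknown$laterality <- "none"
  expect_error(reflect_lateralize(unknown, tpl), "laterality")
})

test_that("rigid transform constructor rejects reflections and scaling", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "reflection")
  expect_error(rigid_transform(2 * diag(3)), "orthonormal")
  tr <- rigid_transform(random_rotation(21), c(1, 2, 3))
  inv <- rigid_transform(t(tr$rotation),
                         -as.vector(t(tr$rotation) %*% tr$translation))
  comp <- compose_transforms(inv, tr)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-12)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-12)
})
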