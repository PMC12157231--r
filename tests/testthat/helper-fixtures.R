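# Shared fixtures, built once per test run.

# Small template: fast enough for geometry tests, large enough to have
# distinct landmark/midline structure.
tiny_template <- make_template(300)

# Mid-sized template used by the synthetic-cohort tests.
small_template <- make_template(800)

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(
    c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
    c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
    c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

random_mesh <- function(n = 50, seed = 1) {
  set.seed(seed)
  triangle_mesh(matrix(rnorm(n * 3, sd = 20), n, 3),
                cbind(1:(n - 2), 2:(n - 1), 3:n))
}

# Independent rigid-fit oracle: Horn's closed-form quaternion method,
# sharing no code with the package's SVD-based solver.
horn_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  S <- t(Ac) %*% Bc
  N <- rbind(
    c(S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1]),
    c(S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3]),
    c(S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2]),
    c(S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]))
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  R <- rbind(
    c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
    c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
    c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
  t <- cb - as.vector(R %*% ca)
  aligned <- A %*% t(R) + matrix(t, nrow(A), 3, byrow = TRUE)
  list(R = R, t = t, aligned = aligned,
       rmsd = sqrt(mean(rowSums((aligned - B)^2))))
}

# Build a minimal valid sample directly from point matrices (bypasses the
# alignment chain; for network-level tests).
make_raw_sample <- function(rest, peak, expression, grade,
                            capture_id = "S_x", subject_id = "S",
                            cohort = "patient") {
  exprs <- expression_types()
  idx <- match(expression, exprs)
  onehot <- numeric(5); onehot[idx] <- 1
  structure(list(rest_points = rest, peak_points = peak,
                 expression = expression, expression_index = idx,
                 onehot = onehot, target_grade = grade,
                 provenance = list(subject_id = subject_id, cohort = cohort,
                                   capture_id = capture_id,
                                   origin = "original",
                                   augmentation = NULL)),
            class = "palsy_sample")
}

# Tiny random sample set covering all five expressions.
make_toy_samples <- function(n, n_points = 40, seed = 1) {
  set.seed(seed)
  exprs <- expression_types()
  lapply(seq_len(n), function(i) {
    make_raw_sample(matrix(rnorm(n_points * 3, sd = 30), n_points, 3),
                    matrix(rnorm(n_points * 3, sd = 30), n_points, 3),
                    exprs[(i - 1) %% 5 + 1],
                    sample(1:5, 1),
                    capture_id = sprintf("S%02d_x", i),
                    subject_id = sprintf("S%02d", i))
  })
}
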