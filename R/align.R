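# Rigid alignment of corresponded point sets (Kabsch / orthogonal Procrustes).

# Least-squares proper rotation + translation mapping moving -> target,
# solved in closed form from the SVD of the 3x3 cross-covariance.
kabsch_fit <- function(Vm, Vt, degeneracy_tol = 1e-12) {
  cm <- colMeans(Vm)
  ct <- colMeans(Vt)
  A <- sweep(Vm, 2, cm)
  B <- sweep(Vt, 2, ct)
  H <- crossprod(A, B)
  s <- svd(H)
  # Collinear or coincident configurations leave the rotation undetermined
  # about the degenerate axis: require rank >= 2 of the cross-covariance.
  if (s$d[1] <= 0 || s$d[2] < degeneracy_tol * s$d[1]) {
    stop("degenerate configuration: points are collinear or coincident",
         call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, ct - as.vector(R %*% cm))
}

#' Partial Procrustes superimposition of corresponded meshes
#'
#' Finds the rotation and translation (no scaling, no reflection) that
#' minimizes the sum of squared distances between corresponded vertices of
#' `moving` and `target`, and applies it to `moving`. Correspondence is by
#' vertex index. Used to place a rest-frame face into the template frame and
#' to align a mirrored face back onto its original.
#'
#' @param moving,target `triangle_mesh` objects (or n x 3 matrices) with equal
#'   vertex counts and index-wise correspondence.
#' @return A list with `transform` (the fitted [rigid_transform]), `aligned`
#'   (the transformed `moving`), and `rmsd` (root-mean-square corresponded
#'   distance after alignment, mm).
#' @export
partial_procrustes <- function(moving, target) {
  Vm <- if (inherits(moving, "triangle_mesh")) moving$vertices else as.matrix(moving)
  Vt <- if (inherits(target, "triangle_mesh")) target$vertices else as.matrix(target)
  if (nrow(Vm) != nrow(Vt)) {
    stop(sprintf("correspondence error: %d vs %d vertices", nrow(Vm), nrow(Vt)),
         call. = FALSE)
  }
  tr <- kabsch_fit(Vm, Vt)
  Va <- apply_transform(tr, Vm)
  aligned <- if (inherits(moving, "triangle_mesh")) {
    m <- moving; m$vertices <- Va; m
  } else Va
  list(transform = tr,
       aligned = aligned,
       rmsd = sqrt(mean(rowSums((Va - Vt)^2))))
}

#' Three-landmark rigid alignment
#'
#' Computes the least-squares rigid fit on three landmark pairs only (the
#' inner eye corners and the nose tip) and applies it to the whole moving
#' mesh. Because these landmarks are nearly motionless across expressions,
#' this removes head motion between the rest and peak frames without
#' absorbing the expression deformation itself.
#'
#' @param moving `triangle_mesh` to align (typically the peak frame).
#' @param reference `triangle_mesh` providing the target landmark positions
#'   (typically the aligned rest frame); it is never modified.
#' @param landmarks Integer vector of three vertex indices valid in both
#'   meshes.
#' @return A list with `transform`, `aligned`, and `landmark_rmsd` (residual
#'   over the three landmarks, mm).
#' @export
landmark_rigid_align <- function(moving, reference, landmarks) {
  stopifnot(inherits(moving, "triangle_mesh"),
            inherits(reference, "triangle_mesh"))
  landmarks <- as.integer(landmarks)
  if (length(landmarks) != 3L) {
    stop("`landmarks` must contain exactly three vertex indices", call. = FALSE)
  }
  nm <- n_vertices(moving)
  if (any(landmarks < 1L | landmarks > min(nm, n_vertices(reference)))) {
    stop("landmark indices out of range", call. = FALSE)
  }
  Pm <- moving$vertices[landmarks, , drop = FALSE]
  Pr <- reference$vertices[landmarks, , drop = FALSE]
  check_noncollinear <- function(P, which) {
    u <- P[2, ] - P[1, ]
    v <- P[3, ] - P[1, ]
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    scale <- max(sqrt(sum(u^2)), sqrt(sum(v^2)))
    if (scale <= 0 || sqrt(sum(cr^2)) < 1e-9 * scale^2) {
      stop(sprintf("degenerate configuration: landmarks are collinear in the %s mesh",
                   which), call. = FALSE)
    }
  }
  check_noncollinear(Pm, "moving")
  check_noncollinear(Pr, "reference")
  tr <- kabsch_fit(Pm, Pr)
  aligned <- apply_transform(tr, moving)
  Pa <- aligned$vertices[landmarks, , drop = FALSE]
  list(transform = tr,
       aligned = aligned,
       landmark_rmsd = sqrt(mean(rowSums((Pa - Pr)^2))))
}
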