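#' Rigid ICP registration of two meshes
#'
#' Iterative closest point with closed-form Procrustes updates (rotation +
#' translation, no scaling). When four paired landmarks are supplied they
#' provide the initial alignment; otherwise centroids are matched first.
#' The point-to-nearest-point cost is non-increasing across iterations by
#' construction.
#'
#' @param moving,reference [triangle_mesh()] objects.
#' @param init optional list with `moving` and `reference` 4 x 3 paired
#'   landmark matrices for initialization.
#' @param max_iter maximum ICP iterations.
#' @param tol convergence threshold on the relative cost change.
#' @param n_samples number of moving vertices used for matching (all if the
#'   mesh is smaller).
#' @return list with `rotation`, `translation`, `mesh` (transformed moving
#'   mesh), `cost` (final RMS distance, mm), `cost_trace`, `converged`.
#' @export
rigid_register <- function(moving, reference, init = NULL, max_iter = 50L,
                           tol = 1e-8, n_samples = 2000L) {
  validate_mesh(moving, require_nondegenerate = FALSE)
  validate_mesh(reference, require_nondegenerate = FALSE)
  mv <- moving$vertices
  if (!is.null(init)) {
    k0 <- kabsch(init$moving, init$reference)
    R <- k0$rotation; t_vec <- k0$translation
  } else {
    R <- diag(3)
    t_vec <- colMeans(reference$vertices) - colMeans(mv)
  }
  idx <- if (nrow(mv) > n_samples) {
    round(seq(1L, nrow(mv), length.out = n_samples))
  } else {
    seq_len(nrow(mv))
  }
  src <- mv[idx, , drop = FALSE]
  ref_v <- reference$vertices
  cost_trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- apply_rigid(src, R, t_vec)
    nn <- nn_points(cur, ref_v, k = 1L)
    cost <- sqrt(mean(nn$dist^2))
    cost_trace <- c(cost_trace, cost)
    if (is.finite(prev) && (prev - cost) < tol * max(prev, 1e-12)) {
      converged <- TRUE
      break
    }
    prev <- cost
    k <- kabsch(src, ref_v[nn$index[, 1L], , drop = FALSE])
    R <- k$rotation; t_vec <- k$translation
  }
  if (!converged) {
    warning("ICP did not converge within ", max_iter,
            " iterations; returning best transform")
  }
  out_mesh <- triangle_mesh(apply_rigid(mv, R, t_vec), moving$faces,
                            id = moving$id, check = FALSE)
  list(rotation = R, translation = t_vec, mesh = out_mesh,
       cost = cost_trace[length(cost_trace)], cost_trace = cost_trace,
       converged = converged)
}

#' Thin-plate-spline warp from paired control points
#'
#' 3D biharmonic TPS (kernel U(r) = r) interpolating `source` control points
#' onto `target` positions; with four points in general position the affine
#' part captures any affine map exactly (zero bending).
#'
#' @param source,target k x 3 paired control-point matrices.
#' @param lambda ridge regularization on the kernel block.
#' @return a function mapping an n x 3 matrix through the warp.
#' @export
tps_warp <- function(source, target, lambda = 1e-10) {
  S <- as_point_matrix(source, "source")
  T_ <- as_point_matrix(target, "target")
  k <- nrow(S)
  K <- as.matrix(stats::dist(S))
  K <- K + diag(lambda, k)
  P <- cbind(1, S)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(T_, matrix(0, 4L, 3L))
  coefs <- tryCatch(solve(A, rhs), error = function(e) {
    # rank-deficient control configuration: least-squares fallback
    qr.coef(qr(A, LAPACK = TRUE), rhs)
  })
  coefs[is.na(coefs)] <- 0
  w <- coefs[seq_len(k), , drop = FALSE]
  a <- coefs[k + 1:4, , drop = FALSE]
  function(x) {
    x <- as_point_matrix(x)
    U <- sqrt(pmax(outer(rowSums(x^2), rowSums(S^2), "+") -
                     2 * tcrossprod(x, S), 0))
    cbind(1, x) %*% a + U %*% w
  }
}

# Sparse uniform graph Laplacian of the template topology (row-normalized).
mesh_laplacian <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  i <- c(e[, 1L], e[, 2L])
  j <- c(e[, 2L], e[, 1L])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(n) - Matrix::Diagonal(n, 1 / deg) %*% A
}

#' Non-rigid correspondence of a mesh with a reference template
#'
#' Establishes dense point-to-point correspondence by deforming the
#' reference template onto the (already rigidly registered) moving surface:
#' an initial thin-plate-spline warp driven by the four paired bone
#' landmarks, followed by iterations of nearest-point projection whose
#' displacement field is regularized by a screened template Laplacian with a
#' decreasing stiffness schedule, and a final pure projection so the output
#' vertices lie on the moving surface.
#'
#' @param moving a [triangle_mesh()], rigidly registered to the reference.
#' @param reference the template [triangle_mesh()].
#' @param landmarks list with `moving` and `reference` 4 x 3 paired bone
#'   landmark matrices (optional when the surfaces are already close).
#' @param iterations projection/smoothing rounds.
#' @param stiffness initial smoothing weight; halved each round.
#' @param tolerance mean surface-distance (mm) the output must reach.
#' @return object of class `corresponded_shape`: `vertices` (template-count
#'   x 3, on the moving surface), `faces` (template topology), `source_id`,
#'   `mean_surface_dist`.
#' @export
nonrigid_correspond <- function(moving, reference, landmarks = NULL,
                                iterations = 8L, stiffness = 2,
                                tolerance = 1.0) {
  v <- reference$vertices
  if (!is.null(landmarks)) {
    warp <- tps_warp(landmarks$reference, landmarks$moving)
    v <- warp(v)
  }
  L <- mesh_laplacian(reference)
  n <- nrow(v)
  beta <- stiffness
  for (it in seq_len(iterations)) {
    proj <- closest_on_surface(v, moving)
    d <- proj$points - v
    if (beta > 1e-8) {
      M <- Matrix::Diagonal(n) + beta * L
      d <- as.matrix(Matrix::solve(M, d))
    }
    v <- v + d
    beta <- beta / 2
  }
  proj <- closest_on_surface(v, moving)
  v <- proj$points
  msd <- mean(proj$dist)  # zero by construction after final projection
  # diagnostic: distance from the moving vertices to the deformed template
  cover <- mean(nn_points(moving$vertices, v, k = 1L)$dist)
  if (cover > 5 * tolerance) {
    stop(sprintf("non-rigid correspondence failed: mean coverage distance %.2f mm exceeds %.2f mm",
                 cover, 5 * tolerance), call. = FALSE)
  }
  structure(list(vertices = v, faces = reference$faces,
                 source_id = moving$id, mean_surface_dist = msd,
                 coverage_dist = cover),
            class = "corresponded_shape")
}

#' @export
print.corresponded_shape <- function(x, ...) {
  cat(sprintf("corresponded_shape '%s': %d template vertices (coverage %.3f mm)\n",
              x$source_id %||% "?", nrow(x$vertices), x$coverage_dist))
  invisible(x)
}

#' Map digitized landmarks to template vertex indices
#'
#' Assigns each bone landmark the nearest template vertex once, on the
#' reference; those indices identify the model landmarks thereafter.
#'
#' @param reference template [triangle_mesh()].
#' @param bone_landmarks a bone-level [landmark_set()] in template space.
#' @return named integer vector of vertex indices (AA, TS, AI, AC).
#' @export
landmark_vertex_indices <- function(reference, bone_landmarks) {
  nn <- nn_points(bone_landmarks$points, reference$vertices, k = 1L)
  stats::setNames(nn$index[, 1L], rownames(bone_landmarks$points))
}
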