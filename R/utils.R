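#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

row_norms <- function(x) sqrt(rowSums(x * x))

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < .Machine$double.eps * 100) {
    stop("cannot normalize a (near-)zero vector", call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

as_point_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop(what, " must be a 3-vector or an n x 3 matrix",
                              call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Nearest neighbours between two 3D point sets
#'
#' Brute-force nearest-neighbour search, evaluated in blocks so that the
#' cross-distance matrix never exceeds a modest memory footprint.
#'
#' @param query n x 3 matrix of query points.
#' @param ref m x 3 matrix of reference points.
#' @param k number of neighbours to return.
#' @return list with `index` (n x k) and `dist` (n x k, Euclidean).
#' @keywords internal
nn_points <- function(query, ref, k = 1L) {
  query <- as_point_matrix(query, "query")
  ref <- as_point_matrix(ref, "ref")
  n <- nrow(query); m <- nrow(ref)
  k <- min(as.integer(k), m)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  ref_sq <- rowSums(ref * ref)
  block <- max(1L, as.integer(4e6 / m))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    q <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(q * q), ref_sq, "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    if (k == 1L) {
      j <- max.col(-d2, ties.method = "first")
      idx[rows, 1L] <- j
      dst[rows, 1L] <- sqrt(d2[cbind(seq_along(j), j)])
    } else {
      for (ii in seq_along(rows)) {
        ord <- order(d2[ii, ])[seq_len(k)]
        idx[rows[ii], ] <- ord
        dst[rows[ii], ] <- sqrt(d2[ii, ord])
      }
    }
  }
  list(index = idx, dist = dst)
}

#' Least-squares rigid superposition of paired point sets
#'
#' Closed-form Procrustes (Kabsch) solution for the rotation and translation
#' mapping `moving` onto `target` without scaling. Reflections are excluded,
#' so the returned rotation has determinant +1.
#'
#' @param moving,target n x 3 matrices of paired points (n >= 3 for a unique
#'   rotation; collinear configurations fall back to translation only with a
#'   warning).
#' @return list with `rotation` (3 x 3), `translation` (length 3), and
#'   `rmsd` after superposition. Apply as `p %*% t(rotation) + translation`.
#' @export
kabsch <- function(moving, target) {
  P <- as_point_matrix(moving, "moving")
  Q <- as_point_matrix(target, "target")
  if (nrow(P) != nrow(Q)) stop("point sets must be paired", call. = FALSE)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2L, pc); Qc <- sweep(Q, 2L, qc)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  # guard against degenerate (rank-deficient) configurations
  if (sv$d[2L] <= max(sv$d[1L], 1) * 1e-12) {
    warning("degenerate (collinear) landmark configuration; translation-only alignment")
    R <- diag(3)
  } else {
    d <- sign(det(tcrossprod(sv$v, sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  t_vec <- qc - as.vector(R %*% pc)
  fitted <- P %*% t(R) + matrix(t_vec, nrow(P), 3L, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

apply_rigid <- function(points, rotation, translation) {
  p <- as_point_matrix(points)
  p %*% t(rotation) + matrix(translation, nrow(p), 3L, byrow = TRUE)
}

#' Derive a reproducible child seed from a base seed
#' @keywords internal
child_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
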