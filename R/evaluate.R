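#' Landmark-to-landmark (L2L) reconstruction error
#'
#' Per-landmark Euclidean distance (mm) between the bone landmarks of the
#' aligned reconstructed shape and the target landmarks — the RMSE over the
#' three coordinates of each landmark, reported per landmark as in the
#' reconstruction literature.
#'
#' @param result a [reconstruct()] result.
#' @param target the target bone landmarks used for the reconstruction
#'   (bone-level [landmark_set()] in the body-fixed frame, or a 12-vector).
#' @return named numeric vector (AA, TS, AI, AC), mm.
#' @export
l2l_error <- function(result, target) {
  if (inherits(target, "landmark_set") && target$frame != "body_fixed") {
    stop("target landmarks must be in the body-fixed frame", call. = FALSE)
  }
  xt <- matrix(flatten_landmarks(target), 4L, 3L, byrow = TRUE)
  d <- row_norms(xt - result$landmarks)
  names(d) <- c("AA", "TS", "AI", "AC")
  d
}

#' Surface-to-surface (S2S) reconstruction error
#'
#' Point-to-point RMSE (mm) over all corresponding vertices between the
#' reconstructed shape and the ground-truth shape, after rigid (no-scale)
#' correspondence-based Procrustes alignment. Per-vertex distances are
#' returned for heat-map rendering. No scaling is removed, so size errors
#' remain visible (overall size is itself a mode of the shape model).
#'
#' @param reconstructed [triangle_mesh()] or vertex matrix on the
#'   correspondence template.
#' @param ground_truth `corresponded_shape`, [triangle_mesh()] or vertex
#'   matrix with the same vertex count.
#' @param align if `FALSE`, skip the Procrustes alignment (shapes already
#'   co-registered).
#' @return list with `rmse` (mm) and `per_vertex` (length-N distances, mm).
#' @export
s2s_error <- function(reconstructed, ground_truth, align = TRUE) {
  get_v <- function(x) {
    if (inherits(x, "triangle_mesh") || inherits(x, "corresponded_shape")) {
      x$vertices
    } else {
      as_point_matrix(x, "shape")
    }
  }
  A <- get_v(reconstructed)
  B <- get_v(ground_truth)
  if (nrow(A) != nrow(B)) {
    stop("vertex counts differ: shapes are not on the same template",
         call. = FALSE)
  }
  if (align) {
    k <- kabsch(A, B)
    A <- apply_rigid(A, k$rotation, k$translation)
  }
  d <- row_norms(A - B)
  list(rmse = sqrt(mean(d^2)), per_vertex = d)
}

#' Compare two error distributions with a Kruskal-Wallis test
#'
#' Two-group Kruskal-Wallis (tie-corrected) H statistic and chi-square
#' p-value, with the accept/reject decision at the 5% significance level.
#' Used to test whether reconstructions from digitized and from predicted
#' bone landmarks yield distinguishable error distributions.
#'
#' For small samples the p-value is computed from the exact permutation
#' distribution of H (enumerating all group assignments), since the
#' chi-square approximation is inaccurate away from the tail at such sizes;
#' larger samples use the usual chi-square reference.
#'
#' @param group_a,group_b numeric vectors of errors (each of length >= 2).
#' @param alpha significance level for the reported decision.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact permutation
#'   p-value; the default enumerates exactly when at most 20000 group
#'   assignments exist.
#' @return list with `H`, `p_value`, `reject` (logical), `alpha`, `method`.
#' @export
compare_error_distributions <- function(group_a, group_b, alpha = 0.05,
                                        exact = NULL) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  x <- c(group_a, group_b)
  if (max(x) - min(x) < .Machine$double.eps * max(abs(x), 1)) {
    return(list(H = 0, p_value = 1, reject = FALSE, alpha = alpha,
                method = "degenerate"))
  }
  n1 <- length(group_a)
  n <- length(x)
  n_comb <- choose(n, n1)
  exact <- exact %||% (n_comb <= 20000)
  kt <- stats::kruskal.test(list(group_a, group_b))
  H <- unname(kt$statistic)
  if (exact) {
    # two-group H is monotone in (R1 - E[R1])^2 and the tie correction is
    # permutation-invariant, so enumerate rank sums of group A
    r <- rank(x)
    mu <- n1 * (n + 1) / 2
    obs <- abs(sum(r[seq_len(n1)]) - mu)
    combos <- utils::combn(n, n1)
    r1 <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(r1 - mu) >= obs - 1e-9)
    method <- "exact permutation"
  } else {
    p <- unname(kt$p.value)
    method <- "chi-square approximation"
  }
  list(H = H, p_value = p, reject = p < alpha, alpha = alpha,
       method = method)
}

#' Per-scenario evaluation report
#'
#' Convenience bundle of the reconstruction quality metrics for one shape:
#' per-landmark L2L, S2S RMSE and the per-vertex distance field.
#'
#' @param result a [reconstruct()] result.
#' @param target target bone landmarks (as in [l2l_error()]).
#' @param ground_truth corresponded ground-truth shape (as in
#'   [s2s_error()]).
#' @param scenario `"digitized"` or `"predicted"`.
#' @param split `"train"` or `"test"`.
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(result, target, ground_truth,
                              scenario = c("digitized", "predicted"),
                              split = c("train", "test")) {
  scenario <- match.arg(scenario)
  split <- match.arg(split)
  l2l <- l2l_error(result, target)
  s2s <- s2s_error(result$mesh, ground_truth)
  structure(list(l2l = l2l, s2s = s2s$rmse, per_vertex = s2s$per_vertex,
                 scenario = scenario, split = split),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s landmarks, %s split)\n",
              x$scenario, x$split))
  cat("  L2L (mm):", paste(names(x$l2l), round(x$l2l, 2), sep = "=",
                           collapse = " "), "\n")
  cat(sprintf("  S2S RMSE: %.3f mm (per-vertex max %.2f)\n",
              x$s2s, max(x$per_vertex)))
  invisible(x)
}
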