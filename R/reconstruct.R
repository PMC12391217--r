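flatten_landmarks <- function(x) {
  if (inherits(x, "landmark_set")) x <- x$points
  if (is.null(dim(x)) && length(x) == 12L) return(as.numeric(x))
  as.vector(t(as_point_matrix(x, "landmarks")))
}

#' Define a landmark-fitting reconstruction problem
#'
#' Bundles the shape model, the number of modes, the target bone-landmark
#' coordinates and the optimizer configuration for [reconstruct()].
#'
#' @param model a [build_ssm()] result carrying `landmark_indices`.
#' @param x_target target bone landmarks: a bone-level [landmark_set()] or a
#'   12-vector (order AA, TS, AI, AC by x, y, z; mm).
#' @param M number of modes optimized (default 5; using few, well-populated
#'   modes trades a little generality for speed and robustness).
#' @param kappa_bound box bound on each mode weight in SD units (default 3).
#' @param penalty_weight multiplier on the exponential weight penalty
#'   (default 1, the plain form; exposed for sensitivity studies).
#' @param alignment `"procrustes_landmarks"` (closed-form paired alignment;
#'   the four landmarks are labeled so no correspondence search is needed)
#'   or `"icp_landmarks"` (nearest-point re-pairing, provided for
#'   comparison).
#' @param population,generations genetic-algorithm size settings.
#' @return an object of class `reconstruction_problem`.
#' @export
reconstruction_problem <- function(model, x_target, M = 5L, kappa_bound = 3,
                                   penalty_weight = 1,
                                   alignment = c("procrustes_landmarks",
                                                 "icp_landmarks"),
                                   population = 50L, generations = 100L) {
  alignment <- match.arg(alignment)
  if (is.null(model$landmark_indices)) {
    stop("model carries no landmark vertex indices", call. = FALSE)
  }
  K <- length(model$mode_sd)
  if (M > K) stop("M = ", M, " exceeds the model rank K = ", K,
                  call. = FALSE)
  xt <- flatten_landmarks(x_target)
  if (length(xt) != 12L || !all(is.finite(xt))) {
    stop("x_target must be 12 finite coordinates", call. = FALSE)
  }
  if (!is.finite(kappa_bound) || kappa_bound <= 0) {
    stop("kappa_bound must be finite and positive", call. = FALSE)
  }
  idx <- model$landmark_indices[c("AA", "TS", "AI", "AC")]
  rows <- as.vector(t(outer(3L * (idx - 1L), 1:3, "+")))
  structure(list(model = model, M = as.integer(M), x_target = xt,
                 kappa_bound = kappa_bound, penalty_weight = penalty_weight,
                 alignment = alignment,
                 population = as.integer(population),
                 generations = as.integer(generations),
                 mean_L = model$mean_shape[rows],
                 modes_L = model$modes[rows, seq_len(M), drop = FALSE] *
                   matrix(model$mode_sd[seq_len(M)], 12L, M, byrow = TRUE)),
            class = "reconstruction_problem")
}

#' Bone landmarks of a synthesized shape
#'
#' Coordinates of the four landmark-index vertices of
#' `synthesize(model, kappa)`, flattened in the fixed AA, TS, AI, AC order.
#' Linear in `kappa`.
#'
#' @param model a [build_ssm()] result with `landmark_indices`.
#' @param kappa mode weights in SD units.
#' @return numeric 12-vector (mm).
#' @export
model_landmarks <- function(model, kappa) {
  if (is.null(model$landmark_indices)) {
    stop("model carries no landmark vertex indices", call. = FALSE)
  }
  idx <- model$landmark_indices[c("AA", "TS", "AI", "AC")]
  v <- synthesize(model, kappa)
  v <- if (inherits(v, "triangle_mesh")) v$vertices else v
  as.vector(t(v[idx, , drop = FALSE]))
}

#' Exponential penalty on mode weights
#'
#' `sum_m (exp(kappa_m^2) - 1)`: zero at the mean shape and sharply
#' increasing for weights beyond ~2 SD, encoding that large mode weights are
#' improbable under the (standard normal) population distribution of
#' weights.
#'
#' @param kappa numeric vector of mode weights (SD units).
#' @return non-negative scalar.
#' @export
penalty <- function(kappa) {
  if (!all(is.finite(kappa))) stop("kappa must be finite", call. = FALSE)
  k2 <- kappa^2
  if (any(k2 > 676)) {
    warning("clamping penalty for |kappa| > 26 to avoid overflow")
    k2 <- pmin(k2, 676)
  }
  sum(exp(k2) - 1)
}

align_landmarks_to_target <- function(xk, target, alignment) {
  P <- matrix(xk, 4L, 3L, byrow = TRUE)
  Q <- matrix(target, 4L, 3L, byrow = TRUE)
  k <- kabsch(P, Q)
  if (alignment == "icp_landmarks") {
    # nearest-point re-pairing; with 4 labeled landmarks this converges to
    # the labeled pairing immediately unless landmarks nearly coincide
    for (it in 1:5) {
      cur <- apply_rigid(P, k$rotation, k$translation)
      j <- nn_points(cur, Q, k = 1L)$index[, 1L]
      if (all(j == seq_len(4L))) break
      k <- kabsch(P, Q[j, , drop = FALSE])
    }
  }
  k
}

#' Reconstruction objective
#'
#' Rigidly aligns the model landmarks `x(kappa)` to the target (paired
#' Procrustes without scaling), then returns the squared landmark misfit
#' plus the exponential weight penalty:
#' `f(kappa) = ||x_target - aligned x(kappa)||^2 + sum(exp(kappa^2) - 1)`.
#'
#' @param problem a [reconstruction_problem()].
#' @param kappa length-M weight vector.
#' @param parts if `TRUE`, return a list with `objective`, `data_term`,
#'   `penalty_term` and the alignment transform.
#' @return scalar objective value (or list when `parts = TRUE`).
#' @export
objective <- function(problem, kappa, parts = FALSE) {
  if (length(kappa) != problem$M) {
    stop("kappa must have length M = ", problem$M, call. = FALSE)
  }
  xk <- problem$mean_L + as.vector(problem$modes_L %*% kappa)
  k <- align_landmarks_to_target(xk, problem$x_target, problem$alignment)
  aligned <- apply_rigid(matrix(xk, 4L, 3L, byrow = TRUE),
                         k$rotation, k$translation)
  data_term <- sum((matrix(problem$x_target, 4L, 3L, byrow = TRUE) -
                      aligned)^2)
  pen <- problem$penalty_weight * penalty(kappa)
  if (!parts) return(data_term + pen)
  list(objective = data_term + pen, data_term = data_term,
       penalty_term = pen, rotation = k$rotation,
       translation = k$translation, aligned_landmarks = aligned)
}

# Seeded real-coded genetic algorithm (tournament selection, uniform
# crossover, Gaussian mutation, elitism). Minimizes fn over a box.
ga_minimize <- function(fn, lower, upper, population = 50L,
                        generations = 100L, mutation_prob = 0.2,
                        mutation_sd = NULL, crossover_prob = 0.9,
                        elite = 2L) {
  d <- length(lower)
  mutation_sd <- mutation_sd %||% (0.1 * (upper - lower))
  pop <- matrix(stats::runif(population * d, rep(lower, each = population),
                             rep(upper, each = population)),
                population, d)
  fit <- apply(pop, 1L, fn)
  best_trace <- numeric(generations)
  for (g in seq_len(generations)) {
    ord <- order(fit)
    new_pop <- pop[ord[seq_len(elite)], , drop = FALSE]
    while (nrow(new_pop) < population) {
      pick <- function() {
        cand <- sample.int(population, 3L)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- if (stats::runif(1) < crossover_prob) {
        mask <- stats::runif(d) < 0.5
        ifelse(mask, p1, p2)
      } else {
        p1
      }
      mut <- stats::runif(d) < mutation_prob
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mutation_sd[mut])
      new_pop <- rbind(new_pop, pmin(pmax(child, lower), upper))
    }
    pop <- new_pop
    fit <- apply(pop, 1L, fn)
    best_trace[g] <- min(fit)
  }
  i <- which.min(fit)
  list(par = pop[i, ], value = fit[i], trace = best_trace)
}

#' Reconstruct a scapula shape from target bone landmarks
#'
#' Minimizes the penalized landmark misfit [objective()] over the first M
#' mode weights: a seeded genetic algorithm explores the `+/- kappa_bound`
#' box globally, and the best individual is refined by bounded quasi-Newton
#' local optimization (`optim` method `"L-BFGS-B"`, numerical gradient) so
#' the returned solution is at least a local minimum; a second refinement
#' started from the mean shape guards against a poor GA draw. The refined
#' value never exceeds the GA value.
#'
#' @param problem a [reconstruction_problem()].
#' @param seed RNG seed; identical seeds give bit-identical results.
#' @return object of class `scapula_reconstruction`: `kappa_opt`,
#'   `objective_value`, `data_term`, `penalty_term`, `mesh` (full synthesized
#'   surface rigidly aligned to the target), `rotation`/`translation`,
#'   `residuals` (per-landmark distances, mm), `ga_value`, `converged`.
#' @export
reconstruct <- function(problem, seed = 1L) {
  stopifnot(inherits(problem, "reconstruction_problem"))
  set.seed(seed)
  f1 <- objective(problem, numeric(problem$M))  # surfaces any alignment warning once
  fn <- function(k) suppressWarnings(objective(problem, k))
  lower <- rep(-problem$kappa_bound, problem$M)
  upper <- rep(problem$kappa_bound, problem$M)
  ga <- ga_minimize(fn, lower, upper, population = problem$population,
                    generations = problem$generations)
  refine <- function(start) {
    tryCatch(
      stats::optim(start, fn, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 200L, factr = 1e4)),
      error = function(e) list(par = start, value = fn(start),
                               convergence = 1L))
  }
  cand <- list(refine(ga$par), refine(rep(0, problem$M)),
               list(par = ga$par, value = ga$value, convergence = 0L))
  vals <- vapply(cand, function(cc) cc$value, 0)
  best <- cand[[which.min(vals)]]
  parts <- suppressWarnings(objective(problem, best$par, parts = TRUE))
  mesh <- synthesize(problem$model, best$par)
  verts <- if (inherits(mesh, "triangle_mesh")) mesh$vertices else mesh
  verts <- apply_rigid(verts, parts$rotation, parts$translation)
  out_mesh <- if (!is.null(problem$model$faces)) {
    triangle_mesh(verts, problem$model$faces, check = FALSE)
  } else {
    verts
  }
  res <- row_norms(matrix(problem$x_target, 4L, 3L, byrow = TRUE) -
                     parts$aligned_landmarks)
  names(res) <- c("AA", "TS", "AI", "AC")
  structure(list(kappa_opt = unname(best$par),
                 landmarks = parts$aligned_landmarks,
                 objective_value = parts$objective,
                 data_term = parts$data_term,
                 penalty_term = parts$penalty_term,
                 mesh = out_mesh,
                 rotation = parts$rotation,
                 translation = parts$translation,
                 residuals = res,
                 ga_value = ga$value,
                 mean_value = f1,
                 converged = !is.null(best$convergence) &&
                   best$convergence == 0L,
                 M = problem$M, seed = seed),
            class = "scapula_reconstruction")
}

#' @export
print.scapula_reconstruction <- function(x, ...) {
  cat(sprintf("scapula_reconstruction: M = %d, f = %.4g (data %.4g + penalty %.4g)\n",
              x$M, x$objective_value, x$data_term, x$penalty_term))
  cat("  kappa*:", paste(round(x$kappa_opt, 3), collapse = ", "), "\n")
  cat("  landmark residuals (mm):",
      paste(names(x$residuals), round(x$residuals, 3), sep = "=",
            collapse = " "), "\n")
  if (!x$converged) cat("  note: local refinement did not report convergence\n")
  invisible(x)
}

#' @export
plot.scapula_reconstruction <- function(x, ...) {
  graphics::barplot(x$residuals, ylab = "landmark residual (mm)",
                    main = "Reconstruction landmark misfit", ...)
  invisible(x)
}
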