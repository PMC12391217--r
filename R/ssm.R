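shape_to_vec <- function(vertices) as.vector(t(vertices))

vec_to_shape <- function(x) matrix(x, ncol = 3L, byrow = TRUE)

cohort_matrix <- function(cohort) {
  vs <- lapply(cohort, function(s) {
    if (is.list(s) && !is.null(s$vertices)) {
      s$vertices
    } else {
      as_point_matrix(s, "shape")
    }
  })
  counts <- vapply(vs, nrow, 0L)
  if (length(unique(counts)) != 1L) {
    stop("all corresponded shapes must have the same vertex count",
         call. = FALSE)
  }
  do.call(rbind, lapply(vs, function(v) shape_to_vec(v)))
}

#' Build a PCA statistical shape model
#'
#' Fits the statistical shape model: the mean of the corresponded shape
#' vectors plus the principal directions and standard deviations of their
#' covariance, obtained from the singular value decomposition of the centered
#' data matrix. Shapes enter as corresponded and rigidly aligned; no scale
#' normalization is applied, so overall size remains a mode of variation
#' (empirically the first).
#'
#' @param cohort list of [nonrigid_correspond()] results (or plain vertex
#'   matrices with equal vertex counts), rigidly aligned to the template.
#' @param faces template topology (f x 3); taken from the first
#'   `corresponded_shape` if omitted.
#' @param landmark_indices named integer vector (AA, TS, AI, AC) of template
#'   vertex indices, as from [landmark_vertex_indices()].
#' @param tol relative singular-value threshold below which modes are
#'   treated as numerically null.
#' @return object of class `scapula_ssm`: `mean_shape` (3N vector, mm),
#'   `modes` (3N x K orthonormal columns), `mode_sd` (K, mm),
#'   `landmark_indices`, `n_training`, `faces`, `training` (n x 3N matrix of
#'   the training shape vectors, kept for the specificity metric).
#' @export
build_ssm <- function(cohort, faces = NULL, landmark_indices = NULL,
                      tol = 1e-10) {
  if (length(cohort) < 3L) {
    stop("need at least 3 corresponded shapes", call. = FALSE)
  }
  X <- cohort_matrix(cohort)
  if (is.null(faces)) {
    first <- cohort[[1L]]
    if (!is.null(first$faces)) faces <- first$faces
  }
  n <- nrow(X)
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2L, mean_shape)
  sv <- svd(Xc, nu = 0, nv = min(n - 1L, ncol(Xc)))
  sd_all <- sv$d[seq_len(ncol(sv$v))] / sqrt(n - 1)
  keep <- sd_all > tol * max(sd_all, .Machine$double.eps)
  K <- sum(keep)
  if (K == 0L) {
    warning("all training shapes are identical: model has zero modes")
  }
  ids <- vapply(cohort, function(s) s$source_id %||% s$id %||% NA_character_,
                "")
  structure(list(mean_shape = mean_shape,
                 modes = sv$v[, keep, drop = FALSE],
                 mode_sd = sd_all[keep],
                 landmark_indices = landmark_indices,
                 n_training = n,
                 faces = faces,
                 training = X,
                 training_ids = ids),
            class = "scapula_ssm")
}

#' @export
print.scapula_ssm <- function(x, ...) {
  cat(sprintf("scapula_ssm: %d training shapes, %d vertices, %d modes\n",
              x$n_training, length(x$mean_shape) / 3L, length(x$mode_sd)))
  if (length(x$mode_sd)) {
    cv <- compactness(x)
    m95 <- which(cv >= 0.95)[1L]
    cat(sprintf("  mode SD (mm): %s%s\n",
                paste(round(utils::head(x$mode_sd, 5L), 2), collapse = ", "),
                if (length(x$mode_sd) > 5L) ", ..." else ""))
    cat(sprintf("  95%% of variance in %d mode(s)\n", m95))
  }
  if (!is.null(x$landmark_indices)) {
    cat("  landmark vertices:",
        paste(names(x$landmark_indices), x$landmark_indices, sep = "=",
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.scapula_ssm <- function(object, ...) {
  cv <- compactness(object)
  out <- data.frame(mode = seq_along(object$mode_sd),
                    sd_mm = object$mode_sd,
                    var_fraction = object$mode_sd^2 / sum(object$mode_sd^2),
                    cum_var_fraction = cv)
  class(out) <- c("summary.scapula_ssm", "data.frame")
  out
}

#' @export
plot.scapula_ssm <- function(x, ...) {
  cv <- compactness(x)
  graphics::plot(seq_along(cv), cv, type = "b", pch = 19,
                 xlab = "number of modes",
                 ylab = "cumulative variance fraction",
                 main = "Shape model compactness", ylim = c(0, 1), ...)
  graphics::abline(h = 0.95, lty = 2, col = "grey40")
  invisible(x)
}

#' Synthesize a shape from mode weights
#'
#' Returns `mean + sum_m kappa_m * sd_m * mode_m`, i.e. weights are in
#' standard-deviation units so that plausible anatomy corresponds to
#' `kappa ~ N(0, I)`.
#'
#' @param model a [build_ssm()] result.
#' @param kappa numeric vector of M mode weights (SD units), M <= K.
#' @return a [triangle_mesh()] (or bare vertex matrix if the model carries no
#'   topology).
#' @export
synthesize <- function(model, kappa) {
  K <- length(model$mode_sd)
  M <- length(kappa)
  if (M > K) stop("requested ", M, " modes but the model has ", K,
                  call. = FALSE)
  x <- model$mean_shape
  if (M > 0L) {
    x <- x + as.vector(model$modes[, seq_len(M), drop = FALSE] %*%
                         (kappa * model$mode_sd[seq_len(M)]))
  }
  v <- vec_to_shape(x)
  if (is.null(model$faces)) return(v)
  triangle_mesh(v, model$faces, check = FALSE)
}

#' @export
predict.scapula_ssm <- function(object, kappa = numeric(0), ...) {
  synthesize(object, kappa)
}

#' Shape model compactness
#'
#' Cumulative fraction of total shape variance captured by the first m
#' modes, for m = 1..K; a non-decreasing sequence ending at 1.
#'
#' @param model a [build_ssm()] result.
#' @return numeric vector of cumulative variance fractions.
#' @export
compactness <- function(model) {
  if (length(model$mode_sd) < 1L) stop("model has no modes", call. = FALSE)
  ev <- model$mode_sd^2
  cumsum(ev) / sum(ev)
}

#' Shape model generalization (leave-one-out reconstruction error)
#'
#' For each shape, a model is built from the remaining shapes and the
#' held-out shape projected onto its first M modes; the per-vertex
#' point-to-point RMSE is averaged over the cohort.
#'
#' @param cohort list of corresponded shapes (>= 3).
#' @param M number of modes used in the projection.
#' @return mean leave-one-out RMSE (mm).
#' @export
generalization <- function(cohort, M) {
  n <- length(cohort)
  if (n < 3L) stop("need at least 3 shapes", call. = FALSE)
  X <- cohort_matrix(cohort)
  errs <- vapply(seq_len(n), function(i) {
    mdl <- build_ssm(lapply(seq_len(n)[-i], function(j) {
      list(vertices = vec_to_shape(X[j, ]))
    }))
    if (M > length(mdl$mode_sd)) {
      stop("M exceeds the rank available in the leave-one-out model",
           call. = FALSE)
    }
    h <- X[i, ] - mdl$mean_shape
    Phi <- mdl$modes[, seq_len(M), drop = FALSE]
    recon <- mdl$mean_shape + as.vector(Phi %*% crossprod(Phi, h))
    d2 <- rowSums((vec_to_shape(recon) - vec_to_shape(X[i, ]))^2)
    sqrt(mean(d2))
  }, 0)
  mean(errs)
}

#' Shape model specificity
#'
#' Samples `kappa ~ N(0, I_M)` in SD units, synthesizes shapes, and reports
#' the mean RMSE to the nearest training shape: low values mean random model
#' samples stay close to the training population.
#'
#' @param model a [build_ssm()] result (must carry its training matrix).
#' @param n_samples number of sampled shapes.
#' @param M number of modes sampled.
#' @param seed RNG seed.
#' @return mean RMSE (mm) to the nearest training shape.
#' @export
specificity <- function(model, n_samples = 100L, M = length(model$mode_sd),
                        seed = 1L) {
  if (is.null(model$training)) {
    stop("model does not carry training shapes", call. = FALSE)
  }
  if (M > length(model$mode_sd)) {
    if (length(model$mode_sd) == 0L) return(0)
    stop("M exceeds the model rank", call. = FALSE)
  }
  set.seed(seed)
  N <- length(model$mean_shape) / 3L
  vals <- vapply(seq_len(n_samples), function(i) {
    kappa <- stats::rnorm(M)
    x <- model$mean_shape
    if (M > 0L) {
      x <- x + as.vector(model$modes[, seq_len(M), drop = FALSE] %*%
                           (kappa * model$mode_sd[seq_len(M)]))
    }
    d <- sweep(model$training, 2L, x)
    rmse <- sqrt(rowSums(d^2) / N)
    min(rmse)
  }, 0)
  mean(vals)
}
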