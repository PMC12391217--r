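PREDICTOR_NAMES <- c("AC.x", "AI.y", "AC.y", "TS.z", "AI.z", "AC.z",
                     "d.AA.TS", "d.AA.AI", "d.AA.AC",
                     "d.TS.AI", "d.TS.AC", "d.AI.AC",
                     "sex", "age", "weight", "height", "bmi")

RESPONSE_NAMES <- as.vector(t(outer(c("AA", "TS", "AI", "AC"),
                                    c("x", "y", "z"), paste, sep = ".")))

#' Assemble the 17 regression predictors for one subject
#'
#' Predictors are the six free skin-landmark coordinates in the body-fixed
#' frame (the other six are structurally zero there and carry no
#' information), the six pairwise skin-landmark distances, and the subject
#' covariates sex, age, weight, height and derived BMI.
#'
#' @param skin_body_frame skin-level [landmark_set()] in the body-fixed
#'   frame.
#' @param subject a [subject_record()].
#' @param tol tolerance on the structural zeros used to verify the landmarks
#'   really are in the body-fixed frame.
#' @return named numeric vector of length 17.
#' @export
assemble_predictors <- function(skin_body_frame, subject, tol = 1e-6) {
  if (!inherits(skin_body_frame, "landmark_set") ||
      skin_body_frame$frame != "body_fixed" ||
      skin_body_frame$level != "skin") {
    stop("expected skin landmarks in the body-fixed frame", call. = FALSE)
  }
  p <- skin_body_frame$points
  zero <- structural_zero_coords()
  zv <- p[cbind(zero$landmark, zero$axis)]
  scale_ref <- max(abs(p), 1)
  if (max(abs(zv)) > tol * scale_ref) {
    stop("landmarks violate the body-fixed-frame zero pattern; ",
         "transform with to_body_frame() first", call. = FALSE)
  }
  d <- as.matrix(stats::dist(p))
  out <- c(p["AC", "x"], p["AI", "y"], p["AC", "y"],
           p["TS", "z"], p["AI", "z"], p["AC", "z"],
           d["AA", "TS"], d["AA", "AI"], d["AA", "AC"],
           d["TS", "AI"], d["TS", "AC"], d["AI", "AC"],
           subject$sex, subject$age, subject$weight, subject$height,
           subject$bmi)
  stats::setNames(out, PREDICTOR_NAMES)
}

#' Mean absolute error
#' @param y_true,y_pred numeric vectors of equal positive length.
#' @return mean of absolute residuals (mm for landmark coordinates).
#' @export
mae <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be non-empty and of equal length",
         call. = FALSE)
  }
  mean(abs(y_true - y_pred))
}

#' Fold evaluation score for model selection
#'
#' Combines the average of the training and testing MAEs with a penalty on
#' their absolute difference, discouraging both under- and over-fitting:
#' `s = ((mae_train + mae_test)/2 + |mae_train - mae_test|) / 2`.
#'
#' @param mae_train,mae_test non-negative mean absolute errors (mm).
#' @return the score `s` (mm), `>= max(mae_train, mae_test)/2`.
#' @export
selection_score <- function(mae_train, mae_test) {
  if (any(c(mae_train, mae_test) < 0)) {
    stop("MAEs must be non-negative", call. = FALSE)
  }
  0.5 * ((mae_train + mae_test) / 2 + abs(mae_train - mae_test))
}

rss_of <- function(X, y) {
  if (ncol(X) == 0L) return(sum((y - mean(y))^2))
  fit <- stats::lm.fit(cbind(1, X), y)
  if (any(is.na(fit$coefficients))) return(NA_real_)
  sum(fit$residuals^2)
}

#' Stepwise regression with F-test entry and removal
#'
#' Classic add-then-prune stepwise selection: at each step the out-of-model
#' predictor with the smallest partial-F p-value is added if below
#' `p_enter`; after every addition, in-model predictors whose partial-F
#' p-value exceeds `p_remove` are pruned (worst first); the loop stops when
#' neither action applies. Partial F statistics come from nested residual
#' sums of squares (equal to the squared t statistic for a single
#' predictor). Predictors are used unscaled.
#'
#' @param X n x p numeric predictor matrix with column names.
#' @param y response vector (one bone-landmark coordinate, mm).
#' @param p_enter entry threshold on the partial-F p-value.
#' @param p_remove removal threshold (must be >= p_enter to avoid cycling).
#' @return object of class `stepwise_fit`: `intercept`, `coefficients`
#'   (named, selected predictors only), `r2`, `r2_adj`, `selected`,
#'   `removal_p` (final partial-F p-values of the selected predictors),
#'   `n`.
#' @export
stepwise_fit <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(y) != n) stop("X and y sizes disagree", call. = FALSE)
  if (p_remove < p_enter) {
    stop("p_remove must be >= p_enter", call. = FALSE)
  }
  const <- apply(X, 2L, function(col) max(col) - min(col) < 1e-12)
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (n < 5L) stop("too few observations for stepwise selection",
                   call. = FALSE)
  tss <- sum((y - mean(y))^2)
  sel <- character(0)
  repeat {
    changed <- FALSE
    # forward step
    rss_cur <- rss_of(X[, sel, drop = FALSE], y)
    candidates <- setdiff(colnames(X), sel)
    if (length(candidates) && rss_cur > 1e-12 * max(tss, 1) &&
        n - length(sel) - 2L >= 1L) {
      pvals <- vapply(candidates, function(j) {
        rss_new <- rss_of(X[, c(sel, j), drop = FALSE], y)
        if (is.na(rss_new)) return(NA_real_)
        df2 <- n - length(sel) - 2L
        f <- (rss_cur - rss_new) / (rss_new / df2)
        if (!is.finite(f)) return(0)
        stats::pf(f, 1L, df2, lower.tail = FALSE)
      }, 0)
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) && min(pvals) < p_enter) {
        sel <- c(sel, names(pvals)[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward steps
    repeat {
      if (length(sel) == 0L) break
      rss_full <- rss_of(X[, sel, drop = FALSE], y)
      df2 <- n - length(sel) - 1L
      pr <- vapply(sel, function(j) {
        rss_red <- rss_of(X[, setdiff(sel, j), drop = FALSE], y)
        f <- (rss_red - rss_full) / (rss_full / df2)
        if (!is.finite(f)) return(0)
        stats::pf(f, 1L, df2, lower.tail = FALSE)
      }, 0)
      if (max(pr) > p_remove) {
        sel <- setdiff(sel, names(pr)[which.max(pr)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, sel, drop = FALSE]), y)
  rss <- sum(fit$residuals^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  p_sel <- length(sel)
  r2_adj <- if (n - p_sel - 1L > 0L) {
    1 - (1 - r2) * (n - 1L) / (n - p_sel - 1L)
  } else {
    r2
  }
  removal_p <- if (p_sel > 0L) {
    df2 <- n - p_sel - 1L
    vapply(sel, function(j) {
      rss_red <- rss_of(X[, setdiff(sel, j), drop = FALSE], y)
      f <- (rss_red - rss) / (rss / df2)
      if (!is.finite(f)) return(0)
      stats::pf(f, 1L, df2, lower.tail = FALSE)
    }, 0)
  } else {
    numeric(0)
  }
  structure(list(intercept = unname(fit$coefficients[1L]),
                 coefficients = fit$coefficients[-1L],
                 selected = sel, r2 = r2, r2_adj = r2_adj,
                 removal_p = removal_p, n = n),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("stepwise_fit: %d predictor(s), R2 %.3f (adj %.3f)\n",
              length(x$selected), x$r2, x$r2_adj))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

predict_stepwise <- function(fit, x) {
  xx <- x[names(fit$coefficients)]
  fit$intercept + sum(fit$coefficients * xx)
}

#' Fit the 12 skin-to-bone regression models with fold-scored selection
#'
#' For each of the 12 bone-landmark coordinates (4 landmarks x 3 axes, in the
#' body-fixed frame), the model is fit independently on each of `n_folds`
#' shuffle-split train/test partitions of the cohort via [stepwise_fit()];
#' training and testing MAEs give a fold score via [selection_score()], and
#' the fold with the lowest score supplies the selected model for that
#' response (ties broken by lower test MAE, then lower fold id).
#'
#' @param X n x 17 predictor matrix (rows = subjects, columns as
#'   [assemble_predictors()]).
#' @param Y n x 12 response matrix, columns `AA.x ... AC.z` (bone-landmark
#'   coordinates in the body-fixed frame, mm).
#' @param n_folds number of shuffle-split folds.
#' @param train_frac fraction of subjects in each fold's training part
#'   (`floor(n * train_frac)` rows; the remainder tests).
#' @param seed RNG seed controlling the shuffle splits (the fit is
#'   reproducible bit-for-bit given the seed).
#' @param p_enter,p_remove stepwise F-test thresholds.
#' @return object of class `skin_to_bone_fit`: a list of 12 selected models
#'   (each a `stepwise_fit` augmented with `response`, `fold_id`,
#'   `mae_train`, `mae_test`, `score_s`), plus `folds` (the per-fold
#'   bookkeeping) and the call parameters.
#' @export
fit_skin_to_bone <- function(X, Y, n_folds = 10L, train_frac = 0.7,
                             seed = 1L, p_enter = 0.05, p_remove = 0.10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y row counts disagree", call. = FALSE)
  if (is.null(colnames(Y))) colnames(Y) <- RESPONSE_NAMES
  n_train <- floor(n * train_frac)
  if (n_train < 5L || n - n_train < 1L) {
    stop("cohort too small for a ", train_frac, " shuffle split",
         call. = FALSE)
  }
  set.seed(seed)
  splits <- lapply(seq_len(n_folds), function(f) {
    tr <- sort(sample.int(n, n_train))
    list(fold_id = f, train = tr, test = setdiff(seq_len(n), tr))
  })
  models <- vector("list", ncol(Y))
  names(models) <- colnames(Y)
  fold_log <- list()
  for (resp in colnames(Y)) {
    y <- Y[, resp]
    best <- NULL
    for (sp in splits) {
      ytr <- y[sp$train]
      if (max(ytr) - min(ytr) < 1e-12) {
        # constant response: the regression degenerates to its intercept
        fit <- structure(list(intercept = mean(ytr),
                              coefficients = stats::setNames(numeric(0),
                                                             character(0)),
                              selected = character(0), r2 = 1, r2_adj = 1,
                              removal_p = numeric(0), n = length(ytr)),
                         class = "stepwise_fit")
      } else fit <- withCallingHandlers(
        stepwise_fit(X[sp$train, , drop = FALSE], ytr,
                     p_enter = p_enter, p_remove = p_remove),
        warning = function(w) {
          if (grepl("constant predictor", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      pred_tr <- apply(X[sp$train, , drop = FALSE], 1L, predict_stepwise,
                       fit = fit)
      pred_te <- apply(X[sp$test, , drop = FALSE], 1L, predict_stepwise,
                       fit = fit)
      m_tr <- mae(ytr, pred_tr)
      m_te <- mae(y[sp$test], pred_te)
      s <- selection_score(m_tr, m_te)
      fold_log[[length(fold_log) + 1L]] <- data.frame(
        response = resp, fold_id = sp$fold_id, n_train = length(sp$train),
        n_test = length(sp$test), n_predictors = length(fit$selected),
        mae_train = m_tr, mae_test = m_te, score_s = s, r2 = fit$r2)
      cand <- list(fit = fit, fold_id = sp$fold_id, mae_train = m_tr,
                   mae_test = m_te, score_s = s)
      if (is.null(best) ||
          s < best$score_s ||
          (s == best$score_s && m_te < best$mae_test) ||
          (s == best$score_s && m_te == best$mae_test &&
             sp$fold_id < best$fold_id)) {
        best <- cand
      }
    }
    if (is.null(best)) {
      stop("all folds degenerate for response ", resp, call. = FALSE)
    }
    m <- best$fit
    m$response <- resp
    m$fold_id <- best$fold_id
    m$mae_train <- best$mae_train
    m$mae_test <- best$mae_test
    m$score_s <- best$score_s
    models[[resp]] <- m
  }
  structure(list(models = models,
                 folds = do.call(rbind, fold_log),
                 n_folds = n_folds, train_frac = train_frac, seed = seed,
                 p_enter = p_enter, p_remove = p_remove,
                 predictor_names = colnames(X)),
            class = "skin_to_bone_fit")
}

#' @rdname fit_skin_to_bone
#' @export
select_best_models <- fit_skin_to_bone

#' @export
print.skin_to_bone_fit <- function(x, ...) {
  cat(sprintf("skin_to_bone_fit: %d response models, %d folds (seed %d)\n",
              length(x$models), x$n_folds, x$seed))
  tab <- do.call(rbind, lapply(x$models, function(m) {
    data.frame(response = m$response, fold = m$fold_id,
               predictors = length(m$selected), r2 = round(m$r2, 3),
               mae_train = round(m$mae_train, 3),
               mae_test = round(m$mae_test, 3),
               s = round(m$score_s, 3))
  }))
  rownames(tab) <- NULL
  print(tab)
  invisible(x)
}

#' @export
coef.skin_to_bone_fit <- function(object, ...) {
  preds <- object$predictor_names
  out <- matrix(0, length(object$models), length(preds) + 1L,
                dimnames = list(names(object$models),
                                c("(Intercept)", preds)))
  for (r in names(object$models)) {
    m <- object$models[[r]]
    out[r, "(Intercept)"] <- m$intercept
    out[r, names(m$coefficients)] <- m$coefficients
  }
  out
}

#' @export
summary.skin_to_bone_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$models, function(m) {
    data.frame(response = m$response, fold_id = m$fold_id,
               n_predictors = length(m$selected),
               predictors = paste(m$selected, collapse = "+"),
               r2 = m$r2, r2_adj = m$r2_adj, mae_train = m$mae_train,
               mae_test = m$mae_test, score_s = m$score_s)
  }))
  rownames(tab) <- NULL
  tab
}

#' Predict bone landmarks from a predictor vector
#'
#' Evaluates the 12 selected regressions and assembles the result as a
#' bone-level landmark set in the body-fixed frame.
#'
#' @param object a [fit_skin_to_bone()] result.
#' @param predictors either a named length-17 vector from
#'   [assemble_predictors()], or a list with `skin` (body-frame skin
#'   [landmark_set()]) and `subject` (a [subject_record()]).
#' @return a bone-level [landmark_set()] in the body-fixed frame.
#' @export
predict.skin_to_bone_fit <- function(object, predictors, ...) {
  if (is.list(predictors) && !is.null(predictors$skin)) {
    predictors <- assemble_predictors(predictors$skin, predictors$subject)
  }
  vals <- vapply(names(object$models), function(r) {
    predict_stepwise(object$models[[r]], predictors)
  }, 0)
  pts <- matrix(vals, 4L, 3L, byrow = TRUE,
                dimnames = list(c("AA", "TS", "AI", "AC"),
                                c("x", "y", "z")))
  landmark_set(pts, level = "bone", frame = "body_fixed")
}

#' @rdname predict.skin_to_bone_fit
#' @param models a [fit_skin_to_bone()] result.
#' @export
predict_bone_landmarks <- function(models, predictors) {
  if (length(models$models) != 12L) {
    stop("expected 12 response models", call. = FALSE)
  }
  predict(models, predictors)
}

#' Export the selected regression models as a coefficient table
#'
#' One row per response with the intercept, one column per predictor
#' (zero when not selected), and the fit/selection diagnostics.
#'
#' @param fit a [fit_skin_to_bone()] result.
#' @param path output CSV path.
#' @export
write_regression_table <- function(fit, path) {
  cf <- coef(fit)
  diag_ <- summary(fit)
  df <- cbind(data.frame(response = rownames(cf)), as.data.frame(cf),
              diag_[, c("r2", "r2_adj", "mae_train", "mae_test", "score_s")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
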