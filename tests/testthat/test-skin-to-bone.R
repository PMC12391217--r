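body_frame_skin <- function() {
  co <- small_cohort()
  fr <- build_isb_scapula_frame(co$skin[[1]])
  to_body_frame(co$skin[[1]], fr)
}

test_that("the predictor vector has exactly the 17 documented entries", {
  skin_bf <- body_frame_skin()
  subj <- subject_record("x", "F", 50, 75.3, 1.71)
  p <- assemble_predictors(skin_bf, subj)
  expect_length(p, 17L)
  expect_identical(names(p), scapssm:::PREDICTOR_NAMES)
  expect_length(grep("^d\\.", names(p)), 6L)
  expect_true(all(p[grep("^d\\.", names(p))] > 0))
  expect_equal(unname(p["bmi"]), 75.3 / 1.71^2, tolerance = 1e-12)
  # TS lies on the z-axis in the body frame, so |TS.z| is the AA-TS distance
  expect_equal(unname(p["d.AA.TS"]), abs(unname(p["TS.z"])),
               tolerance = 1e-9)
  # excluded structurally-zero coordinates never appear
  expect_false(any(c("AA.x", "AA.y", "AA.z", "TS.x", "TS.y", "AI.x") %in%
                     names(p)))
  # global-frame landmarks are rejected
  expect_error(assemble_predictors(small_cohort()$skin[[1]], subj),
               "body-fixed")
})

test_that("mae and the selection score obey their closed forms", {
  expect_equal(mae(c(1, -1, 2), c(0, 0, 0)), 4 / 3)
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(7, 2), 5)
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
  expect_equal(selection_score(2, 2), 1.0)
  expect_equal(selection_score(1, 3), 2.0)
  expect_equal(selection_score(0, 0), 0.0)
  expect_error(selection_score(-1, 0), "non-negative")
  set.seed(8)
  for (i in 1:25) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5)
    expect_equal(selection_score(a, b), selection_score(b, a))
    expect_equal(selection_score(a, a), a / 2)
    expect_gte(selection_score(a, b), max(a, b) / 2 - 1e-12)
  }
})

test_that("stepwise selection recovers exact linear relations", {
  set.seed(21)
  n <- 30L
  X <- matrix(stats::rnorm(n * 17), n, 17,
              dimnames = list(NULL, scapssm:::PREDICTOR_NAMES))
  y <- 2 * X[, "TS.z"]
  fit <- stepwise_fit(X, y)
  expect_identical(fit$selected, "TS.z")
  expect_equal(unname(fit$coefficients["TS.z"]), 2, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lte(fit$r2_adj, fit$r2)
})

test_that("stepwise never keeps a predictor beyond the removal threshold", {
  set.seed(33)
  for (i in 1:10) {
    n <- 27L
    X <- matrix(stats::rnorm(n * 17), n, 17,
                dimnames = list(NULL, paste0("p", 1:17)))
    y <- stats::rnorm(n)  # independent of everything
    fit <- stepwise_fit(X, y)
    if (length(fit$selected)) {
      expect_true(all(fit$removal_p <= 0.10 + 1e-12))
    }
  }
})

test_that("stepwise agrees with exhaustive search under the same criteria", {
  set.seed(14)
  for (rep in 1:6) {
    n <- 40L
    X <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    beta <- c(1.5, -2, 0, 0, 0)
    y <- X %*% beta + stats::rnorm(n, sd = 0.5)
    fit <- stepwise_fit(X, y)
    stable <- stable_subsets(X, y)
    expect_true(any(vapply(stable, setequal, TRUE, y = fit$selected)))
    # the true support is always selected (extras may enter at these
    # thresholds by design of the F-test criteria)
    expect_true(all(c("x1", "x2") %in% fit$selected))
  }
})

test_that("fold-scored selection is exact on noise-free linear cohorts", {
  cfg <- population_config(n_subjects = 25L, template_vertices = 162L,
                           noise_sd = 0, seed = 13L)
  co <- generate_cohort(cfg)
  reg <- cohort_regression_data(co$skin, co$bone, co$subjects)
  fit <- suppressWarnings(fit_skin_to_bone(reg$X, reg$Y, seed = 2L))
  expect_length(fit$models, 12L)
  expect_identical(names(fit$models), scapssm:::RESPONSE_NAMES)
  for (m in fit$models) {
    expect_lt(m$mae_train, 1e-6)
    expect_lt(m$mae_test, 1e-6)
    expect_lt(m$score_s, 1e-6)
  }
  # a noise-free fit predicts the digitized bone landmarks exactly
  fr <- build_isb_scapula_frame(co$skin[[3]])
  skin_bf <- to_body_frame(co$skin[[3]], fr)
  bone_bf <- to_body_frame(co$bone[[3]], fr)
  pred <- predict_bone_landmarks(fit,
                                 assemble_predictors(skin_bf,
                                                     co$subjects[[3]]))
  expect_equal(pred$points, bone_bf$points, tolerance = 1e-6)
})

test_that("fold selection is reproducible and prediction is linear", {
  co <- small_cohort()
  reg <- cohort_regression_data(co$skin, co$bone, co$subjects)
  f1 <- suppressWarnings(fit_skin_to_bone(reg$X, reg$Y, seed = 4L))
  f2 <- suppressWarnings(fit_skin_to_bone(reg$X, reg$Y, seed = 4L))
  expect_identical(coef(f1), coef(f2))
  expect_identical(summary(f1), summary(f2))
  p1 <- reg$X[1, ]; p2 <- reg$X[2, ]
  al <- 0.3
  mix <- predict(f1, al * p1 + (1 - al) * p2)$points
  expect_equal(mix, al * predict(f1, p1)$points +
                 (1 - al) * predict(f1, p2)$points, tolerance = 1e-9)
  broken <- f1
  broken$models <- broken$models[1:11]
  expect_error(predict_bone_landmarks(broken, p1), "12")
})

test_that("the exported regression table mirrors the fitted models", {
  co <- small_cohort()
  reg <- cohort_regression_data(co$skin, co$bone, co$subjects)
  fit <- suppressWarnings(fit_skin_to_bone(reg$X, reg$Y, seed = 4L))
  p <- tempfile(fileext = ".csv")
  write_regression_table(fit, p)
  tab <- read.csv(p)
  expect_equal(nrow(tab), 12L)
  expect_true(all(c("response", "X.Intercept.", "r2", "score_s") %in%
                    names(tab) | c("response", "(Intercept)", "r2",
                                   "score_s") %in% names(tab)))
  expect_equal(tab$r2, unname(vapply(fit$models, function(m) m$r2, 0)))
})
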