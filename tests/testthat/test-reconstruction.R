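test_that("model landmarks are the indexed vertices and linear in kappa", {
  m <- small_ssm()
  x0 <- model_landmarks(m, numeric(0))
  idx <- m$landmark_indices[c("AA", "TS", "AI", "AC")]
  expect_equal(x0, as.vector(t(scapssm:::vec_to_shape(m$mean_shape)[idx, ])))
  k1 <- c(1, 0, -0.5, 0, 0); k2 <- c(0, 2, 0, 1, 0)
  d1 <- model_landmarks(m, k1) - x0
  d2 <- model_landmarks(m, k2) - x0
  expect_equal(model_landmarks(m, k1 + k2) - x0, d1 + d2,
               tolerance = 1e-9)
  # single-mode perturbation: direct indexing oracle
  rows <- as.vector(t(outer(3 * (idx - 1), 1:3, "+")))
  expect_equal(model_landmarks(m, c(0.7, 0, 0, 0, 0)) - x0,
               0.7 * m$mode_sd[1] * m$modes[rows, 1], tolerance = 1e-9)
})

test_that("the exponential penalty matches its analytic values", {
  expect_equal(penalty(0), 0)
  expect_equal(penalty(1), exp(1) - 1)
  expect_equal(penalty(c(1, 2)), (exp(1) - 1) + (exp(4) - 1))
  expect_error(penalty(c(NA, 1)), "finite")
  expect_warning(p <- penalty(30), "clamp")
  expect_true(is.finite(p))
})

test_that("objective vanishes at the mean for mean-shape targets and is
          invariant to rigid motion of the target", {
  m <- small_ssm()
  x0 <- model_landmarks(m, numeric(0))
  prob <- reconstruction_problem(m, x0, M = 5L)
  expect_equal(objective(prob, rep(0, 5)), 0, tolerance = 1e-12)
  set.seed(6)
  R <- random_rotation(); t_vec <- stats::rnorm(3, sd = 50)
  xt <- as.vector(t(apply_rigid(matrix(x0, 4, 3, byrow = TRUE), R, t_vec)))
  prob2 <- reconstruction_problem(m, xt, M = 5L)
  expect_lt(objective(prob2, rep(0, 5)), 1e-12)
  # additivity of the two terms
  kap <- c(0.5, -1, 0.3, 0, 1.2)
  parts <- objective(prob2, kap, parts = TRUE)
  expect_equal(parts$objective, parts$data_term + parts$penalty_term,
               tolerance = 1e-9)
  expect_equal(parts$objective - parts$data_term, penalty(kap),
               tolerance = 1e-9)
  expect_gte(parts$penalty_term, 0)
})

test_that("reconstruction of the mean-shape target returns kappa near zero", {
  m <- small_ssm()
  prob <- reconstruction_problem(m, model_landmarks(m, numeric(0)), M = 5L,
                                 population = 30L, generations = 50L)
  rec <- reconstruct(prob, seed = 3L)
  expect_true(all(abs(rec$kappa_opt) < 0.05))
  expect_lt(rec$objective_value, 1e-4)
})

test_that("the optimizer pipeline is monotone and deterministic", {
  m <- small_ssm()
  set.seed(17)
  ktrue <- pmin(pmax(stats::rnorm(5), -2), 2)
  prob <- reconstruction_problem(m, model_landmarks(m, ktrue), M = 5L,
                                 population = 30L, generations = 50L)
  r1 <- reconstruct(prob, seed = 12L)
  r2 <- reconstruct(prob, seed = 12L)
  expect_identical(r1$kappa_opt, r2$kappa_opt)
  expect_identical(r1$objective_value, r2$objective_value)
  expect_lte(r1$objective_value, r1$ga_value + 1e-12)
  # optimality relative to the generating weights (penalty shrinks kappa)
  expect_lte(r1$objective_value, objective(prob, ktrue) + 1e-6)
})

test_that("the penalty shrinks single-mode solutions toward zero", {
  m <- small_ssm()
  for (kt in c(-1.5, 0.8, 2)) {
    ktrue <- c(kt, 0, 0, 0, 0)
    prob <- reconstruction_problem(m, model_landmarks(m, ktrue), M = 5L,
                                   population = 30L, generations = 40L)
    rec <- reconstruct(prob, seed = 5L)
    expect_lte(abs(rec$kappa_opt[1]), abs(kt) + 0.05)
  }
})

test_that("rigidly moving the target leaves the optimum unchanged", {
  m <- small_ssm()
  set.seed(23)
  ktrue <- pmin(pmax(stats::rnorm(5), -2), 2)
  x0 <- model_landmarks(m, ktrue)
  prob <- reconstruction_problem(m, x0, M = 5L, population = 30L,
                                 generations = 40L)
  r0 <- reconstruct(prob, seed = 2L)
  R <- random_rotation(); t_vec <- stats::rnorm(3, sd = 100)
  xt <- as.vector(t(apply_rigid(matrix(x0, 4, 3, byrow = TRUE), R, t_vec)))
  probT <- reconstruction_problem(m, xt, M = 5L, population = 30L,
                                  generations = 40L)
  rT <- reconstruct(probT, seed = 2L)
  expect_equal(rT$objective_value, r0$objective_value, tolerance = 1e-6)
})

test_that("problem validation catches bad inputs", {
  m <- small_ssm()
  expect_error(reconstruction_problem(m, model_landmarks(m, numeric(0)),
                                      M = 50L), "exceeds")
  expect_error(reconstruction_problem(m, rep(NA_real_, 12)), "finite")
  m2 <- m; m2$landmark_indices <- NULL
  expect_error(reconstruction_problem(m2, rep(0, 12)), "landmark")
  expect_error(model_landmarks(m2, numeric(0)), "landmark")
  prob <- reconstruction_problem(m, model_landmarks(m, numeric(0)), M = 5L)
  expect_error(objective(prob, rep(0, 3)), "length")
})
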