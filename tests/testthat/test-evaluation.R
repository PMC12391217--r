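test_that("L2L errors are per-landmark distances tied to the objective", {
  pts <- rbind(AA = c(0, 0, 0), TS = c(0, 0, -100), AI = c(0, -120, -80),
               AC = c(25, 10, 5))
  fake <- list(landmarks = pts)
  target <- landmark_set(pts, level = "bone", frame = "body_fixed")
  expect_equal(unname(l2l_error(fake, target)), rep(0, 4))
  shifted <- pts; shifted["TS", ] <- shifted["TS", ] + c(3, 0, 0)
  t2 <- landmark_set(shifted, level = "bone", frame = "body_fixed")
  e <- l2l_error(fake, t2)
  expect_equal(unname(e), c(0, 3, 0, 0))
  # consistency with the objective decomposition on a real reconstruction
  m <- small_ssm()
  set.seed(31)
  ktrue <- pmin(pmax(stats::rnorm(5), -2), 2)
  xt <- model_landmarks(m, ktrue)
  prob <- reconstruction_problem(m, xt, M = 5L, population = 30L,
                                 generations = 40L)
  rec <- reconstruct(prob, seed = 7L)
  expect_equal(sum(l2l_error(rec, xt)^2), rec$data_term, tolerance = 1e-9)
})

test_that("S2S is an aligned per-vertex RMSE", {
  s <- icosphere(2, radius = 50)
  same <- s2s_error(s, s)
  expect_equal(same$rmse, 0)
  expect_equal(same$per_vertex, rep(0, nrow(s$vertices)))
  # rigid motion is absorbed by the alignment
  set.seed(12)
  R <- random_rotation(); t_vec <- stats::rnorm(3, sd = 40)
  moved <- triangle_mesh(apply_rigid(s$vertices, R, t_vec), s$faces)
  expect_lt(s2s_error(moved, s)$rmse, 1e-9)
  # a 2 mm radial displacement survives rigid alignment
  grown <- triangle_mesh(s$vertices * (52 / 50), s$faces)
  sg <- s2s_error(grown, s)
  expect_equal(sg$rmse, 2, tolerance = 1e-6)
  expect_equal(sqrt(mean(sg$per_vertex^2)), sg$rmse, tolerance = 1e-9)
  # invariance to a common rigid motion of both shapes
  m1 <- triangle_mesh(apply_rigid(grown$vertices, R, t_vec), s$faces)
  m2 <- triangle_mesh(apply_rigid(s$vertices, R, t_vec), s$faces)
  expect_equal(s2s_error(m1, m2)$rmse, sg$rmse, tolerance = 1e-9)
  expect_error(s2s_error(s, icosphere(1, 50)), "vertex counts")
})

test_that("Kruskal-Wallis comparisons behave and match the rank-sum oracle", {
  expect_error(compare_error_distributions(1, c(1, 2)), "at least 2")
  same <- compare_error_distributions(rep(2, 5), rep(2, 6))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  set.seed(19)
  a <- stats::rnorm(20)
  shift <- compare_error_distributions(a, stats::rnorm(20) + 5)
  expect_lt(shift$p_value, 0.05)
  expect_true(shift$reject)
  # exact small-sample p equals the two-sided exact rank-sum p (tie-free)
  for (i in 1:8) {
    g1 <- stats::rnorm(6); g2 <- stats::rnorm(6) + stats::runif(1, 0, 2)
    ours <- compare_error_distributions(g1, g2)
    oracle <- stats::wilcox.test(g1, g2, exact = TRUE)$p.value
    expect_equal(ours$p_value, oracle, tolerance = 1e-12)
  }
})

test_that("evaluation reports bundle the metrics consistently", {
  m <- small_ssm()
  co <- small_cohort()
  xt <- model_landmarks(m, numeric(0))
  prob <- reconstruction_problem(m, xt, M = 2L, population = 20L,
                                 generations = 20L)
  rec <- reconstruct(prob, seed = 1L)
  rep_ <- evaluation_report(rec, xt, co$shapes[[1]], scenario = "digitized",
                            split = "train")
  expect_equal(rep_$s2s, sqrt(mean(rep_$per_vertex^2)), tolerance = 1e-9)
  expect_true(all(rep_$l2l >= 0))
  expect_output(print(rep_), "S2S RMSE")
})
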