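test_that("a rank-1 cohort recovers its generating direction and scale", {
  set.seed(4)
  n_v <- 30L
  base <- matrix(stats::rnorm(n_v * 3, sd = 20), n_v, 3L)
  phi <- stats::rnorm(3L * n_v)
  phi <- phi / sqrt(sum(phi^2))
  sigma <- 2.5
  a_vals <- c(-2, -1, 0, 1, 2) * sigma
  cohort <- lapply(a_vals, function(a) {
    list(vertices = base + scapssm:::vec_to_shape(a * phi))
  })
  m <- build_ssm(cohort)
  expect_equal(length(m$mode_sd), 1L)
  expect_equal(m$mode_sd[1], sigma * stats::sd(c(-2, -1, 0, 1, 2)),
               tolerance = 1e-9)
  expect_gt(abs(sum(m$modes[, 1] * phi)), 1 - 1e-9)
})

test_that("identical shapes give a zero-mode model with a warning", {
  v <- icosphere(1, 5)$vertices
  expect_warning(m <- build_ssm(list(list(vertices = v),
                                     list(vertices = v),
                                     list(vertices = v))),
                 "identical")
  expect_equal(length(m$mode_sd), 0L)
  expect_equal(specificity(m, n_samples = 3L, M = 0L), 0)
})

test_that("PCA basis is orthonormal and complete on training shapes", {
  m <- small_ssm()
  G <- crossprod(m$modes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(m$mode_sd) <= 1e-12))
  expect_lte(length(m$mode_sd), m$n_training - 1L)
  # full-mode reconstruction of a training shape is exact
  for (i in c(1L, 7L)) {
    x <- m$training[i, ]
    h <- x - m$mean_shape
    recon <- m$mean_shape + as.vector(m$modes %*% crossprod(m$modes, h))
    expect_lt(max(abs(recon - x)), 1e-6)
  }
})

test_that("synthesis is linear and scaled in SD units", {
  m <- small_ssm()
  mean_mesh <- synthesize(m, numeric(0))
  expect_identical(scapssm:::shape_to_vec(mean_mesh$vertices), m$mean_shape)
  plus <- synthesize(m, c(3, 0, 0, 0, 0))$vertices
  minus <- synthesize(m, c(-3, 0, 0, 0, 0))$vertices
  expect_equal((plus + minus) / 2, mean_mesh$vertices, tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in 1:3) {
    kap <- rep(0, j); kap[j] <- 1
    disp <- scapssm:::shape_to_vec(synthesize(m, kap)$vertices) - m$mean_shape
    expect_equal(sqrt(sum(disp^2)), m$mode_sd[j], tolerance = 1e-9)
  }
  expect_error(synthesize(m, rep(0, length(m$mode_sd) + 1L)), "modes")
})

test_that("compactness is simple cumulative-variance arithmetic", {
  fake <- structure(list(mode_sd = sqrt(c(4, 3, 2, 1))),
                    class = "scapula_ssm")
  expect_equal(compactness(fake), c(0.4, 0.7, 0.9, 1.0))
  fake1 <- structure(list(mode_sd = 2), class = "scapula_ssm")
  expect_equal(compactness(fake1), 1.0)
  fake5 <- structure(list(mode_sd = rep(1, 5)), class = "scapula_ssm")
  expect_equal(compactness(fake5), seq(0.2, 1, by = 0.2))
  cv <- compactness(small_ssm())
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[length(cv)], 1.0, tolerance = 1e-12)
})

test_that("generalization vanishes for in-span cohorts and shrinks with M", {
  set.seed(9)
  n_v <- 25L
  base <- matrix(stats::rnorm(n_v * 3, sd = 15), n_v, 3L)
  B <- qr.Q(qr(matrix(stats::rnorm(3L * n_v * 2L), 3L * n_v, 2L)))
  cohort <- lapply(1:8, function(i) {
    list(vertices = base +
           scapssm:::vec_to_shape(as.vector(B %*% stats::rnorm(2, sd = 4))))
  })
  expect_lt(generalization(cohort, M = 2L), 1e-6)
  co <- small_cohort()
  g <- vapply(1:4, function(M) generalization(co$shapes[1:8], M), 0)
  expect_true(all(diff(g) <= 1e-9))
  expect_error(generalization(co$shapes[1:4], M = 10L), "rank|exceeds|M")
})

test_that("specificity stays small for a well-populated model", {
  m <- small_ssm()
  sp <- specificity(m, n_samples = 25L, M = 2L, seed = 3L)
  expect_gte(sp, 0)
  # samples live in the training span, so distances stay of the order of
  # the smallest mode amplitudes (per-vertex)
  expect_lt(sp, 3 * sum(m$mode_sd) / sqrt(length(m$mean_shape) / 3))
})
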