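rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("ICP recovers a known rigid transform with landmark init", {
  co <- small_cohort()
  tpl <- co$template$mesh
  R <- rot_z(30); t_vec <- c(10, 0, 0)
  moved <- triangle_mesh(apply_rigid(tpl$vertices, R, t_vec), tpl$faces)
  lm_idx <- co$template$landmark_indices
  init <- list(moving = moved$vertices[lm_idx, ],
               reference = tpl$vertices[lm_idx, ])
  reg <- rigid_register(moved, tpl, init = init)
  back <- apply_rigid(moved$vertices, reg$rotation, reg$translation)
  expect_lt(sqrt(mean(rowSums((back - tpl$vertices)^2))), 1e-3)
  # monotone up to the fp noise floor of the distance computation (~1e-7 mm)
  expect_true(all(diff(reg$cost_trace) <= 1e-6))
})

test_that("registering a mesh to itself yields the identity", {
  tpl <- small_cohort()$template$mesh
  reg <- rigid_register(tpl, tpl)
  expect_lt(max(abs(reg$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(reg$translation)), 1e-6)
  expect_lt(reg$cost, 1e-5)
})

test_that("self-correspondence is the identity", {
  tpl <- small_cohort()$template$mesh
  lm_idx <- small_cohort()$template$landmark_indices
  lp <- list(moving = tpl$vertices[lm_idx, ],
             reference = tpl$vertices[lm_idx, ])
  cs <- nonrigid_correspond(tpl, tpl, landmarks = lp, iterations = 4L)
  expect_equal(cs$vertices, tpl$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a uniformly scaled copy is matched through the affine TPS part", {
  tpl <- small_cohort()$template$mesh
  lm_idx <- small_cohort()$template$landmark_indices
  scaled <- triangle_mesh(tpl$vertices * 1.1, tpl$faces)
  lp <- list(moving = scaled$vertices[lm_idx, ],
             reference = tpl$vertices[lm_idx, ])
  cs <- nonrigid_correspond(scaled, tpl, landmarks = lp)
  expect_lt(mean(row_norms(cs$vertices - tpl$vertices * 1.1)), 0.1)
})

test_that("corresponded vertices land on a smoothly bumped surface", {
  s <- icosphere(3, radius = 30)
  dirs <- s$vertices / row_norms(s$vertices)
  bump <- 3 * exp(-rowSums(sweep(dirs, 2, c(0, 0, 1))^2) / 0.3)
  bumped <- triangle_mesh(s$vertices + dirs * bump, s$faces)
  cs <- nonrigid_correspond(bumped, s, landmarks = NULL)
  d <- closest_on_surface(cs$vertices, bumped)$dist
  expect_lt(mean(d), 0.5)
  # correspondence should track the bump, not collapse: vertex near the pole
  top <- which.max(s$vertices[, 3])
  expect_gt(row_norms(cs$vertices[top, , drop = FALSE]), 31.5)
})

test_that("correspondence commutes with rigid motion of the moving shape", {
  s <- icosphere(2, radius = 20)
  dirs <- s$vertices / row_norms(s$vertices)
  moving <- triangle_mesh(s$vertices + dirs *
                            (1.5 * sin(s$vertices[, 1] / 8)), s$faces)
  cs0 <- nonrigid_correspond(moving, s)
  R <- rot_z(25); t_vec <- c(5, -3, 2)
  # move both the moving surface and the reference by the same rigid motion
  moved <- triangle_mesh(apply_rigid(moving$vertices, R, t_vec),
                         moving$faces)
  ref_moved <- triangle_mesh(apply_rigid(s$vertices, R, t_vec), s$faces)
  cs1 <- nonrigid_correspond(moved, ref_moved)
  d <- row_norms(cs1$vertices - apply_rigid(cs0$vertices, R, t_vec))
  # floating-point sensitivity of nearest-face selection makes this
  # approximate; the deformations themselves commute
  expect_lt(mean(d), 0.02)
  expect_lt(max(d), 0.5)
})

test_that("thin-plate splines reproduce affine maps exactly", {
  set.seed(3)
  src <- matrix(stats::rnorm(12, sd = 40), 4, 3)
  A <- diag(3) * 1.1
  b <- c(4, -2, 7)
  warp <- tps_warp(src, src %*% A + matrix(b, 4, 3, byrow = TRUE))
  q <- matrix(stats::rnorm(60, sd = 40), 20, 3)
  expect_equal(warp(q), q %*% A + matrix(b, 20, 3, byrow = TRUE),
               tolerance = 1e-6)
})
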