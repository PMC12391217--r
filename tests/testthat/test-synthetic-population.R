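test_that("the procedural template is deterministic with valid landmarks", {
  t1 <- make_template(seed = 3L, n_vertices = 642L)
  t2 <- make_template(seed = 3L, n_vertices = 642L)
  expect_identical(t1$mesh$vertices, t2$mesh$vertices)
  expect_identical(t1$landmark_indices, t2$landmark_indices)
  expect_equal(nrow(t1$mesh$vertices), 642L)
  expect_true(is_closed_mesh(t1$mesh))
  expect_length(unique(t1$landmark_indices), 4L)
  tri <- t1$mesh$vertices[t1$landmark_indices[c("AA", "TS", "AI")], ]
  area <- 0.5 * sqrt(sum(scapssm:::cross3(tri[2, ] - tri[1, ],
                                          tri[3, ] - tri[1, ])^2))
  expect_gt(area, 100)  # well-separated, non-collinear
  t3 <- make_template(seed = 4L, n_vertices = 642L)
  expect_false(identical(t1$mesh$vertices, t3$mesh$vertices))
})

test_that("cohort generation is reproducible under a fixed seed", {
  cfg <- population_config(n_subjects = 6L, template_vertices = 162L,
                           seed = 9L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$kappa_true, c2$kappa_true)
  expect_identical(c1$skin[[4]]$points, c2$skin[[4]]$points)
  expect_identical(c1$shapes[[2]]$vertices, c2$shapes[[2]]$vertices)
})

test_that("zero noise and zero offsets make skin equal bone", {
  ot <- scapssm:::default_offset_table()
  ot[, c("base", "weight", "bmi", "sex", "age")] <- 0
  cfg <- population_config(n_subjects = 4L, template_vertices = 162L,
                           noise_sd = 0, offset_table = ot, seed = 2L)
  co <- generate_cohort(cfg)
  for (i in seq_along(co$skin)) {
    expect_equal(co$skin[[i]]$points, co$bone[[i]]$points,
                 tolerance = 1e-12)
  }
})

test_that("the zero-noise offset model holds exactly in the body frame", {
  cfg <- population_config(n_subjects = 5L, template_vertices = 162L,
                           noise_sd = 0, seed = 3L)
  co <- generate_cohort(cfg)
  for (i in seq_along(co$skin)) {
    fr <- build_isb_scapula_frame(co$skin[[i]])
    diff_bf <- to_body_frame(co$skin[[i]], fr)$points -
      to_body_frame(co$bone[[i]], fr)$points
    o <- scapssm:::offset_for_subject(cfg$offset_table,
                                      cfg$covariate_centers,
                                      co$subjects[[i]])
    expect_equal(as.vector(t(diff_bf)), o, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("a known-rank cohort yields a model of exactly that rank", {
  cfg <- population_config(n_subjects = 40L, n_true_modes = 3L,
                           mode_rms_mm = c(4, 2.5, 1.5),
                           template_vertices = 162L, seed = 21L)
  co <- generate_cohort(cfg)
  m <- build_ssm(co$shapes, faces = co$template$mesh$faces,
                 landmark_indices = co$template$landmark_indices)
  expect_gt(compactness(m)[3], 0.999)
})

test_that("cohort demographics match the configured samplers", {
  cfg <- population_config(n_subjects = 60L, template_vertices = 162L,
                           seed = 31L)
  co <- generate_cohort(cfg)
  w <- vapply(co$subjects, function(s) s$weight, 0)
  h <- vapply(co$subjects, function(s) s$height, 0)
  d <- cfg$demographics
  expect_lt(abs(mean(w) - d$weight_mean), 3 * d$weight_sd / sqrt(60))
  expect_lt(abs(mean(h) - d$height_mean), 3 * d$height_sd / sqrt(60))
  bmi <- vapply(co$subjects, function(s) s$bmi, 0)
  expect_equal(bmi, w / h^2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("written cohorts reload through the standard readers", {
  cfg <- population_config(n_subjects = 4L, template_vertices = 162L,
                           seed = 6L)
  co <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  rt <- scapssm:::read_cohort_dir(dir)
  expect_length(rt$meshes, 4L)
  expect_equal(rt$meshes$S002$vertices, co$shapes$S002$vertices,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rt$skin$S003$points, co$skin$S003$points, tolerance = 1e-12)
  expect_equal(rt$subjects$S001$bmi, co$subjects$S001$bmi)
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$noise_sd, cfg$noise_sd)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(population_config(n_true_modes = 0L), ">= 1")
  expect_error(population_config(n_true_modes = 3L, mode_rms_mm = c(1, 2)),
               "per true mode")
  expect_error(population_config(noise_sd = -1), "non-negative")
})
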