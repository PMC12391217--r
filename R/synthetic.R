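# Synthetic scapula-like population: a procedural template with labeled
# landmarks, smooth orthonormal deformation modes with known standard
# deviations, demographics matching the cohort statistics the pipeline is
# designed for, and covariate-driven soft-tissue offsets between bone and
# skin landmarks. Every stage of the pipeline is testable against this
# generator's exact ground truth.

#' Procedural scapula-like template surface
#'
#' A smooth, flattened, wing-like closed surface (a deformed geodesic
#' sphere: strongly anisotropic scaling, superior-inferior taper, a spine-
#' like ridge and an acromion-like bump) decimated to exactly `n_vertices`,
#' with four well-separated labeled vertices standing in for AA, TS, AI and
#' AC. It reproduces the structural features the algorithms exercise (four
#' non-collinear landmarks, smooth curvature, ~mm scale), not scapular
#' anatomy.
#'
#' @param seed RNG seed (jitters the bump geometry reproducibly).
#' @param n_vertices exact vertex count of the returned template.
#' @return list with `mesh` (a [triangle_mesh()]) and `landmark_indices`
#'   (named integer vector AA, TS, AI, AC).
#' @export
make_template <- function(seed = 1L, n_vertices = 6000L) {
  set.seed(seed)
  counts <- c(42L, 162L, 642L, 2562L, 10242L, 40962L)
  sub <- which(counts >= n_vertices)[1L]
  if (is.na(sub)) stop("n_vertices too large for the template generator",
                       call. = FALSE)
  s <- icosphere(sub, radius = 1)
  v <- s$vertices
  # flattened wing: thin along x, tall along y, wide along z (mm)
  v <- cbind(9 * v[, 1L], 72 * v[, 2L], 52 * v[, 3L])
  # superior-inferior taper (narrower at the bottom)
  taper <- 1 - 0.35 * pmax(-v[, 2L] / 72, 0)
  v[, 3L] <- v[, 3L] * taper
  # spine-like ridge along the upper third and an acromion-like bump at the
  # lateral end (seeded jitter keeps distinct seeds distinct)
  jit <- stats::rnorm(6, 0, 1)
  ridge <- 5 * exp(-((v[, 2L] - (30 + jit[1L]))^2) / (2 * 12^2))
  bump <- 7 * exp(-(((v[, 2L] - (34 + jit[2L]))^2) / (2 * 14^2) +
                      ((v[, 3L] - (44 + jit[3L]))^2) / (2 * 14^2)))
  v[, 1L] <- v[, 1L] + (ridge + bump) * sign(v[, 1L] + 1e-9) *
    pmax(v[, 1L] / 9, 0.15)
  mesh <- triangle_mesh(v, s$faces, id = "template")
  if (n_vertices < nrow(v)) mesh <- decimate_to(mesh, n_vertices)
  vv <- mesh$vertices
  pick <- function(score, exclude = integer(0)) {
    s <- score
    s[exclude] <- -Inf
    which.max(s)
  }
  aa <- pick(vv[, 3L] + 0.4 * vv[, 2L])                 # lateral-superior
  ts <- pick(-vv[, 3L] + 0.4 * vv[, 2L], aa)            # medial-superior
  ai <- pick(-vv[, 2L], c(aa, ts))                      # inferior angle
  ac <- pick(vv[, 3L] + 0.8 * vv[, 2L] + 2 * vv[, 1L],  # anterior-lateral
             c(aa, ts, ai))
  idx <- c(AA = aa, TS = ts, AI = ai, AC = ac)
  tri <- vv[idx[c("AA", "TS", "AI")], ]
  if (sqrt(sum(cross3(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])^2)) < 1) {
    stop("degenerate template: AA, TS, AI nearly collinear", call. = FALSE)
  }
  list(mesh = mesh, landmark_indices = idx)
}

# Smooth orthonormal deformation fields on the template, echoing the kinds
# of variation a scapula SSM exhibits: uniform scaling, height change,
# bending about a medial-lateral axis, thickness change, and a local
# acromion-region change; higher modes are smooth trigonometric fields.
make_modes <- function(template, n_modes) {
  v <- template$mesh$vertices
  n <- nrow(v)
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  h <- max(abs(vc[, 2L])); w <- max(abs(vc[, 3L]))
  aa <- v[template$landmark_indices[["AA"]], ]
  d_aa2 <- rowSums(sweep(v, 2L, aa)^2)
  raw <- list(
    vc,                                                   # uniform scaling
    cbind(0, vc[, 2L], 0),                                # height
    cbind((vc[, 2L] / h)^2, 0, 0),                        # bending
    cbind(vc[, 1L], 0, 0),                                # thickness
    exp(-d_aa2 / (2 * (0.3 * w)^2)) * vc / pmax(row_norms(vc), 1e-9),
    cbind(sin(pi * vc[, 2L] / h), 0, 0),
    cbind(0, 0, sin(pi * vc[, 3L] / w)),
    cbind(0, sin(pi * vc[, 3L] / w), 0))
  if (n_modes > length(raw)) {
    stop("at most ", length(raw), " true modes supported", call. = FALSE)
  }
  B <- vapply(raw[seq_len(n_modes)], shape_to_vec, numeric(3L * n))
  qr.Q(qr(B))[, seq_len(n_modes), drop = FALSE]
}

default_offset_table <- function() {
  # base soft-tissue offsets (mm, body-fixed frame; x anterior) and linear
  # covariate coefficients; AI carries the largest offsets and the weight
  # dependence, AA the sex dependence, TS/AC the BMI/age dependences
  data.frame(
    landmark = rep(c("AA", "TS", "AI", "AC"), each = 3L),
    axis = rep(c("x", "y", "z"), 4L),
    base = c(4, 2, 1, 6, 3, 2, 10, 4, 3, 5, 2, 1),
    weight = c(0, 0, 0, 0, 0, 0, 0.10, 0.05, 0.08, 0, 0, 0),
    bmi = c(0, 0, 0, 0.25, 0, 0.15, 0, 0, 0, 0.20, 0, 0),
    sex = c(1.5, 1.0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    age = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.05, 0),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic population generator
#'
#' Defaults encode the study conditions the pipeline is designed for:
#' demographics with mean weight 75.3 kg (SD 15.9), height 1.71 m (SD 0.08),
#' age 50 y (SD 18) and 23/56 male fraction; isotropic skin-landmark noise of
#' SD 0.3 mm; five true modes with per-vertex RMS amplitudes of
#' 4, 2.5, 1.5, 1.0 and 0.6 mm per standard deviation.
#'
#' @param n_subjects cohort size.
#' @param n_true_modes number of generating modes (<= 8).
#' @param mode_rms_mm per-vertex RMS amplitude (mm) of one SD of each mode.
#' @param noise_sd isotropic skin-landmark noise SD (mm, body frame).
#' @param offset_table soft-tissue offset model (see
#'   `scapssm:::default_offset_table`).
#' @param template_vertices template vertex count.
#' @param template_seed seed for the procedural template.
#' @param demographics list of sampler parameters.
#' @param seed RNG seed for the cohort draw.
#' @return a `population_config` list.
#' @export
population_config <- function(n_subjects = 56L, n_true_modes = 5L,
                              mode_rms_mm = c(4, 2.5, 1.5, 1.0, 0.6),
                              noise_sd = 0.3,
                              offset_table = default_offset_table(),
                              template_vertices = 6000L,
                              template_seed = 1L,
                              demographics = list(
                                p_male = 23 / 56,
                                age_mean = 50, age_sd = 18,
                                weight_mean = 75.3, weight_sd = 15.9,
                                height_mean = 1.71, height_sd = 0.08),
                              seed = 1L) {
  if (n_true_modes < 1L) stop("n_true_modes must be >= 1", call. = FALSE)
  if (length(mode_rms_mm) < n_true_modes) {
    stop("mode_rms_mm must supply one amplitude per true mode", call. = FALSE)
  }
  if (any(mode_rms_mm < 0) || noise_sd < 0) {
    stop("amplitudes and noise SD must be non-negative", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_true_modes = as.integer(n_true_modes),
                 mode_rms_mm = mode_rms_mm[seq_len(n_true_modes)],
                 noise_sd = noise_sd, offset_table = offset_table,
                 template_vertices = as.integer(template_vertices),
                 template_seed = as.integer(template_seed),
                 demographics = demographics,
                 covariate_centers = c(weight = 75.3, bmi = 25.75, age = 50),
                 seed = as.integer(seed)),
            class = "population_config")
}

sample_demographics <- function(cfg, i) {
  d <- cfg$demographics
  subject_record(
    id = sprintf("S%03d", i),
    sex = stats::rbinom(1L, 1L, d$p_male),
    age = min(max(stats::rnorm(1L, d$age_mean, d$age_sd), 20), 85),
    weight = min(max(stats::rnorm(1L, d$weight_mean, d$weight_sd), 42), 130),
    height = min(max(stats::rnorm(1L, d$height_mean, d$height_sd), 1.45),
                 2.05))
}

offset_for_subject <- function(offset_table, centers, subject) {
  with(offset_table,
       base + weight * (subject$weight - centers[["weight"]]) +
         bmi * (subject$bmi - centers[["bmi"]]) +
         sex * subject$sex +
         age * (subject$age - centers[["age"]]))
}

# Solve skin = bone + offset expressed in the skin-derived body frame:
# fixed-point iteration on skin <- bone + o_bf %*% axes(skin). At the fixed
# point, to_body_frame(skin) - to_body_frame(bone) equals o_bf exactly.
solve_skin_landmarks <- function(bone_points, o_bf, max_iter = 50L,
                                 tol = 1e-12) {
  o <- matrix(o_bf, 4L, 3L, byrow = TRUE)
  skin <- bone_points + o
  rownames(skin) <- rownames(bone_points)
  for (it in seq_len(max_iter)) {
    fr <- build_isb_scapula_frame(landmark_set(skin, level = "skin"))
    new_skin <- bone_points + o %*% fr$axes
    delta <- max(abs(new_skin - skin))
    skin <- new_skin
    rownames(skin) <- rownames(bone_points)
    if (delta < tol) break
  }
  if (delta >= 1e-9) {
    warning("skin-landmark fixed point converged only to ", signif(delta, 2),
            " mm")
  }
  skin
}

#' Generate a synthetic corresponded cohort
#'
#' Each subject's shape is `template + sum_m kappa_m sigma_m phi_m` with
#' `kappa ~ N(0, 1)` over smooth orthonormal modes; bone landmarks are the
#' deformed landmark vertices; demographics are drawn from the configured
#' samplers; skin landmarks equal bone landmarks plus a covariate-dependent
#' soft-tissue offset plus isotropic noise, where the offset model holds
#' exactly in each subject's own skin-derived body-fixed frame (solved by a
#' short fixed-point iteration), so the regression ground truth is exact.
#'
#' @param config a [population_config()].
#' @return object of class `synthetic_cohort`: `template` (mesh +
#'   `landmark_indices`), `shapes` (list of `corresponded_shape`),
#'   `kappa_true` (n x M), `bone`/`skin` (lists of global-frame
#'   [landmark_set()]s), `subjects`, `modes` (orthonormal 3N x M),
#'   `mode_sd` (vector-norm units, mm), and the generating `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "population_config"))
  template <- make_template(config$template_seed, config$template_vertices)
  n_v <- nrow(template$mesh$vertices)
  modes <- make_modes(template, config$n_true_modes)
  mode_sd <- config$mode_rms_mm * sqrt(n_v)  # per-vertex RMS -> vector norm
  set.seed(config$seed)
  M <- config$n_true_modes
  n <- config$n_subjects
  kappa <- matrix(stats::rnorm(n * M), n, M)
  t_vec <- shape_to_vec(template$mesh$vertices)
  lm_idx <- template$landmark_indices
  shapes <- vector("list", n)
  bone <- skin <- subjects <- vector("list", n)
  for (i in seq_len(n)) {
    x <- t_vec + as.vector(modes %*% (kappa[i, ] * mode_sd))
    verts <- vec_to_shape(x)
    sid <- sprintf("S%03d", i)
    shapes[[i]] <- structure(list(vertices = verts,
                                  faces = template$mesh$faces,
                                  source_id = sid),
                             class = "corresponded_shape")
    subjects[[i]] <- sample_demographics(config, i)
    bone_pts <- verts[lm_idx, , drop = FALSE]
    rownames(bone_pts) <- names(lm_idx)
    o_bf <- offset_for_subject(config$offset_table, config$covariate_centers,
                               subjects[[i]]) +
      stats::rnorm(12L, 0, config$noise_sd)
    skin_pts <- solve_skin_landmarks(bone_pts, o_bf)
    bone[[i]] <- landmark_set(bone_pts, level = "bone")
    skin[[i]] <- landmark_set(skin_pts, level = "skin")
  }
  ids <- vapply(subjects, function(s) s$id, "")
  names(shapes) <- names(bone) <- names(skin) <- names(subjects) <- ids
  structure(list(template = template, shapes = shapes,
                 kappa_true = kappa, bone = bone, skin = skin,
                 subjects = subjects, modes = modes, mode_sd = mode_sd,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d true modes, template %d vertices\n",
              length(x$shapes), ncol(x$kappa_true),
              nrow(x$template$mesh$vertices)))
  invisible(x)
}

#' Regression design matrices for a cohort
#'
#' Builds, for each subject, the body-fixed frame from the skin landmarks and
#' assembles the 17 predictors and 12 bone-coordinate responses used by
#' [fit_skin_to_bone()].
#'
#' @param skin,bone named lists of global-frame [landmark_set()]s.
#' @param subjects named list of [subject_record()]s (same order).
#' @return list with `X` (n x 17), `Y` (n x 12), `frames` (per-subject
#'   [build_isb_scapula_frame()] objects).
#' @export
cohort_regression_data <- function(skin, bone, subjects) {
  n <- length(skin)
  stopifnot(length(bone) == n, length(subjects) == n)
  X <- matrix(0, n, length(PREDICTOR_NAMES),
              dimnames = list(names(skin), PREDICTOR_NAMES))
  Y <- matrix(0, n, length(RESPONSE_NAMES),
              dimnames = list(names(skin), RESPONSE_NAMES))
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- build_isb_scapula_frame(skin[[i]])
    skin_bf <- to_body_frame(skin[[i]], fr)
    bone_bf <- to_body_frame(bone[[i]], fr)
    X[i, ] <- assemble_predictors(skin_bf, subjects[[i]])
    Y[i, ] <- as.vector(t(bone_bf$points))
    frames[[i]] <- fr
  }
  names(frames) <- names(skin)
  list(X = X, Y = Y, frames = frames)
}

#' Write a synthetic cohort to disk in the package's interchange formats
#'
#' PLY meshes, the landmark CSV schema of [load_landmarks()], the subject CSV
#' schema of [load_subjects()], and a ground-truth JSON (true mode weights,
#' offset model, landmark vertex indices).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "meshes"), recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$shapes)) {
    sh <- cohort$shapes[[sid]]
    write_ply(triangle_mesh(sh$vertices, sh$faces, check = FALSE),
              file.path(dir, "meshes", paste0(sid, ".ply")))
  }
  lm <- list()
  for (sid in names(cohort$bone)) {
    lm[[sid]] <- list(bone = cohort$bone[[sid]], skin = cohort$skin[[sid]])
  }
  write_landmarks(lm, file.path(dir, "landmarks.csv"))
  write_subjects(cohort$subjects, file.path(dir, "subjects.csv"))
  gt <- list(kappa_true = cohort$kappa_true,
             mode_rms_mm = cohort$config$mode_rms_mm,
             noise_sd = cohort$config$noise_sd,
             offset_table = cohort$config$offset_table,
             covariate_centers = as.list(cohort$config$covariate_centers),
             landmark_indices = as.list(cohort$template$landmark_indices),
             template_seed = cohort$config$template_seed,
             seed = cohort$config$seed)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
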