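# Shared fixtures, built once per test run (all generated in code).

.fixtures <- new.env()

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# 20-subject cohort on a 642-vertex template: the workhorse fixture
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(population_config(n_subjects = 20L,
                                      template_vertices = 642L, seed = 7L))
  })
}

small_ssm <- function() {
  fixture("small_ssm", function() {
    co <- small_cohort()
    build_ssm(co$shapes, faces = co$template$mesh$faces,
              landmark_indices = co$template$landmark_indices)
  })
}

# random valid skin landmark configuration at anatomical scale (mm)
rand_skin_landmarks <- function() {
  repeat {
    pts <- matrix(stats::rnorm(12, sd = 60), 4L, 3L,
                  dimnames = list(c("AA", "TS", "AI", "AC"),
                                  c("x", "y", "z")))
    span <- min(dist(pts[1:3, ]))
    area <- sqrt(sum(scapssm:::cross3(pts[2, ] - pts[1, ],
                                      pts[3, ] - pts[1, ])^2))
    if (span > 20 && area > 400) {
      return(landmark_set(pts, level = "skin"))
    }
  }
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# tetrahedron PLY written to a temp file
write_tetra_ply <- function(path, nan = FALSE) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (nan) v[2, 1] <- NaN
  lines <- c("ply", "format ascii 1.0", "element vertex 4",
             "property float x", "property float y", "property float z",
             "element face 4",
             "property list uchar int vertex_indices", "end_header",
             apply(v, 1, paste, collapse = " "),
             "3 0 2 1", "3 0 1 3", "3 0 3 2", "3 1 2 3")
  writeLines(lines, path)
  path
}

write_mesh_as_ascii_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  out <- c("solid shape")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    out <- c(out, "facet normal 0 0 0", "outer loop",
             paste("vertex", apply(format(tri, digits = 17), 1, paste,
                                   collapse = " ")),
             "endloop", "endfacet")
  }
  writeLines(c(out, "endsolid shape"), path)
  path
}

# Exhaustive stepwise oracle: subsets stable under the same F criteria
# (no in-model predictor removable above p_remove, no out-of-model predictor
# enterable below p_enter). Independent brute-force enumeration.
stable_subsets <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  p <- ncol(X); n <- nrow(X)
  all_sets <- unlist(lapply(0:p, function(k) {
    utils::combn(colnames(X), k, simplify = FALSE)
  }), recursive = FALSE)
  Filter(function(s) {
    rss_s <- scapssm:::rss_of(X[, s, drop = FALSE], y)
    if (length(s)) {
      df2 <- n - length(s) - 1L
      pr <- vapply(s, function(j) {
        rss_red <- scapssm:::rss_of(X[, setdiff(s, j), drop = FALSE], y)
        stats::pf((rss_red - rss_s) / (rss_s / df2), 1, df2,
                  lower.tail = FALSE)
      }, 0)
      if (any(pr > p_remove)) return(FALSE)
    }
    out <- setdiff(colnames(X), s)
    if (length(out) && rss_s > 1e-12 * sum((y - mean(y))^2)) {
      df2 <- n - length(s) - 2L
      pe <- vapply(out, function(j) {
        rss_new <- scapssm:::rss_of(X[, c(s, j), drop = FALSE], y)
        f <- (rss_s - rss_new) / (rss_new / df2)
        if (!is.finite(f)) return(0)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, 0)
      if (any(pe < p_enter)) return(FALSE)
    }
    TRUE
  }, all_sets)
}

# which responses' generating predictors are recovered with coefficients
# within `tol` relative error (the skin coordinate enters with coefficient 1
# where it is a free predictor)
recovered_responses <- function(fit, offset_table, tol = 0.15) {
  cf <- coef(fit)
  free <- c(TS.z = "TS.z", AI.y = "AI.y", AI.z = "AI.z",
            AC.x = "AC.x", AC.y = "AC.y", AC.z = "AC.z")
  vapply(rownames(cf), function(r) {
    lmk <- sub("[.].*", "", r); ax <- sub(".*[.]", "", r)
    row <- offset_table[offset_table$landmark == lmk &
                          offset_table$axis == ax, ]
    truth <- c(weight = -row$weight, bmi = -row$bmi, sex = -row$sex,
               age = -row$age)
    truth <- truth[truth != 0]
    if (r %in% names(free)) truth <- c(truth, stats::setNames(1, free[[r]]))
    if (length(truth) == 0L) return(TRUE)  # intercept-only ground truth
    got <- cf[r, names(truth)]
    all(got != 0) && all(abs(got - truth) / abs(truth) <= tol)
  }, TRUE)
}
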