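#' Triangle surface mesh
#'
#' Light-weight container for a triangulated surface: an n x 3 matrix of
#' vertex coordinates (mm) and an f x 3 integer matrix of 1-based vertex
#' indices. All package geometry (registration, shape modelling,
#' reconstruction) operates on this class.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates in mm.
#' @param faces f x 3 integer matrix of vertex indices (1-based).
#' @param id optional identifier (subject or shape id).
#' @param check if `TRUE`, validate invariants (finite coordinates, indices
#'   in range, no zero-area faces).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `id`.
#' @export
triangle_mesh <- function(vertices, faces, id = NULL, check = TRUE) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces, id = id),
                    class = "triangle_mesh")
  if (check) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh, require_nondegenerate = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) < 3L) stop("mesh must have at least 3 vertices", call. = FALSE)
  if (!all(is.finite(v))) stop("mesh vertices contain non-finite coordinates",
                               call. = FALSE)
  if (nrow(f) < 1L) stop("mesh has no faces", call. = FALSE)
  if (min(f) < 1L || max(f) > nrow(v)) {
    stop("face indices out of range", call. = FALSE)
  }
  if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L])) {
    stop("mesh contains topologically degenerate faces", call. = FALSE)
  }
  if (require_nondegenerate) {
    a <- face_areas(mesh)
    if (any(a <= 0)) stop("mesh contains zero-area faces", call. = FALSE)
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh%s: %d vertices, %d faces\n",
              if (!is.null(x$id)) paste0(" '", x$id, "'") else "",
              nrow(x$vertices), nrow(x$faces)))
  ext <- apply(x$vertices, 2L, range)
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

#' Per-face areas and normals
#' @param mesh a [triangle_mesh()].
#' @return `face_areas`: numeric vector of triangle areas;
#'   `face_normals`: f x 3 matrix of unit normals.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- row_norms(n)
  len[len == 0] <- 1
  n / len
}

#' Area-weighted vertex normals
#' @param mesh a [triangle_mesh()].
#' @keywords internal
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], mesh$faces[, j], reorder = FALSE)
      n[as.integer(rownames(acc)), k] <- n[as.integer(rownames(acc)), k] + acc
    }
  }
  len <- row_norms(n)
  len[len == 0] <- 1
  n / len
}

#' Undirected edge list of a mesh
#' @return matrix with columns v1, v2 (v1 < v2) and `count` attribute giving
#'   the number of incident faces per edge.
#' @keywords internal
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key <- paste(e[, 1L], e[, 2L])
  tab <- table(key)
  uk <- !duplicated(key)
  edges <- e[uk, , drop = FALSE]
  attr(edges, "count") <- as.integer(tab[paste(edges[, 1L], edges[, 2L])])
  edges
}

is_closed_mesh <- function(mesh) {
  all(attr(mesh_edges(mesh), "count") == 2L)
}

euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Sample points uniformly on a mesh surface
#' @param mesh a [triangle_mesh()].
#' @param n number of points.
#' @param seed optional RNG seed for reproducibility.
#' @return n x 3 matrix of surface points.
#' @keywords internal
sample_surface_points <- function(mesh, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- face_areas(mesh)
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = a)
  f <- mesh$faces[fi, , drop = FALSE]
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  mesh$vertices[f[, 1L], , drop = FALSE] * w1 +
    mesh$vertices[f[, 2L], , drop = FALSE] * w2 +
    mesh$vertices[f[, 3L], , drop = FALSE] * w3
}

# Vectorized closest point on triangles (one triangle per query row).
# Standard barycentric region classification.
closest_point_on_triangles <- function(p, a, b, c) {
  dot <- function(x, y) rowSums(x * y)
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- dot(ab, ap); d2 <- dot(ac, ap)
  bp <- p - b; d3 <- dot(ab, bp); d4 <- dot(ac, bp)
  cp <- p - c; d5 <- dot(ab, cp); d6 <- dot(ac, cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  out <- matrix(NA_real_, nrow(p), 3L)
  done <- rep(FALSE, nrow(p))
  set <- function(mask, val) {
    m <- mask & !done
    if (any(m)) {
      out[m, ] <<- val[m, , drop = FALSE]
      done[m] <<- TRUE
    }
  }
  set(d1 <= 0 & d2 <= 0, a)
  set(d3 >= 0 & d4 <= d3, b)
  v_ab <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * ifelse(is.finite(v_ab), v_ab, 0))
  set(d6 >= 0 & d5 <= d6, c)
  w_ac <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * ifelse(is.finite(w_ac), w_ac, 0))
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
      b + (c - b) * ifelse(is.finite(w_bc), w_bc, 0))
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  set(rep(TRUE, nrow(p)), a + ab * ifelse(is.finite(v), v, 0) +
        ac * ifelse(is.finite(w), w, 0))
  out
}

#' Closest points on a mesh surface
#'
#' For each query point, finds the exact closest point on the triangulated
#' surface. Candidate triangles are restricted to those incident to the `k`
#' nearest mesh vertices, which is exact for well-shaped meshes and verified
#' against brute force in the test suite.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a [triangle_mesh()].
#' @param k number of nearest vertices whose incident faces are examined.
#' @return list with `points` (n x 3 closest surface points) and `dist`.
#' @export
closest_on_surface <- function(points, mesh, k = 8L) {
  p <- as_point_matrix(points)
  v <- mesh$vertices; f <- mesh$faces
  vf <- vertex_face_incidence(mesh)
  nn <- nn_points(p, v, k = k)
  out <- matrix(0, nrow(p), 3L)
  d <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    cand <- unique(unlist(vf[nn$index[i, ]], use.names = FALSE))
    tri <- f[cand, , drop = FALSE]
    pp <- matrix(p[i, ], nrow(tri), 3L, byrow = TRUE)
    cps <- closest_point_on_triangles(pp, v[tri[, 1L], , drop = FALSE],
                                      v[tri[, 2L], , drop = FALSE],
                                      v[tri[, 3L], , drop = FALSE])
    dd <- rowSums((cps - pp)^2)
    j <- which.min(dd)
    out[i, ] <- cps[j, ]
    d[i] <- sqrt(dd[j])
  }
  list(points = out, dist = d)
}

vertex_face_incidence <- function(mesh) {
  f <- mesh$faces
  fi <- rep(seq_len(nrow(f)), 3L)
  split(fi, as.vector(f))[as.character(seq_len(nrow(mesh$vertices)))]
}

#' Surface distance between two meshes
#'
#' Samples points on `from` and measures distance to the surface of `to`;
#' returns the mean and maximum (a Monte-Carlo Hausdorff estimate when
#' symmetrized by the caller).
#'
#' @param from,to [triangle_mesh()] objects.
#' @param n_samples number of surface sample points.
#' @param seed RNG seed for the surface sampling.
#' @return list with `mean` and `max` distances (mm).
#' @export
surface_distance <- function(from, to, n_samples = 2000L, seed = 1L) {
  pts <- rbind(sample_surface_points(from, n_samples, seed = seed),
               from$vertices)
  d <- closest_on_surface(pts, to)$dist
  list(mean = mean(d), max = max(d))
}

#' Icosphere test surface
#'
#' Geodesic sphere produced by repeated 1-to-4 subdivision of an icosahedron
#' with re-projection onto the sphere; used as a fixture surface and as the
#' base shape for the procedural scapula-like template.
#'
#' @param subdivisions number of subdivision rounds (vertex counts 12, 42,
#'   162, 642, 2562, 10242, ...).
#' @param radius sphere radius (mm).
#' @return a [triangle_mesh()].
#' @export
icosphere <- function(subdivisions = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / row_norms(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    n_v <- nrow(v)
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    e_sorted <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    key <- e_sorted[, 1L] * (n_v + 1L) + e_sorted[, 2L]
    uk <- !duplicated(key)
    mid_of <- match(key, key[uk])
    mids <- (v[e_sorted[uk, 1L], , drop = FALSE] +
               v[e_sorted[uk, 2L], , drop = FALSE]) / 2
    mids <- mids / row_norms(mids)
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- n_v + mid_of[seq_len(nf)]
    m23 <- n_v + mid_of[nf + seq_len(nf)]
    m31 <- n_v + mid_of[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1L], m12, m31),
               cbind(f[, 2L], m23, m12),
               cbind(f[, 3L], m31, m23),
               cbind(m12, m23, m31))
  }
  triangle_mesh(v * radius, f, id = "icosphere")
}
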