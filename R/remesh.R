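# Explicit isotropic remeshing: iterative edge split / collapse / flip with
# tangential relaxation and back-projection onto the input surface, followed
# by an exact-count pass so downstream shape vectors are fixed-size.
# Operates on a small mutable edit structure (environment).

mesh_editor <- function(mesh) {
  ed <- new.env(parent = emptyenv())
  ed$v <- mesh$vertices
  ed$f <- mesh$faces
  ed$v_alive <- rep(TRUE, nrow(ed$v))
  ed$f_alive <- rep(TRUE, nrow(ed$f))
  fi <- rep(seq_len(nrow(ed$f)), 3L)
  ed$vf <- split(fi, as.vector(ed$f))
  # ensure one (possibly empty) slot per vertex
  full <- vector("list", nrow(ed$v))
  full[as.integer(names(ed$vf))] <- ed$vf
  full[vapply(full, is.null, TRUE)] <- list(integer(0))
  ed$vf <- full
  ed
}

ed_faces_of <- function(ed, v) {
  fs <- ed$vf[[v]]
  fs <- fs[ed$f_alive[fs]]
  ed$vf[[v]] <- fs
  fs
}

ed_neighbors <- function(ed, v) {
  fs <- ed_faces_of(ed, v)
  u <- unique(as.vector(ed$f[fs, , drop = FALSE]))
  u[u != v]
}

ed_shared_faces <- function(ed, a, b) {
  intersect(ed_faces_of(ed, a), ed_faces_of(ed, b))
}

ed_add_vertex <- function(ed, pos) {
  ed$v <- rbind(ed$v, pos)
  ed$v_alive <- c(ed$v_alive, TRUE)
  ed$vf <- c(ed$vf, list(integer(0)))
  nrow(ed$v)
}

ed_add_face <- function(ed, tri) {
  ed$f <- rbind(ed$f, tri)
  ed$f_alive <- c(ed$f_alive, TRUE)
  id <- nrow(ed$f)
  for (vv in tri) ed$vf[[vv]] <- c(ed$vf[[vv]], id)
  id
}

tri_normal_area <- function(p1, p2, p3) {
  n <- cross3(p2 - p1, p3 - p1)
  list(normal = n, area2 = sqrt(sum(n * n)))
}

# Collapse edge (a,b) to its midpoint, keeping vertex a. Returns TRUE on
# success; refuses collapses that violate the link condition, create
# duplicate faces, or fold triangle normals.
ed_collapse <- function(ed, a, b) {
  if (!ed$v_alive[a] || !ed$v_alive[b]) return(FALSE)
  shared <- ed_shared_faces(ed, a, b)
  if (length(shared) != 2L) return(FALSE)
  opp <- vapply(shared, function(ff) {
    tri <- ed$f[ff, ]
    tri[tri != a & tri != b][1L]
  }, 0L)
  na <- ed_neighbors(ed, a); nb <- ed_neighbors(ed, b)
  common <- intersect(na, nb)
  if (!setequal(common, opp)) return(FALSE)          # link condition
  if (length(unique(c(na, nb))) <= 4L) return(FALSE) # keep >= tetrahedron
  m <- (ed$v[a, ] + ed$v[b, ]) / 2
  affected <- setdiff(unique(c(ed_faces_of(ed, a), ed_faces_of(ed, b))), shared)
  # fold-over / degeneracy guard
  for (ff in affected) {
    tri <- ed$f[ff, ]
    old <- tri_normal_area(ed$v[tri[1L], ], ed$v[tri[2L], ], ed$v[tri[3L], ])
    pos <- lapply(tri, function(vv) if (vv == a || vv == b) m else ed$v[vv, ])
    new <- tri_normal_area(pos[[1L]], pos[[2L]], pos[[3L]])
    if (new$area2 <= 1e-12 * max(old$area2, 1e-300)) return(FALSE)
    if (sum(new$normal * old$normal) <= 0) return(FALSE)
  }
  ed$v[a, ] <- m
  ed$f_alive[shared] <- FALSE
  fb <- ed_faces_of(ed, b)
  for (ff in fb) {
    tri <- ed$f[ff, ]
    tri[tri == b] <- a
    ed$f[ff, ] <- tri
    ed$vf[[a]] <- c(ed$vf[[a]], ff)
  }
  ed$v_alive[b] <- FALSE
  ed$vf[[b]] <- integer(0)
  TRUE
}

# Split edge (a,b) at its midpoint; each incident face becomes two.
ed_split <- function(ed, a, b) {
  shared <- ed_shared_faces(ed, a, b)
  if (length(shared) != 2L) return(FALSE)
  m <- ed_add_vertex(ed, (ed$v[a, ] + ed$v[b, ]) / 2)
  for (ff in shared) {
    tri <- ed$f[ff, ]
    ia <- which(tri == a)
    nxt <- tri[ia %% 3L + 1L]
    ed$f_alive[ff] <- FALSE
    third <- tri[tri != a & tri != b][1L]
    if (nxt == b) { # cyclic order a -> b
      ed_add_face(ed, c(a, m, third))
      ed_add_face(ed, c(m, b, third))
    } else {        # cyclic order b -> a
      ed_add_face(ed, c(b, m, third))
      ed_add_face(ed, c(m, a, third))
    }
  }
  TRUE
}

# Flip edge (a,b) to the opposite diagonal if it improves vertex valences.
ed_flip <- function(ed, a, b) {
  shared <- ed_shared_faces(ed, a, b)
  if (length(shared) != 2L) return(FALSE)
  # orient: f1 contains a->b cyclically
  tri1 <- ed$f[shared[1L], ]
  ia <- which(tri1 == a)
  if (tri1[ia %% 3L + 1L] != b) shared <- rev(shared)
  t1 <- ed$f[shared[1L], ]; t2 <- ed$f[shared[2L], ]
  c_v <- t1[t1 != a & t1 != b][1L]
  d_v <- t2[t2 != a & t2 != b][1L]
  if (c_v == d_v) return(FALSE)
  if (d_v %in% ed_neighbors(ed, c_v)) return(FALSE) # edge already exists
  val <- function(v) length(ed_neighbors(ed, v))
  dev_before <- (val(a) - 6L)^2 + (val(b) - 6L)^2 +
    (val(c_v) - 6L)^2 + (val(d_v) - 6L)^2
  dev_after <- (val(a) - 7L)^2 + (val(b) - 7L)^2 +
    (val(c_v) - 5L)^2 + (val(d_v) - 5L)^2
  if (dev_after >= dev_before) return(FALSE)
  o1 <- tri_normal_area(ed$v[a, ], ed$v[b, ], ed$v[c_v, ])
  o2 <- tri_normal_area(ed$v[b, ], ed$v[a, ], ed$v[d_v, ])
  ref <- o1$normal + o2$normal
  n1 <- tri_normal_area(ed$v[a, ], ed$v[d_v, ], ed$v[c_v, ])
  n2 <- tri_normal_area(ed$v[d_v, ], ed$v[b, ], ed$v[c_v, ])
  if (n1$area2 <= 1e-12 || n2$area2 <= 1e-12) return(FALSE)
  if (sum(n1$normal * ref) <= 0 || sum(n2$normal * ref) <= 0) return(FALSE)
  ed$f_alive[shared] <- FALSE
  ed_add_face(ed, c(a, d_v, c_v))
  ed_add_face(ed, c(d_v, b, c_v))
  TRUE
}

ed_edges <- function(ed) {
  f <- ed$f[ed$f_alive, , drop = FALSE]
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e[, 1L] * (nrow(ed$v) + 1) + e[, 2L]), , drop = FALSE]
}

ed_vertex_count <- function(ed) sum(ed$v_alive)

ed_to_mesh <- function(ed, id = NULL) {
  keep <- which(ed$v_alive)
  remap <- integer(nrow(ed$v))
  remap[keep] <- seq_along(keep)
  f <- ed$f[ed$f_alive, , drop = FALSE]
  triangle_mesh(ed$v[keep, , drop = FALSE],
                matrix(remap[f], ncol = 3L), id = id)
}

edge_lengths <- function(ed, e) {
  row_norms(ed$v[e[, 1L], , drop = FALSE] - ed$v[e[, 2L], , drop = FALSE])
}

# one greedy pass over candidate edges; `op` returns TRUE when applied
greedy_edge_pass <- function(ed, edges, op, stop_at = NULL) {
  touched <- rep(FALSE, nrow(ed$v) + 2L * nrow(edges))
  n_done <- 0L
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    if (a <= length(touched) && touched[a]) next
    if (b <= length(touched) && touched[b]) next
    if (op(a, b)) {
      n_done <- n_done + 1L
      touched[c(a, b)] <- TRUE
      if (!is.null(stop_at) && ed_vertex_count(ed) == stop_at) break
    }
  }
  n_done
}

ed_relax_project <- function(ed, original, lambda = 0.5) {
  alive <- which(ed$v_alive)
  new_pos <- ed$v
  for (vv in alive) {
    nb <- ed_neighbors(ed, vv)
    if (length(nb) >= 3L) {
      cen <- colMeans(ed$v[nb, , drop = FALSE])
      new_pos[vv, ] <- ed$v[vv, ] + lambda * (cen - ed$v[vv, ])
    }
  }
  proj <- closest_on_surface(new_pos[alive, , drop = FALSE], original)
  # reject moves that would fold local triangles
  for (k in seq_along(alive)) {
    vv <- alive[k]
    cand <- proj$points[k, ]
    ok <- TRUE
    for (ff in ed_faces_of(ed, vv)) {
      tri <- ed$f[ff, ]
      old <- tri_normal_area(ed$v[tri[1L], ], ed$v[tri[2L], ], ed$v[tri[3L], ])
      pos <- lapply(tri, function(u) if (u == vv) cand else ed$v[u, ])
      new <- tri_normal_area(pos[[1L]], pos[[2L]], pos[[3L]])
      if (new$area2 <= 1e-12 || sum(new$normal * old$normal) <= 0) {
        ok <- FALSE
        break
      }
    }
    if (ok) ed$v[vv, ] <- cand
  }
  invisible(ed)
}

#' Remesh a surface to a fixed number of near-isotropic vertices
#'
#' Explicit isotropic remeshing in the split/collapse/flip/relax style: edges
#' much longer than the target edge length are split, much shorter ones
#' collapsed, valences equalized by flips, and vertices tangentially relaxed
#' and re-projected onto the input surface. A final pass collapses (or
#' splits) edges one at a time until the vertex count equals
#' `target_vertices` exactly, so corresponded shape vectors downstream are
#' fixed-size.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param target_vertices desired vertex count (default 6000, the working
#'   resolution of the scapula pipeline). Must be >= 4.
#' @param iterations number of split/collapse/flip/relax rounds.
#' @param project if `TRUE`, relax steps re-project vertices onto the input
#'   surface.
#' @return a [triangle_mesh()] with exactly `target_vertices` vertices.
#' @export
remesh_isotropic <- function(mesh, target_vertices = 6000L, iterations = 4L,
                             project = TRUE) {
  if (target_vertices < 4L) {
    stop("target_vertices must be at least 4", call. = FALSE)
  }
  if (!is_closed_mesh(mesh)) {
    stop("remesh_isotropic requires a closed (watertight) mesh", call. = FALSE)
  }
  original <- mesh
  ed <- mesh_editor(mesh)
  area <- sum(face_areas(mesh))
  # equilateral triangles: F ~ 2V, A = F * sqrt(3)/4 * L^2
  target_len <- sqrt(2 * area / (sqrt(3) * target_vertices))
  for (it in seq_len(iterations)) {
    e <- ed_edges(ed)
    len <- edge_lengths(ed, e)
    long <- e[len > 4 / 3 * target_len, , drop = FALSE]
    long <- long[order(-len[len > 4 / 3 * target_len]), , drop = FALSE]
    greedy_edge_pass(ed, long, function(a, b) ed_split(ed, a, b))
    e <- ed_edges(ed)
    len <- edge_lengths(ed, e)
    short <- e[len < 0.8 * target_len, , drop = FALSE]
    short <- short[order(len[len < 0.8 * target_len]), , drop = FALSE]
    greedy_edge_pass(ed, short, function(a, b) ed_collapse(ed, a, b),
                     stop_at = max(target_vertices, 4L))
    e <- ed_edges(ed)
    greedy_edge_pass(ed, e, function(a, b) ed_flip(ed, a, b))
    if (project) ed_relax_project(ed, original)
  }
  # exact-count pass
  guard <- 0L
  while (ed_vertex_count(ed) != target_vertices) {
    guard <- guard + 1L
    if (guard > 20L * target_vertices) {
      stop("remeshing failed to reach the requested vertex count",
           call. = FALSE)
    }
    e <- ed_edges(ed)
    len <- edge_lengths(ed, e)
    if (ed_vertex_count(ed) > target_vertices) {
      done <- greedy_edge_pass(ed, e[order(len), , drop = FALSE],
                               function(a, b) ed_collapse(ed, a, b),
                               stop_at = target_vertices)
      if (done == 0L) {
        stop("cannot decimate further: target below what the surface topology allows",
             call. = FALSE)
      }
    } else {
      need <- target_vertices - ed_vertex_count(ed)
      ord <- order(-len)[seq_len(min(need, nrow(e)))]
      greedy_edge_pass(ed, e[ord, , drop = FALSE],
                       function(a, b) ed_split(ed, a, b))
    }
  }
  if (project) ed_relax_project(ed, original, lambda = 0)
  out <- ed_to_mesh(ed, id = mesh$id)
  validate_mesh(out)
  out
}

#' Decimate a closed mesh to an exact vertex count
#'
#' Greedy shortest-edge collapse with manifoldness and fold-over guards;
#' used by the remesher's exact-count stage and by the procedural template
#' generator.
#'
#' @inheritParams remesh_isotropic
#' @return a [triangle_mesh()] with exactly `target_vertices` vertices.
#' @export
decimate_to <- function(mesh, target_vertices) {
  if (target_vertices < 4L) {
    stop("target_vertices must be at least 4", call. = FALSE)
  }
  if (nrow(mesh$vertices) < target_vertices) {
    stop("mesh already has fewer vertices than the target", call. = FALSE)
  }
  ed <- mesh_editor(mesh)
  while (ed_vertex_count(ed) > target_vertices) {
    e <- ed_edges(ed)
    len <- edge_lengths(ed, e)
    done <- greedy_edge_pass(ed, e[order(len), , drop = FALSE],
                             function(a, b) ed_collapse(ed, a, b),
                             stop_at = target_vertices)
    if (done == 0L) {
      stop("cannot decimate further: target below what the surface topology allows",
           call. = FALSE)
    }
  }
  ed_to_mesh(ed, id = mesh$id)
}
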