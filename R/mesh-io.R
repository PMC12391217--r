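#' Read a triangle mesh from PLY, STL or OBJ
#'
#' Minimal readers for the three interchange formats the pipeline consumes.
#' PLY is supported in ASCII and binary-little-endian form, STL in ASCII and
#' binary form, OBJ in ASCII form (vertex/face records; polygonal faces are
#' fan-triangulated). Coordinates are taken to be mm.
#'
#' @param path path to a `.ply`, `.stl` or `.obj` file.
#' @param id identifier stored on the mesh; defaults to the file stem.
#' @return a [triangle_mesh()].
#' @export
load_mesh <- function(path, id = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  id <- id %||% tools::file_path_sans_ext(basename(path))
  mesh <- switch(ext,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    stop("unsupported mesh format '", ext, "' (expected ply, stl or obj)",
         call. = FALSE))
  if (nrow(mesh$vertices) == 0L) stop("empty mesh: ", path, call. = FALSE)
  if (!all(is.finite(mesh$vertices))) {
    stop("mesh contains non-finite vertex coordinates: ", path, call. = FALSE)
  }
  triangle_mesh(mesh$vertices, mesh$faces, id = id)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header", call. = FALSE)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1L]) != "ply") stop("not a PLY file", call. = FALSE)
  fmt_line <- grep("^format", trimws(header), value = TRUE)
  fmt <- strsplit(fmt_line, "\\s+")[[1L]][2L]
  elements <- list()
  cur <- NULL
  for (line in trimws(header)) {
    tok <- strsplit(line, "\\s+")[[1L]]
    if (tok[1L] == "element") {
      cur <- tok[2L]
      elements[[cur]] <- list(count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1L]] <- tok[-1L]
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("PLY file lacks vertex/face elements", call. = FALSE)
  }
  nv <- elements$vertex$count
  nf <- elements$face$count
  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    vprops <- vapply(elements$vertex$props, function(p) p[2L], "")
    vmat <- matrix(as.numeric(unlist(vl)), nv, length(vprops), byrow = TRUE)
    xyz <- match(c("x", "y", "z"), vprops)
    if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z", call. = FALSE)
    vertices <- vmat[, xyz, drop = FALSE]
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(fl, function(tok) {
      n <- as.integer(tok[1L])
      if (n != 3L) stop("non-triangular PLY face", call. = FALSE)
      as.integer(tok[2:4])
    }, integer(3L)))
  } else if (fmt == "binary_little_endian") {
    type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    read_scalar <- function(type) {
      sz <- type_size[[type]]
      if (type %in% c("float", "float32", "double", "float64")) {
        readBin(con, "double", 1L, size = sz, endian = "little")
      } else {
        readBin(con, "integer", 1L, size = sz, endian = "little",
                signed = !(sz < 4L && grepl("^u", type)))
      }
    }
    vprops <- elements$vertex$props
    vertices <- matrix(0, nv, 3L)
    names_v <- vapply(vprops, function(p) p[2L], "")
    for (i in seq_len(nv)) {
      vals <- vapply(vprops, function(p) read_scalar(p[1L]), 0)
      vertices[i, ] <- vals[match(c("x", "y", "z"), names_v)]
    }
    faces <- matrix(0L, nf, 3L)
    fp <- elements$face$props[[1L]]
    for (i in seq_len(nf)) {
      n <- read_scalar(fp[2L])
      if (n != 3L) stop("non-triangular PLY face", call. = FALSE)
      faces[i, ] <- vapply(1:3, function(j) as.integer(read_scalar(fp[3L])), 0L)
    }
  } else {
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  }
  list(vertices = vertices, faces = faces + 1L)
}

read_stl <- function(path) {
  # binary STL: 80-byte header then uint32 triangle count
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80L)
  n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  size <- file.info(path)$size
  is_binary <- !is.na(n_tri) && size == 84 + 50 * n_tri
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    tri <- matrix(0, n_tri * 3L, 3L)
    for (i in seq_len(n_tri)) {
      vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L)
      tri[(i - 1L) * 3L + 1:3, ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    }
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    vx <- grep("^vertex\\s", lines, value = TRUE)
    if (length(vx) == 0L || length(vx) %% 3L != 0L) {
      stop("malformed ASCII STL", call. = FALSE)
    }
    tri <- matrix(as.numeric(unlist(lapply(strsplit(vx, "\\s+"),
                                           function(t) t[2:4]))),
                  ncol = 3L, byrow = TRUE)
  }
  weld_triangle_soup(tri)
}

# STL stores a triangle soup; merge coincident vertices to recover topology.
weld_triangle_soup <- function(tri, tol = 1e-6) {
  key <- apply(round(tri / tol) * tol, 1L, paste, collapse = "|")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  vertices <- tri[uk, , drop = FALSE]
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) {
    stop("malformed OBJ file", call. = FALSE)
  }
  vertices <- matrix(as.numeric(unlist(lapply(strsplit(vl, "\\s+"),
                                              function(t) t[2:4]))),
                     ncol = 3L, byrow = TRUE)
  faces_list <- lapply(strsplit(fl, "\\s+"), function(tok) {
    idx <- as.integer(sub("/.*$", "", tok[-1L]))
    if (length(idx) < 3L) stop("OBJ face with <3 vertices", call. = FALSE)
    # fan-triangulate polygons
    cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  })
  list(vertices = vertices, faces = do.call(rbind, faces_list))
}

#' Write a triangle mesh as ASCII PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param scalar optional per-vertex scalar field written as a `quality`
#'   property (used for distance heat maps).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nv),
              "property float x", "property float y", "property float z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == nv)
    header <- c(header, "property float quality")
  }
  header <- c(header, paste("element face", nf),
              "property list uchar int vertex_indices", "end_header")
  vtxt <- apply(mesh$vertices, 1L, function(r) paste(format(r, digits = 17),
                                                     collapse = " "))
  if (!is.null(scalar)) vtxt <- paste(vtxt, format(scalar, digits = 9))
  ftxt <- apply(mesh$faces - 1L, 1L, function(r) paste(c(3L, r),
                                                       collapse = " "))
  writeLines(c(header, vtxt, ftxt), path)
  invisible(path)
}
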