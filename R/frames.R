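#' ISB body-fixed scapular coordinate frame from skin landmarks
#'
#' Builds the scapular coordinate system recommended by the International
#' Society of Biomechanics from the skin-level landmarks: origin at AA,
#' z-axis the unit vector from TS toward AA, x-axis the unit normal of the
#' AA-TS-AI plane pointing anteriorly (ventrally, away from the thorax for a
#' right scapula), and y = z x x. Expressing both skin and bone landmark
#' coordinates in this frame makes them comparable across subjects and
#' forces six skin coordinates to be structurally zero (x of AA/TS/AI, y of
#' AA/TS, z of AA).
#'
#' The anterior sign of the x-axis is fixed so that the AC landmark, which
#' lies anterior/lateral on a right scapula, has positive x whenever its
#' projection on the plane normal is non-negligible; `flip_x` overrides the
#' automatic choice.
#'
#' @param skin a skin-level [landmark_set()] in the global frame.
#' @param flip_x optional logical forcing the x-axis sign.
#' @return object of class `body_fixed_frame` with `origin` (mm) and `axes`
#'   (3 x 3 rotation, rows = x, y, z unit vectors in global coordinates).
#' @export
build_isb_scapula_frame <- function(skin, flip_x = NULL) {
  if (!inherits(skin, "landmark_set")) {
    stop("skin must be a landmark_set", call. = FALSE)
  }
  if (skin$frame != "global") {
    stop("skin landmarks must be in the global frame", call. = FALSE)
  }
  p <- skin$points
  aa <- p["AA", ]; ts <- p["TS", ]; ai <- p["AI", ]; ac <- p["AC", ]
  v_z <- aa - ts
  if (sqrt(sum(v_z^2)) < 1e-9) {
    stop("AA and TS coincide: frame undefined", call. = FALSE)
  }
  z <- unit(v_z)
  n <- cross3(aa - ts, ai - ts)
  nn <- sqrt(sum(n * n))
  if (nn < 1e-9 * max(sqrt(sum((aa - ts)^2)), 1)) {
    stop("AA, TS, AI are collinear: scapular plane undefined", call. = FALSE)
  }
  x <- n / nn
  if (is.null(flip_x)) {
    proj_ac <- sum((ac - aa) * x)
    if (abs(proj_ac) > 1e-9 && proj_ac < 0) x <- -x
  } else if (isTRUE(flip_x)) {
    x <- -x
  }
  y <- cross3(z, x)
  axes <- rbind(x = x, y = y, z = z)
  colnames(axes) <- c("gx", "gy", "gz")
  structure(list(origin = aa, axes = axes,
                 convention = "ISB scapula (origin AA, z TS->AA, x plane normal anterior, y = z x x)"),
            class = "body_fixed_frame")
}

#' @export
print.body_fixed_frame <- function(x, ...) {
  cat("body_fixed_frame:", x$convention, "\n")
  cat("  origin (mm):", paste(round(x$origin, 3), collapse = ", "), "\n")
  invisible(x)
}

validate_frame <- function(frame) {
  if (!inherits(frame, "body_fixed_frame")) {
    stop("not a body_fixed_frame", call. = FALSE)
  }
  R <- frame$axes
  if (max(abs(R %*% t(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop("frame axes are not a proper rotation", call. = FALSE)
  }
  invisible(frame)
}

#' Transform points or landmark sets into a body-fixed frame
#'
#' Applies `p' = R (p - origin)` where the rows of `R` are the frame axes.
#' The inverse map is [from_body_frame()].
#'
#' @param x a [landmark_set()] (global frame) or an n x 3 matrix of points.
#' @param frame a [build_isb_scapula_frame()] result.
#' @return same type as `x`, coordinates in the body-fixed frame.
#' @export
to_body_frame <- function(x, frame) {
  validate_frame(frame)
  if (inherits(x, "landmark_set")) {
    if (x$frame != "global") {
      stop("landmarks are already in a body-fixed frame", call. = FALSE)
    }
    out <- x
    out$points <- to_body_frame(x$points, frame)
    out$frame <- "body_fixed"
    return(out)
  }
  p <- as_point_matrix(x)
  out <- sweep(p, 2L, frame$origin) %*% t(frame$axes)
  dimnames(out) <- dimnames(p)
  if (!is.null(colnames(out))) colnames(out) <- c("x", "y", "z")
  out
}

#' @rdname to_body_frame
#' @export
from_body_frame <- function(x, frame) {
  validate_frame(frame)
  if (inherits(x, "landmark_set")) {
    if (x$frame != "body_fixed") {
      stop("landmarks are not in a body-fixed frame", call. = FALSE)
    }
    out <- x
    out$points <- from_body_frame(x$points, frame)
    out$frame <- "global"
    return(out)
  }
  p <- as_point_matrix(x)
  out <- p %*% frame$axes + matrix(frame$origin, nrow(p), 3L, byrow = TRUE)
  dimnames(out) <- dimnames(p)
  out
}

# The six skin coordinates forced to zero by the ISB frame construction,
# as (landmark, axis) pairs; the complement defines the free predictors.
structural_zero_coords <- function() {
  data.frame(landmark = c("AA", "AA", "AA", "TS", "TS", "AI"),
             axis = c("x", "y", "z", "x", "y", "x"),
             stringsAsFactors = FALSE)
}

free_skin_coords <- function() {
  data.frame(landmark = c("AC", "AI", "AC", "TS", "AI", "AC"),
             axis = c("x", "y", "y", "z", "z", "z"),
             stringsAsFactors = FALSE)
}
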