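LANDMARK_NAMES <- c("AA", "TS", "AI", "AC")

#' Scapular landmark set
#'
#' Named 3D positions (mm) of the four scapular landmarks used throughout the
#' pipeline: the acromial angle (AA), the root of the scapular spine (TS),
#' the inferior angle (AI) and the acromioclavicular joint (AC), either at
#' bone level (on the bone surface) or at skin level (palpated positions, as
#' in motion capture).
#'
#' @param points 4 x 3 numeric matrix with rownames AA, TS, AI, AC, or a
#'   named list of 3-vectors.
#' @param level `"bone"` or `"skin"`.
#' @param frame `"global"` or `"body_fixed"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, level = c("bone", "skin"),
                         frame = c("global", "body_fixed")) {
  level <- match.arg(level)
  frame <- match.arg(frame)
  if (is.list(points)) {
    points <- do.call(rbind, points[LANDMARK_NAMES])
    rownames(points) <- LANDMARK_NAMES
  }
  points <- as_point_matrix(points, "landmarks")
  if (is.null(rownames(points))) {
    stop("landmark matrix must carry rownames AA, TS, AI, AC", call. = FALSE)
  }
  missing <- setdiff(LANDMARK_NAMES, rownames(points))
  if (length(missing)) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  points <- points[LANDMARK_NAMES, , drop = FALSE]
  if (!all(is.finite(points))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, level = level, frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set (%s level, %s frame) [mm]\n", x$level, x$frame))
  print(round(x$points, 3))
  invisible(x)
}

#' Read landmark sets from CSV or JSON
#'
#' CSV schema: columns `subject_id, level, name, x, y, z` with
#' `level` in bone/skin and `name` in AA/TS/AI/AC, coordinates in mm,
#' global frame. The JSON equivalent is a list of objects with the same
#' fields. Returns a nested list `[[subject_id]][[level]]` of
#' [landmark_set()] objects.
#'
#' @param path CSV or JSON file path.
#' @return nested list of landmark sets keyed by subject id then level.
#' @export
load_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c("subject_id", "level", "name", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("landmark file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (sid in unique(df$subject_id)) {
    for (lv in unique(df$level[df$subject_id == sid])) {
      sub <- df[df$subject_id == sid & df$level == lv, , drop = FALSE]
      missing_lm <- setdiff(LANDMARK_NAMES, sub$name)
      if (length(missing_lm)) {
        stop("subject ", sid, " (", lv, "): missing landmark(s) ",
             paste(missing_lm, collapse = ", "), call. = FALSE)
      }
      pts <- as.matrix(sub[match(LANDMARK_NAMES, sub$name), c("x", "y", "z")])
      rownames(pts) <- LANDMARK_NAMES
      out[[as.character(sid)]][[lv]] <- landmark_set(pts, level = lv)
    }
  }
  out
}

#' Write landmark sets to the standard CSV schema
#' @param landmarks nested list as returned by [load_landmarks()].
#' @param path output CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- list()
  for (sid in names(landmarks)) {
    for (lv in names(landmarks[[sid]])) {
      p <- landmarks[[sid]][[lv]]$points
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, level = lv, name = rownames(p),
        x = p[, 1L], y = p[, 2L], z = p[, 3L], row.names = NULL)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Subject demographics record
#'
#' Demographics used as regression covariates. BMI is always derived from
#' weight and height at construction so it can never disagree with them.
#'
#' @param id subject identifier.
#' @param sex 0 (female) or 1 (male); `"F"`/`"M"` accepted.
#' @param age years, `>= 0`.
#' @param weight kg, `> 0`.
#' @param height m, `> 0`. Values above 3 are rejected as likely cm.
#' @return object of class `subject_record` with derived `bmi` (kg/m^2).
#' @export
subject_record <- function(id, sex, age, weight, height) {
  if (is.character(sex)) {
    sex <- c(F = 0, M = 1)[toupper(sex)]
  }
  sex <- as.numeric(sex)
  if (!sex %in% c(0, 1)) stop("sex must be 0/1 or F/M", call. = FALSE)
  if (!is.finite(age) || age < 0) stop("age must be >= 0", call. = FALSE)
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0 kg",
                                              call. = FALSE)
  if (!is.finite(height) || height <= 0) stop("height must be > 0 m",
                                              call. = FALSE)
  if (height > 3) {
    stop("height ", height, " m fails the sanity range (was it given in cm?)",
         call. = FALSE)
  }
  structure(list(id = as.character(id), sex = sex, age = as.numeric(age),
                 weight = as.numeric(weight), height = as.numeric(height),
                 bmi = as.numeric(weight) / as.numeric(height)^2),
            class = "subject_record")
}

#' Read subject records from CSV
#'
#' Schema: `subject_id, sex, age, weight_kg, height_m` with sex as F/M or
#' 0/1.
#'
#' @param path CSV path.
#' @return named list of [subject_record()] objects.
#' @export
load_subjects <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "sex", "age", "weight_kg", "height_m")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("subject file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    subject_record(df$subject_id[i], df$sex[i], df$age[i],
                   df$weight_kg[i], df$height_m[i])
  })
  names(out) <- as.character(df$subject_id)
  out
}

#' @rdname load_subjects
#' @param subjects named list of [subject_record()]s.
#' @export
write_subjects <- function(subjects, path) {
  df <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$id, sex = s$sex, age = s$age,
               weight_kg = s$weight, height_m = s$height)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
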