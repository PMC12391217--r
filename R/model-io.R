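#' Save and load fitted model containers
#'
#' Serializes the package's model objects (`scapula_ssm`,
#' `skin_to_bone_fit`, `synthetic_cohort`, `scapula_reconstruction`) with
#' R's native RDS format, which round-trips all numeric arrays
#' bit-identically.
#'
#' @param object a model object of one of the classes above.
#' @param path file path (conventionally `.rds`).
#' @return `path` invisibly for `save_model`; the object for `load_model`.
#' @export
save_model <- function(object, path) {
  ok <- c("scapula_ssm", "skin_to_bone_fit", "synthetic_cohort",
          "scapula_reconstruction")
  if (!inherits(object, ok)) {
    stop("save_model expects one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  saveRDS(object, path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  ok <- c("scapula_ssm", "skin_to_bone_fit", "synthetic_cohort",
          "scapula_reconstruction")
  if (!inherits(obj, ok)) {
    stop("file does not contain a recognized model object", call. = FALSE)
  }
  obj
}
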