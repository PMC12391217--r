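#' Reconstruct and score a set of subjects from digitized and predicted
#' bone landmarks
#'
#' For each subject: builds the ISB body-fixed frame from the skin
#' landmarks, assembles the regression predictors, predicts the bone
#' landmarks with the fitted skin-to-bone models, then reconstructs the
#' scapula twice — once targeting the digitized bone landmarks and once the
#' predicted ones — and reports per-landmark L2L errors and the S2S RMSE
#' against the corresponded ground-truth shape.
#'
#' @param model a [build_ssm()] result.
#' @param fit a [fit_skin_to_bone()] result.
#' @param shapes named list of ground-truth corresponded shapes.
#' @param skin,bone named lists of global-frame [landmark_set()]s.
#' @param subjects named list of [subject_record()]s.
#' @param ids subject ids to evaluate (default: all names of `shapes`).
#' @param split label recorded in the output (`"train"` or `"test"`).
#' @param M,population,generations reconstruction settings (see
#'   [reconstruction_problem()]).
#' @param seed base RNG seed; each subject/scenario uses a derived seed.
#' @param predicted_bias optional 4 x 3 matrix (mm) added to the predicted
#'   bone landmarks, used to study sensitivity to landmark error.
#' @return data.frame with one row per subject x scenario: L2L per landmark,
#'   S2S RMSE, and bookkeeping columns.
#' @export
evaluate_reconstructions <- function(model, fit, shapes, skin, bone,
                                     subjects, ids = names(shapes),
                                     split = "test", M = 5L,
                                     population = 30L, generations = 50L,
                                     seed = 1L, predicted_bias = NULL) {
  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    fr <- build_isb_scapula_frame(skin[[id]])
    skin_bf <- to_body_frame(skin[[id]], fr)
    bone_bf <- to_body_frame(bone[[id]], fr)
    preds <- assemble_predictors(skin_bf, subjects[[id]])
    pred_bf <- predict_bone_landmarks(fit, preds)
    if (!is.null(predicted_bias)) {
      pred_bf$points <- pred_bf$points + predicted_bias
    }
    targets <- list(digitized = bone_bf, predicted = pred_bf)
    for (scen in names(targets)) {
      prob <- reconstruction_problem(model, targets[[scen]], M = M,
                                     population = population,
                                     generations = generations)
      rec <- reconstruct(prob, seed = child_seed(seed,
                                                 2L * i + (scen == "predicted")))
      l2l <- l2l_error(rec, targets[[scen]])
      s2s <- s2s_error(rec$mesh, shapes[[id]])$rmse
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, scenario = scen, split = split,
        l2l_AA = l2l[["AA"]], l2l_TS = l2l[["TS"]],
        l2l_AI = l2l[["AI"]], l2l_AC = l2l[["AC"]],
        s2s = s2s, objective = rec$objective_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Seeded 70-30 subject-level split
#'
#' The training/testing division used consistently by the SSM and the
#' regression stage, performed once per cohort at subject level.
#'
#' @param ids character vector of subject ids.
#' @param train_frac training fraction.
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_cohort <- function(ids, train_frac = 0.7, seed = 1L) {
  set.seed(seed)
  n_train <- floor(length(ids) * train_frac)
  tr <- sort(sample(seq_along(ids), n_train))
  list(train = ids[tr], test = ids[-tr])
}
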