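#' Fixed registries: biometric features, emotion labels, games, measures
#'
#' The pipeline operates on a fixed vocabulary: 16 biometric features
#' (4 eye-tracking, 5 digit-tracking, 7 emotion probabilities), two
#' gamified tasks with a fixed challenge count each, and 15 target
#' neuropsychological measures (10 WISC-V subtests plus 5 questionnaire
#' scores). All column orders downstream (binned matrices, construct
#' loadings) follow the order returned here.
#'
#' @param modality one of "multimodal", "eye", "touch", "emotion"
#' @return `biometric_features()`: character vector of feature names, in
#'   the fixed feature-major order used by the binned matrix.
#' @export
biometric_features <- function(modality = c("multimodal", "eye", "touch", "emotion")) {
  modality <- match.arg(modality)
  eye <- c("gaze_angular_distance", "gaze_total_angular_distance",
           "gaze_angular_velocity", "gaze_saccade")
  touch <- c("touch_speed", "touch_area", "touch_distance",
             "touch_duration", "touch_height")
  emo <- paste0("emotion_", emotion_labels())
  switch(modality,
         multimodal = c(eye, touch, emo),
         eye = eye,
         touch = touch,
         emotion = emo)
}

#' @rdname biometric_features
#' @return `emotion_labels()`: the seven emotion class labels, in the
#'   fixed column order of emotion.csv.
#' @export
emotion_labels <- function() {
  c("anger", "disgust", "fear", "happiness", "neutral", "sadness", "surprise")
}

#' @rdname biometric_features
#' @param game one of "Rocket", "Connect"
#' @return `game_challenges()`: integer number of challenges in a game
#'   (11 for Rocket, 6 for Connect).
#' @export
game_challenges <- function(game = c("Rocket", "Connect")) {
  game <- match.arg(game)
  c(Rocket = 11L, Connect = 6L)[[game]]
}

#' @rdname biometric_features
#' @return `target_measures()`: the 15 target measure names (raw-score
#'   registry for participants and norms).
#' @export
target_measures <- function() {
  c(
    # WISC-V subtests
    "block_design", "matrix_reasoning", "digit_span",
    "letter_number_sequencing", "cancellation", "coding", "symbol_search",
    "comprehension", "similarities", "vocabulary",
    # questionnaires
    "hyperactivity_impulsivity", "inattention", "social_problems",
    "achievement", "manual_laterality"
  )
}

# internal: validate a game string (allows lower case on disk)
canonical_game <- function(game) {
  g <- c(rocket = "Rocket", connect = "Connect")[tolower(game)]
  if (any(is.na(g))) {
    stop("unknown game(s): ", paste(unique(game[is.na(g)]), collapse = ", "))
  }
  unname(g)
}
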