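#' Emotion probability series for one challenge
#'
#' Validates per-frame emotion probability vectors (seven classes: anger,
#' disgust, fear, happiness, neutral, sadness, surprise) and exposes them
#' as seven aligned feature series. The classifier producing these
#' probabilities is an upstream input; this package never computes them
#' from video.
#'
#' @param emotions data frame with column `t` plus the seven emotion
#'   columns, each value in [0, 1] (tolerance 1e-6).
#' @param normalise if TRUE each frame is rescaled to sum to 1; frames
#'   already on the simplex are unchanged (no-op within 1e-12). A frame
#'   summing to 0 is an error naming the frame. Default FALSE.
#' @return data frame with columns `feature` (emotion_<label>), `t`,
#'   `value`; zero rows if no frames.
#' @export
load_emotions <- function(emotions, normalise = FALSE) {
  empty <- data.frame(feature = character(), t = numeric(), value = numeric())
  if (is.null(emotions) || nrow(emotions) == 0) return(empty)
  labs <- emotion_labels()
  missing_cols <- setdiff(c("t", labs), names(emotions))
  if (length(missing_cols)) {
    stop("load_emotions: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  p <- as.matrix(emotions[, labs])
  bad <- which(p < -1e-6 | p > 1 + 1e-6, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("load_emotions: probability outside [0, 1] at frame ", bad[1, 1],
         " (", labs[bad[1, 2]], " = ", p[bad[1, , drop = FALSE]], ")")
  }
  p <- pmin(pmax(p, 0), 1)
  if (normalise) {
    s <- rowSums(p)
    if (any(s == 0)) {
      stop("load_emotions: frame ", which(s == 0)[1],
           " has zero probability mass; cannot normalise")
    }
    p <- p / s
  }
  data.frame(
    feature = rep(paste0("emotion_", labs), each = nrow(p)),
    t = rep(emotions$t, length(labs)),
    value = as.vector(p)
  )
}
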