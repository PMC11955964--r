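#' Read and validate a cohort directory
#'
#' A cohort lives in one directory:
#' \preformatted{
#'   cohort/
#'     participants.csv            # participant_id, age, sex, <15 measures>
#'     norms.csv                   # measure, sex, age_lo, age_hi, mean, sd
#'     <participant_id>/
#'       challenges.csv            # game, challenge_index, duration
#'       <game>_<index>/
#'         gaze.csv                # t, dx, dy, dz
#'         touch.csv               # gesture_id, t, x, y
#'         emotion.csv             # t, anger, ..., surprise
#' }
#' All CSVs are comma-separated UTF-8 with '.' decimals and a header row.
#' Timestamps are seconds from challenge start. Gaze directions are unit
#' 3-vectors; vectors within 1e-3 of unit length are renormalised, others
#' rejected. Every file violating a stated invariant is rejected with a
#' located error; nothing is silently coerced.
#'
#' @param path cohort directory.
#' @return an object of class `bm_cohort`: list with `participants`
#'   (data frame), `norms` (data frame or NULL), and `challenges` (list of
#'   challenge records sorted by participant, game, challenge index; each
#'   a list with `participant_id`, `game`, `challenge_index`, `duration`,
#'   `gaze`, `touch`, `emotions`).
#' @export
read_cohort <- function(path) {
  stopifnot(dir.exists(path))
  pfile <- file.path(path, "participants.csv")
  if (!file.exists(pfile)) stop("missing file: ", pfile)
  participants <- validate_participants(read_table(pfile))
  nfile <- file.path(path, "norms.csv")
  norms <- if (file.exists(nfile)) validate_norms(read_table(nfile)) else NULL
  challenges <- read_session(path, participants$participant_id)
  structure(list(participants = participants, norms = norms,
                 challenges = challenges),
            class = "bm_cohort")
}

#' @rdname read_cohort
#' @param participant_ids which participant subdirectories to read; by
#'   default every subdirectory containing a challenges.csv.
#' @return `read_session()`: the sorted list of validated challenge
#'   records.
#' @export
read_session <- function(path, participant_ids = NULL) {
  stopifnot(dir.exists(path))
  if (is.null(participant_ids)) {
    subs <- list.dirs(path, recursive = FALSE, full.names = FALSE)
    participant_ids <- subs[file.exists(file.path(path, subs, "challenges.csv"))]
  }
  participant_ids <- sort(as.character(participant_ids))
  out <- list()
  for (pid in participant_ids) {
    pdir <- file.path(path, pid)
    cfile <- file.path(pdir, "challenges.csv")
    if (!file.exists(cfile)) stop("missing file: ", cfile)
    idx <- read_table(cfile)
    idx$game <- canonical_game(idx$game)
    idx <- idx[order(idx$game, idx$challenge_index), , drop = FALSE]
    for (i in seq_len(nrow(idx))) {
      out[[length(out) + 1L]] <- read_challenge(
        pdir, pid, idx$game[i], idx$challenge_index[i], idx$duration[i])
    }
  }
  ord <- order(vapply(out, `[[`, "", "participant_id"),
               vapply(out, `[[`, "", "game"),
               vapply(out, function(x) x$challenge_index, 0))
  out[ord]
}

read_challenge <- function(pdir, pid, game, challenge_index, duration) {
  nmax <- game_challenges(game)
  if (challenge_index < 1 || challenge_index > nmax) {
    stop(sprintf("challenge_index %d out of range [1, %d] for %s (%s)",
                 challenge_index, nmax, game, pid))
  }
  if (!is.finite(duration) || duration <= 0) {
    stop("non-positive challenge duration for ", pid, " ", game, " ",
         challenge_index)
  }
  cdir <- file.path(pdir, sprintf("%s_%02d", tolower(game), challenge_index))
  gfile <- file.path(cdir, "gaze.csv")
  tfile <- file.path(cdir, "touch.csv")
  efile <- file.path(cdir, "emotion.csv")
  for (f in c(gfile, tfile, efile)) {
    if (!file.exists(f)) stop("missing stream file: ", f)
  }
  gaze <- validate_gaze(read_table(gfile), gfile)
  touch <- validate_touch(read_table(tfile), tfile)
  emotions <- validate_emotions(read_table(efile), efile)
  if (nrow(gaze) == 0) warning("empty gaze stream: ", gfile)
  for (s in list(gaze$t, touch$t, emotions$t)) {
    if (length(s) && (min(s) < 0 || max(s) > duration + 1e-9)) {
      stop("stream timestamps outside [0, duration] in ", cdir)
    }
  }
  list(participant_id = pid, game = game,
       challenge_index = as.integer(challenge_index),
       duration = duration, gaze = gaze, touch = touch, emotions = emotions)
}

validate_gaze <- function(gaze, file = "gaze") {
  need <- c("t", "dx", "dy", "dz")
  if (!all(need %in% names(gaze))) stop("bad gaze schema in ", file)
  if (nrow(gaze) == 0) return(gaze)
  bad <- which(diff(gaze$t) <= 0)
  if (length(bad)) {
    stop("non-increasing gaze timestamps in ", file, " at row ", bad[1] + 1L)
  }
  v <- as.matrix(gaze[, c("dx", "dy", "dz")])
  nv <- sqrt(rowSums(v^2))
  off <- which(abs(nv - 1) > 1e-3)
  if (length(off)) {
    stop("gaze direction not unit length in ", file, " at row ", off[1],
         " (|v| = ", signif(nv[off[1]], 6), ")")
  }
  gaze[, c("dx", "dy", "dz")] <- v / nv
  gaze
}

validate_touch <- function(touch, file = "touch") {
  need <- c("gesture_id", "t", "x", "y")
  if (!all(need %in% names(touch))) stop("bad touch schema in ", file)
  if (nrow(touch) == 0) return(touch)
  if (!all(is.finite(touch$x)) || !all(is.finite(touch$y))) {
    stop("non-finite touch coordinates in ", file)
  }
  for (g in split(seq_len(nrow(touch)), touch$gesture_id)) {
    bad <- which(diff(touch$t[g]) < 0)
    if (length(bad)) {
      stop("decreasing touch timestamps in ", file, " at row ", g[bad[1] + 1L])
    }
  }
  touch
}

validate_emotions <- function(emotions, file = "emotion") {
  need <- c("t", emotion_labels())
  if (!all(need %in% names(emotions))) stop("bad emotion schema in ", file)
  if (nrow(emotions) == 0) return(emotions)
  p <- as.matrix(emotions[, emotion_labels()])
  bad <- which(p < -1e-6 | p > 1 + 1e-6, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("emotion probability outside [0, 1] in ", file, " at row ", bad[1, 1])
  }
  emotions
}

validate_participants <- function(p) {
  need <- c("participant_id", "age", "sex")
  if (!all(need %in% names(p))) stop("participants.csv must have ",
                                     paste(need, collapse = ", "))
  if (any(p$age < 7 | p$age > 15)) stop("participant age outside [7, 15]")
  if (!all(p$sex %in% c("girl", "boy"))) stop("sex must be 'girl' or 'boy'")
  extra <- setdiff(names(p), c(need, target_measures()))
  if (length(extra)) {
    stop("unknown measure column(s) in participants.csv: ",
         paste(extra, collapse = ", "))
  }
  p$participant_id <- as.character(p$participant_id)
  p
}

validate_norms <- function(n) {
  need <- c("measure", "sex", "age_lo", "age_hi", "mean", "sd")
  if (!all(need %in% names(n))) stop("norms.csv must have ",
                                     paste(need, collapse = ", "))
  if (any(n$sd <= 0)) stop("norms.csv: sd must be > 0 in every cell")
  bad <- setdiff(unique(n$measure), target_measures())
  if (length(bad)) stop("norms.csv: unknown measure(s): ",
                        paste(bad, collapse = ", "))
  # age bands must partition [7, 15] without overlap, per (measure, sex)
  for (key in split(n, paste(n$measure, n$sex))) {
    key <- key[order(key$age_lo), , drop = FALSE]
    if (key$age_lo[1] > 7 || key$age_hi[nrow(key)] < 15 ||
        (nrow(key) > 1 && any(abs(key$age_lo[-1] - key$age_hi[-nrow(key)]) > 1e-9))) {
      stop("norms.csv: age bands do not partition [7, 15] for ",
           key$measure[1], "/", key$sex[1])
    }
  }
  n
}

#' Write / read a result table as CSV
#'
#' Plain-CSV serialisation used by every pipeline output (feature tables,
#' binned matrices, construct scores, association results, comparison
#' tables). Numeric values round-trip losslessly at 1e-12 relative
#' tolerance through the matching reader.
#'
#' @param rows a data frame; must be non-empty unless `allow_empty`.
#' @param path output file path.
#' @param allow_empty permit writing a header-only CSV.
#' @export
write_table <- function(rows, path, allow_empty = FALSE) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0 && !allow_empty) {
    stop("refusing to write empty table to ", path, " without allow_empty")
  }
  num <- vapply(rows, is.numeric, TRUE)
  rows[num] <- lapply(rows[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop("cannot write table to ", path)
  invisible(NULL)
}

#' @rdname write_table
#' @return `read_table()`: the data frame read from `path`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @export
print.bm_cohort <- function(x, ...) {
  cat("<bm_cohort> ", nrow(x$participants), " participants, ",
      length(x$challenges), " challenges",
      if (!is.null(x$norms)) ", with norms" else "", "\n", sep = "")
  invisible(x)
}
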