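#' I-VT configuration
#'
#' Parameters for velocity-threshold identification (I-VT) of fixations
#' and saccades. Intervals with point-to-point angular velocity strictly
#' below `velocity_threshold` are fixations; intervals at or above it are
#' saccades. Fixation events shorter than `min_fixation_duration` are
#' relabelled "undefined" and excluded from fixation counts.
#'
#' @param velocity_threshold degrees per second; default 100.
#' @param min_fixation_duration seconds; default 0.070 (70 ms).
#' @return an object of class `ivt_config`.
#' @export
ivt_config <- function(velocity_threshold = 100, min_fixation_duration = 0.070) {
  stopifnot(is.numeric(velocity_threshold), length(velocity_threshold) == 1,
            velocity_threshold > 0,
            is.numeric(min_fixation_duration), length(min_fixation_duration) == 1,
            min_fixation_duration > 0)
  structure(list(velocity_threshold = velocity_threshold,
                 min_fixation_duration = min_fixation_duration),
            class = "ivt_config")
}

#' Angular distance between two gaze directions
#'
#' The angle arccos(a.b / (|a||b|)) between two 3-vectors, in degrees,
#' clamped to [0, 180]. Symmetric in its arguments. Inputs need not be
#' exactly unit length; they are normalised internally.
#'
#' @param a,b numeric 3-vectors (nonzero).
#' @return angle in degrees.
#' @export
angular_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3, is.finite(a), is.finite(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("angular_distance: zero vector")
  cosang <- sum(a * b) / (na * nb)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Per-interval gaze kinematics
#'
#' Computes, for each pair of consecutive gaze samples, the angular
#' distance alpha (degrees), angular velocity alpha / dt (degrees/s) and
#' the running total angular distance (degrees). Interval timestamps are
#' the midpoints of the sample pair.
#'
#' @param gaze data frame with columns `t`, `dx`, `dy`, `dz`: strictly
#'   increasing timestamps (seconds) and gaze direction vectors.
#' @return an object of class `gaze_kinematics`: data frame with columns
#'   `t` (interval midpoint), `t0`, `t1`, `angular_distance`,
#'   `angular_velocity`, `total_angular_distance`.
#' @export
gaze_kinematics <- function(gaze) {
  stopifnot(is.data.frame(gaze), all(c("t", "dx", "dy", "dz") %in% names(gaze)))
  n <- nrow(gaze)
  if (n < 2) stop("gaze_kinematics: need at least 2 samples")
  t <- gaze$t
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("gaze_kinematics: non-increasing timestamps at row ",
         which(dt <= 0)[1] + 1L)
  }
  v <- as.matrix(gaze[, c("dx", "dy", "dz")])
  nv <- sqrt(rowSums(v^2))
  if (any(nv == 0)) stop("gaze_kinematics: zero direction vector")
  v <- v / nv
  cosang <- rowSums(v[-n, , drop = FALSE] * v[-1, , drop = FALSE])
  cosang <- pmin(1, pmax(-1, cosang))
  alpha <- acos(cosang) * 180 / pi
  out <- data.frame(
    t = (t[-n] + t[-1]) / 2,
    t0 = t[-n],
    t1 = t[-1],
    angular_distance = alpha,
    angular_velocity = alpha / dt,
    total_angular_distance = cumsum(abs(alpha))
  )
  class(out) <- c("gaze_kinematics", "data.frame")
  out
}

#' I-VT fixation/saccade classification
#'
#' Labels each inter-sample interval as "saccade" (velocity at or above
#' the threshold) or "fixation" (strictly below), merges consecutive
#' same-label intervals into events, and relabels fixation events shorter
#' than the minimum fixation duration as "undefined". Ties at the
#' threshold classify as saccade, since fixations are defined by
#' velocities strictly below it.
#'
#' @param kin a `gaze_kinematics` data frame (from [gaze_kinematics()]).
#' @param config an [ivt_config()].
#' @return list with `intervals` (the input plus a `label` column) and
#'   `events` (data frame: `type`, `start`, `end`, `duration`), where
#'   event boundaries are sample timestamps.
#' @export
ivt_classify <- function(kin, config = ivt_config()) {
  stopifnot(inherits(config, "ivt_config"),
            is.data.frame(kin),
            all(c("t0", "t1", "angular_velocity") %in% names(kin)))
  lab <- ifelse(kin$angular_velocity >= config$velocity_threshold,
                "saccade", "fixation")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_start <- kin$t0[starts]
  ev_end <- kin$t1[ends]
  ev_dur <- ev_end - ev_start
  type <- r$values
  short_fix <- type == "fixation" & ev_dur < config$min_fixation_duration
  type[short_fix] <- "undefined"
  for (i in which(short_fix)) lab[starts[i]:ends[i]] <- "undefined"
  kin$label <- lab
  list(
    intervals = kin,
    events = data.frame(type = type, start = ev_start, end = ev_end,
                        duration = ev_dur)
  )
}

#' Eye-tracking feature series for one challenge
#'
#' Runs kinematics and I-VT on a challenge's gaze samples and returns the
#' four eye-tracking features as long-format series indexed by interval
#' midpoint time: per-interval angular distance, running total angular
#' distance, angular velocity, and the saccade indicator (1 = saccade,
#' 0 = fixation, NA = undefined).
#'
#' @param gaze gaze sample data frame (`t`, `dx`, `dy`, `dz`).
#' @param config an [ivt_config()].
#' @return data frame with columns `feature`, `t`, `value`; zero rows if
#'   fewer than 2 gaze samples.
#' @export
gaze_features <- function(gaze, config = ivt_config()) {
  if (is.null(gaze) || nrow(gaze) < 2) {
    return(data.frame(feature = character(), t = numeric(), value = numeric()))
  }
  kin <- gaze_kinematics(gaze)
  cls <- ivt_classify(kin, config)
  sacc <- ifelse(cls$intervals$label == "undefined", NA_real_,
                 as.numeric(cls$intervals$label == "saccade"))
  data.frame(
    feature = rep(c("gaze_angular_distance", "gaze_total_angular_distance",
                    "gaze_angular_velocity", "gaze_saccade"),
                  each = nrow(kin)),
    t = rep(kin$t, 4),
    value = c(kin$angular_distance, kin$total_angular_distance,
              kin$angular_velocity, sacc)
  )
}
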