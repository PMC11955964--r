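#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The generator emulates
#' the statistical structure the analysis assumes — it does not claim
#' behavioural realism. Each participant carries three latent
#' session-level factors (oculomotor, motor, arousal; standard normal)
#' which drive, respectively, the gaze saccade rate/amplitude, the touch
#' gesture speed/extent, and the emotion-simplex concentration; raw
#' assessment scores are the age/sex normative mean plus a linear
#' combination of the latents (on the normative-sd scale) plus Gaussian
#' noise, so downstream association models have a known ground truth.
#'
#' @param n_participants cohort size (default 24, the study cohort).
#' @param n_reference reference cohort size for the PCA fit (default 63).
#' @param seed RNG seed.
#' @param gaze_rate gaze/emotion sampling rate, Hz (default 28).
#' @param touch_rate touch sampling rate, Hz (default 100).
#' @param fixation_dwell mean fixation duration, seconds (default 0.35).
#' @param saccade_amplitude mean saccade amplitude, degrees (default 12;
#'   amplitudes are floored at 9.5 degrees so every saccade crosses the
#'   default 100 degrees/s detection threshold at 28 Hz sampling).
#' @param saccade_peak_velocity mean saccade peak velocity, degrees/s
#'   (default 400; must exceed the I-VT threshold used downstream).
#' @param fixation_jitter per-sample fixation jitter sd, degrees
#'   (default 0.25; set 0 for noise-free traces).
#' @param touch_speed mean gesture drawing speed, pixels/s (default 600).
#' @param gesture_rate gestures per second of challenge (default 0.4).
#' @param latent_loadings named list: measure -> length-3 coefficient
#'   vector over (oculomotor, motor, arousal), on the z-score scale.
#'   Default: moderate loadings cycling measures over the three factors.
#' @param noise_sd residual sd of the scores on the z scale (default 0.6).
#' @param challenge_effect_sd sd of per-challenge random stream shifts
#'   (default 0.2, log scale).
#' @param rocket_duration,connect_duration challenge durations, seconds
#'   (defaults 20 and 30).
#' @param age_range sampled participant ages, years (default c(7, 12)).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 24, n_reference = 63, seed = 1,
                       gaze_rate = 28, touch_rate = 100,
                       fixation_dwell = 0.35, saccade_amplitude = 12,
                       saccade_peak_velocity = 400, fixation_jitter = 0.25,
                       touch_speed = 600, gesture_rate = 0.4,
                       latent_loadings = NULL, noise_sd = 0.6,
                       challenge_effect_sd = 0.2,
                       rocket_duration = 20, connect_duration = 30,
                       age_range = c(7, 12)) {
  stopifnot(n_participants >= 2, n_reference >= 3,
            gaze_rate > 0, touch_rate > 0, fixation_dwell > 0,
            saccade_amplitude > 0, saccade_peak_velocity > 100,
            rocket_duration > 0, connect_duration > 0,
            age_range[1] >= 7, age_range[2] <= 15)
  if (is.null(latent_loadings)) latent_loadings <- default_loadings()
  stopifnot(all(names(latent_loadings) %in% target_measures()),
            all(lengths(latent_loadings) == 3))
  structure(list(
    n_participants = n_participants, n_reference = n_reference, seed = seed,
    gaze_rate = gaze_rate, touch_rate = touch_rate,
    fixation_dwell = fixation_dwell, saccade_amplitude = saccade_amplitude,
    saccade_peak_velocity = saccade_peak_velocity,
    fixation_jitter = fixation_jitter, touch_speed = touch_speed,
    gesture_rate = gesture_rate, latent_loadings = latent_loadings,
    noise_sd = noise_sd, challenge_effect_sd = challenge_effect_sd,
    rocket_duration = rocket_duration, connect_duration = connect_duration,
    age_range = age_range
  ), class = "sim_config")
}

default_loadings <- function() {
  ms <- target_measures()
  out <- stats::setNames(vector("list", length(ms)), ms)
  for (i in seq_along(ms)) {
    v <- c(0, 0, 0)
    v[(i - 1) %% 3 + 1] <- 0.5
    v[i %% 3 + 1] <- 0.2
    out[[i]] <- v
  }
  out
}

#' @rdname sim_config
#' @param path YAML file whose keys are `sim_config()` arguments.
#' @return `sim_config_from_yaml()`: the parsed `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$age_range)) args$age_range <- unlist(args$age_range)
  if (!is.null(args$latent_loadings)) {
    args$latent_loadings <- lapply(args$latent_loadings, unlist)
  }
  do.call(sim_config, args)
}

#' Simulate a synthetic normative table
#'
#' Age-band x sex reference means and sds for every target measure.
#' Means increase smoothly and monotonically with age (all slopes
#' positive); sds are strictly positive everywhere. Bands partition
#' [7, 15] as [7,9), [9,11), [11,13), [13,15].
#'
#' @param config a [sim_config()] (only the seed is used).
#' @return normative table data frame: measure, sex, age_lo, age_hi,
#'   mean, sd.
#' @export
simulate_norms <- function(config = sim_config()) {
  set.seed(config$seed %% 2147483647L + 13L)
  ms <- target_measures()
  base <- stats::runif(length(ms), 10, 50)
  slope <- stats::runif(length(ms), 0.8, 2.5)   # per year of age, > 0
  sexoff <- stats::rnorm(length(ms), 0, 0.8)
  sdv <- stats::runif(length(ms), 2, 5)
  bands <- data.frame(age_lo = c(7, 9, 11, 13), age_hi = c(9, 11, 13, 15))
  out <- expand.grid(measure = ms, sex = c("girl", "boy"),
                     band = seq_len(nrow(bands)), stringsAsFactors = FALSE)
  i <- match(out$measure, ms)
  mid <- (bands$age_lo[out$band] + bands$age_hi[out$band]) / 2
  data.frame(
    measure = out$measure, sex = out$sex,
    age_lo = bands$age_lo[out$band], age_hi = bands$age_hi[out$band],
    mean = base[i] + slope[i] * (mid - 7) + ifelse(out$sex == "boy", sexoff[i], 0),
    sd = sdv[i]
  )
}

#' Simulate a cohort with known ground truth
#'
#' Generates a full session-readable cohort: per participant, 11 Rocket
#' and 6 Connect challenges with gaze traces alternating fixations
#' (small-amplitude jitter, velocity far below threshold) and ballistic
#' saccades (raised-cosine velocity profile crossing the threshold),
#' touch gestures as smoothed random polylines, emotion frames from a
#' temporally smoothed Dirichlet whose concentration drifts with the
#' arousal latent, and raw assessment scores tied linearly to the
#' latent factors. Identical config and seed give identical cohorts.
#'
#' @param config a [sim_config()].
#' @param dir optional directory: when given, the cohort is written in
#'   the [read_cohort()] layout together with ground_truth.json.
#' @param n_participants override of `config$n_participants` (used to
#'   generate reference cohorts).
#' @return list with `cohort` (a `bm_cohort`), `ground_truth` (latents,
#'   challenge effects, generating loadings, per-challenge saccade
#'   counts), and `dir` (NULL if not written). The ground truth is never
#'   consumed by the pipeline itself.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL,
                            n_participants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_participants)) n_participants <- config$n_participants
  set.seed(config$seed %% 2147483647L)
  norms <- simulate_norms(config)
  set.seed(config$seed %% 2147483647L)

  pids <- sprintf("P%03d", seq_len(n_participants))
  ages <- round(stats::runif(n_participants, config$age_range[1],
                             config$age_range[2]), 2)
  sexes <- sample(c("girl", "boy"), n_participants, replace = TRUE)
  latents <- matrix(stats::rnorm(n_participants * 3), n_participants, 3,
                    dimnames = list(pids, c("oculomotor", "motor", "arousal")))

  games <- data.frame(
    game = c(rep("Rocket", 11), rep("Connect", 6)),
    challenge_index = c(1:11, 1:6),
    duration = c(rep(config$rocket_duration, 11),
                 rep(config$connect_duration, 6)))
  games$delta <- stats::rnorm(nrow(games), 0, config$challenge_effect_sd)

  challenges <- vector("list", n_participants * nrow(games))
  sacc_counts <- integer(length(challenges))
  k <- 0L
  for (i in seq_len(n_participants)) {
    for (g in seq_len(nrow(games))) {
      k <- k + 1L
      ch <- simulate_challenge(config, latents[i, ], games$delta[g],
                               games$duration[g])
      challenges[[k]] <- list(
        participant_id = pids[i], game = games$game[g],
        challenge_index = games$challenge_index[g],
        duration = games$duration[g],
        gaze = ch$gaze, touch = ch$touch, emotions = ch$emotions)
      sacc_counts[k] <- ch$n_saccades
    }
  }

  # canonical order, matching read_session()
  ord <- order(vapply(challenges, `[[`, "", "participant_id"),
               vapply(challenges, `[[`, "", "game"),
               vapply(challenges, function(x) x$challenge_index, 0L))
  challenges <- challenges[ord]
  sacc_counts <- sacc_counts[ord]

  # raw scores: normative mean for (measure, sex, age band) + loadings
  # on the normative-sd scale + residual noise
  participants <- data.frame(participant_id = pids, age = ages, sex = sexes,
                             stringsAsFactors = FALSE)
  for (m in names(config$latent_loadings)) {
    nm <- norms[norms$measure == m, , drop = FALSE]
    mu <- sd <- numeric(n_participants)
    for (i in seq_len(n_participants)) {
      cell <- nm[nm$sex == sexes[i] & nm$age_lo <= ages[i] &
                   (ages[i] < nm$age_hi | nm$age_hi >= 15), , drop = FALSE]
      mu[i] <- cell$mean[1]; sd[i] <- cell$sd[1]
    }
    lam <- config$latent_loadings[[m]]
    participants[[m]] <- mu + sd * (as.vector(latents %*% lam) +
                                      stats::rnorm(n_participants, 0, config$noise_sd))
  }

  cohort <- structure(list(participants = participants, norms = norms,
                           challenges = challenges), class = "bm_cohort")
  ground_truth <- list(
    latents = latents,
    challenge_effects = games[, c("game", "challenge_index", "delta")],
    loadings = config$latent_loadings,
    saccade_counts = data.frame(
      participant_id = vapply(challenges, `[[`, "", "participant_id"),
      game = vapply(challenges, `[[`, "", "game"),
      challenge_index = vapply(challenges, function(x) x$challenge_index, 0L),
      n_saccades = sacc_counts),
    seed = config$seed)
  if (!is.null(dir)) write_cohort(cohort, ground_truth, dir)
  list(cohort = cohort, ground_truth = ground_truth, dir = dir)
}

#' @rdname simulate_cohort
#' @return `simulate_reference()`: same structure, with
#'   `config$n_reference` participants, no latent effect on the scores
#'   (reference children are norm-typical), and an independent seed
#'   stream derived from the config seed.
#' @export
simulate_reference <- function(config = sim_config()) {
  ref_cfg <- config
  ref_cfg$seed <- (config$seed + 77777L) %% 2147483647L
  simulate_cohort(ref_cfg, n_participants = config$n_reference)
}

# one challenge's three streams; returns generator bookkeeping too
simulate_challenge <- function(config, latent, delta, duration) {
  g <- simulate_gaze(config, latent[["oculomotor"]], delta, duration)
  list(gaze = g$gaze, n_saccades = g$n_saccades,
       touch = simulate_touch(config, latent[["motor"]], delta, duration),
       emotions = simulate_emotions(config, latent[["arousal"]], delta, duration))
}

# alternating fixations and raised-cosine saccades in (yaw, pitch) degrees
simulate_gaze <- function(config, l_eye, delta, duration) {
  dt <- 1 / config$gaze_rate
  tt <- seq(0, duration, by = dt)
  yaw <- pitch <- numeric(length(tt))
  dwell <- config$fixation_dwell / exp(0.3 * l_eye + delta)
  amp_mult <- exp(0.2 * l_eye + delta)
  pos <- c(stats::runif(1, -10, 10), stats::runif(1, -8, 8))
  tcur <- 0; n_sacc <- 0L
  jit <- config$fixation_jitter
  while (tcur < duration) {
    fdur <- max(0.15, stats::rgamma(1, shape = 4, scale = dwell / 4))
    fend <- tcur + fdur
    in_fix <- if (fend >= duration) which(tt >= tcur) else
      which(tt >= tcur & tt < fend)
    if (length(in_fix)) {
      steps <- cbind(stats::rnorm(length(in_fix), 0, jit),
                     stats::rnorm(length(in_fix), 0, jit))
      wob <- apply(steps, 2, cumsum)
      wob <- sweep(matrix(wob, ncol = 2), 2, colMeans(matrix(wob, ncol = 2)))
      yaw[in_fix] <- pos[1] + wob[, 1]
      pitch[in_fix] <- pos[2] + wob[, 2]
    }
    tcur <- tcur + fdur
    if (tcur >= duration) break
    # saccade: amplitude floored so one sampling interval always crosses
    # the 100 deg/s threshold at 28 Hz
    amp <- max(9.5, stats::rnorm(1, config$saccade_amplitude * amp_mult,
                                 config$saccade_amplitude * 0.1))
    vp <- max(300, stats::rnorm(1, config$saccade_peak_velocity,
                                config$saccade_peak_velocity * 0.05))
    sdur <- 2 * amp / vp
    if (tcur + sdur + 0.15 >= duration) {   # no truncated saccades
      in_tail <- which(tt >= tcur)
      yaw[in_tail] <- pos[1]; pitch[in_tail] <- pos[2]
      break
    }
    # direction: centre-biased so the trace stays in the camera frustum
    ang <- atan2(-pos[2] * 0.15 + stats::rnorm(1),
                 -pos[1] * 0.15 + stats::rnorm(1))
    target <- pos + amp * c(cos(ang), sin(ang))
    in_sac <- which(tt >= tcur & tt < tcur + sdur)
    if (length(in_sac)) {
      tau <- (tt[in_sac] - tcur) / sdur
      s <- tau - sin(2 * pi * tau) / (2 * pi)   # integral of raised cosine
      yaw[in_sac] <- pos[1] + (target[1] - pos[1]) * s
      pitch[in_sac] <- pos[2] + (target[2] - pos[2]) * s
    }
    pos <- target
    tcur <- tcur + sdur
    n_sacc <- n_sacc + 1L
  }
  yr <- yaw * pi / 180; pr <- pitch * pi / 180
  gaze <- data.frame(t = tt,
                     dx = sin(yr) * cos(pr),
                     dy = sin(pr),
                     dz = cos(yr) * cos(pr))
  list(gaze = gaze, n_saccades = n_sacc)
}

# smoothed random polylines; speed/extent scale with the motor latent
simulate_touch <- function(config, l_motor, delta, duration) {
  n_g <- max(1L, stats::rpois(1, config$gesture_rate * duration))
  speed <- config$touch_speed * exp(0.3 * l_motor + delta)
  starts <- sort(stats::runif(n_g, 0, duration * 0.9))
  rows <- list()
  for (g in seq_len(n_g)) {
    upper <- max(0.15, min(1.2, duration - starts[g]))
    gdur <- stats::runif(1, min(0.1, upper), upper)
    tg <- seq(0, gdur, by = 1 / config$touch_rate)
    heading <- stats::runif(1, 0, 2 * pi) +
      cumsum(stats::rnorm(length(tg), 0, 0.25))
    step <- speed / config$touch_rate
    x <- 960 + cumsum(step * cos(heading)); x <- x - x[1] +
      stats::runif(1, 200, 1700)
    y <- 540 + cumsum(step * sin(heading)); y <- y - y[1] +
      stats::runif(1, 150, 950)
    rows[[g]] <- data.frame(gesture_id = sprintf("g%02d", g),
                            t = starts[g] + tg, x = x, y = y)
  }
  do.call(rbind, rows)
}

# temporally smoothed Dirichlet; arousal shifts mass off "neutral"
simulate_emotions <- function(config, l_arousal, delta, duration) {
  tt <- seq(0, duration, by = 1 / config$gaze_rate)
  alpha <- c(anger = 1, disgust = 0.8, fear = 0.8, happiness = 2,
             neutral = 6, sadness = 1, surprise = 1.2)
  act <- exp(0.5 * l_arousal + delta)
  alpha[c("anger", "happiness", "surprise")] <-
    alpha[c("anger", "happiness", "surprise")] * act
  alpha["neutral"] <- alpha["neutral"] / act
  n <- length(tt)
  draws <- matrix(stats::rgamma(n * 7, shape = rep(alpha, each = n)), n, 7)
  draws <- draws / rowSums(draws)
  p <- draws
  for (i in 2:n) p[i, ] <- 0.8 * p[i - 1, ] + 0.2 * draws[i, ]
  colnames(p) <- emotion_labels()
  cbind(data.frame(t = tt), as.data.frame(p))
}

#' Write a simulated cohort to disk
#'
#' Writes the [read_cohort()] layout plus ground_truth.json at the
#' cohort root. Deterministic: the same cohort always produces
#' byte-identical files.
#'
#' @param cohort a `bm_cohort`.
#' @param ground_truth the generator's bookkeeping (or NULL to skip).
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, ground_truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(cohort$participants, file.path(dir, "participants.csv"))
  if (!is.null(cohort$norms)) {
    write_table(cohort$norms, file.path(dir, "norms.csv"))
  }
  for (ch in cohort$challenges) {
    pdir <- file.path(dir, ch$participant_id)
    cdir <- file.path(pdir, sprintf("%s_%02d", tolower(ch$game),
                                    ch$challenge_index))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    write_table(ch$gaze, file.path(cdir, "gaze.csv"), allow_empty = TRUE)
    write_table(ch$touch, file.path(cdir, "touch.csv"), allow_empty = TRUE)
    write_table(ch$emotions, file.path(cdir, "emotion.csv"),
                allow_empty = TRUE)
  }
  idx <- data.frame(
    participant_id = vapply(cohort$challenges, `[[`, "", "participant_id"),
    game = vapply(cohort$challenges, `[[`, "", "game"),
    challenge_index = vapply(cohort$challenges,
                             function(x) x$challenge_index, 0L),
    duration = vapply(cohort$challenges, function(x) x$duration, 0))
  for (pid in unique(idx$participant_id)) {
    sub <- idx[idx$participant_id == pid,
               c("game", "challenge_index", "duration")]
    write_table(sub, file.path(dir, pid, "challenges.csv"))
  }
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    gt$latents <- cbind(data.frame(participant_id = rownames(gt$latents)),
                        as.data.frame(gt$latents))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(NULL)
}
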