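#' Causal moving-average smoothing
#'
#' Averages each observation with the preceding `window - 1` observations
#' (fewer at the head of the series). `window = 1` is the identity. This
#' realises the moving-average treatment of the feature time series;
#' smoothing is off by default throughout the pipeline.
#'
#' @param values numeric vector in time order.
#' @param window number of past observations to average (>= 1).
#' @return smoothed numeric vector, same length.
#' @export
smooth_series <- function(values, window = 1) {
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    stop("smooth_series: window must be >= 1")
  }
  window <- as.integer(window)
  if (window == 1 || length(values) <= 1) return(values)
  n <- length(values)
  cs <- cumsum(c(0, values))
  lo <- pmax(0, seq_len(n) - window)
  (cs[seq_len(n) + 1] - cs[lo + 1]) / (seq_len(n) - lo)
}

#' Bin one feature series into equal-width time bins
#'
#' Divides [0, duration] into `n_bins` equal-width bins (half-open
#' [lo, hi), final bin closed) and averages the observations falling in
#' each. Empty interior bins are filled by linear interpolation between
#' the nearest non-empty bins; empty leading/trailing bins carry the
#' nearest non-empty value. NA observations are dropped first. An
#' all-empty series yields all-NA values with every bin flagged missing.
#'
#' @param t observation timestamps (seconds in [0, duration]).
#' @param values observation values.
#' @param duration challenge duration in seconds (> 0).
#' @param n_bins number of bins (default 100).
#' @return list with `values` (length `n_bins`) and `missing` (logical:
#'   bin had no observation before filling).
#' @export
bin_series <- function(t, values, duration, n_bins = 100) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("bin_series: duration must be positive")
  }
  stopifnot(length(t) == length(values), n_bins >= 1)
  keep <- is.finite(t) & !is.na(values)
  t <- t[keep]; values <- values[keep]
  if (length(t) == 0) {
    return(list(values = rep(NA_real_, n_bins), missing = rep(TRUE, n_bins)))
  }
  idx <- pmin(n_bins, pmax(1L, floor(t / duration * n_bins) + 1L))
  sums <- rep(0, n_bins); cnt <- rep(0L, n_bins)
  agg <- rowsum(values, idx)
  ii <- as.integer(rownames(agg))
  sums[ii] <- agg[, 1]
  cnt[ii] <- tabulate(idx, nbins = n_bins)[ii]
  missing <- cnt == 0
  v <- ifelse(missing, NA_real_, sums / pmax(cnt, 1L))
  filled <- which(!missing)
  if (length(filled) < n_bins) {
    v <- stats::approx(filled, v[filled], xout = seq_len(n_bins),
                       method = if (length(filled) == 1) "constant" else "linear",
                       rule = 2)$y
  }
  list(values = v, missing = missing)
}

# per-challenge long-format feature table: gaze + touch + emotion
challenge_features <- function(ch, config = ivt_config(),
                               normalise_emotions = FALSE, smooth_window = 1) {
  fx <- rbind(
    gaze_features(ch$gaze, config),
    aggregate_touch(ch$touch),
    load_emotions(ch$emotions, normalise = normalise_emotions)
  )
  if (smooth_window > 1 && nrow(fx)) {
    fx <- do.call(rbind, lapply(split(fx, fx$feature), function(d) {
      d <- d[order(d$t), , drop = FALSE]
      d$value <- smooth_series(d$value, smooth_window)
      d
    }))
    rownames(fx) <- NULL
  }
  fx
}

#' Assemble the binned feature matrix for one game
#'
#' One row per (participant, challenge) of the chosen game; columns are
#' feature x bin in fixed feature-major order (all 100 bins of feature 1,
#' then feature 2, ...). Feature counts per modality set: eye 4, touch 5,
#' emotion 7, multimodal 16, so a multimodal matrix has 1600 columns.
#' A participant missing a challenge contributes an all-missing row with
#' a warning. Row order is canonical (participant, challenge index)
#' regardless of input order.
#'
#' @param cohort a `bm_cohort` (see [read_cohort()], [simulate_cohort()]).
#' @param game "Rocket" or "Connect".
#' @param modality one of "multimodal", "eye", "touch", "emotion".
#' @param config an [ivt_config()] for the eye features.
#' @param n_bins bins per feature (default 100).
#' @param normalise_emotions passed to [load_emotions()].
#' @param smooth_window causal moving-average window (1 = off).
#' @return object of class `binned_matrix`: list with `values` (numeric
#'   matrix), `missing` (logical matrix), `rows` (data frame:
#'   participant_id, game, challenge_index), `features`, `n_bins`.
#' @export
assemble_matrix <- function(cohort, game, modality = "multimodal",
                            config = ivt_config(), n_bins = 100,
                            normalise_emotions = FALSE, smooth_window = 1) {
  game <- canonical_game(game)
  feats <- biometric_features(modality)
  pids <- sort(unique(vapply(cohort$challenges, `[[`, "", "participant_id")))
  nch <- game_challenges(game)
  keys <- expand.grid(challenge_index = seq_len(nch), participant_id = pids,
                      stringsAsFactors = FALSE)
  keys <- keys[order(keys$participant_id, keys$challenge_index), c(2, 1)]
  rownames(keys) <- NULL
  chmap <- new.env(parent = emptyenv())
  for (ch in cohort$challenges) {
    if (ch$game == game) {
      assign(paste(ch$participant_id, ch$challenge_index), ch, envir = chmap)
    }
  }
  p <- length(feats) * n_bins
  vals <- matrix(NA_real_, nrow(keys), p)
  miss <- matrix(TRUE, nrow(keys), p)
  colnames(vals) <- colnames(miss) <-
    paste0(rep(feats, each = n_bins), "_bin", sprintf("%03d", seq_len(n_bins)))
  for (i in seq_len(nrow(keys))) {
    key <- paste(keys$participant_id[i], keys$challenge_index[i])
    if (!exists(key, envir = chmap)) {
      warning("participant ", keys$participant_id[i], " missing ", game,
              " challenge ", keys$challenge_index[i], "; all-missing row")
      next
    }
    ch <- get(key, envir = chmap)
    fx <- challenge_features(ch, config, normalise_emotions, smooth_window)
    for (j in seq_along(feats)) {
      sel <- fx$feature == feats[j]
      b <- bin_series(fx$t[sel], fx$value[sel], ch$duration, n_bins)
      cols <- ((j - 1) * n_bins + 1):(j * n_bins)
      vals[i, cols] <- b$values
      miss[i, cols] <- b$missing
    }
  }
  structure(list(values = vals, missing = miss,
                 rows = cbind(keys[, "participant_id", drop = FALSE],
                              game = game,
                              keys[, "challenge_index", drop = FALSE]),
                 features = feats, n_bins = n_bins),
            class = "binned_matrix")
}

#' Restrict a binned matrix to one modality's features
#'
#' Columns of a modality are contiguous in the feature-major layout, so
#' a unimodal matrix is an exact column slice of the multimodal one.
#'
#' @param bm a multimodal `binned_matrix`.
#' @param modality "eye", "touch", "emotion" (or "multimodal", identity).
#' @return the sliced `binned_matrix`.
#' @export
subset_modality <- function(bm, modality) {
  stopifnot(inherits(bm, "binned_matrix"))
  feats <- biometric_features(modality)
  if (!all(feats %in% bm$features)) {
    stop("subset_modality: matrix lacks features of modality ", modality)
  }
  cols <- as.vector(vapply(feats, function(f) {
    which(bm$features == f) * bm$n_bins - bm$n_bins + seq_len(bm$n_bins)
  }, numeric(bm$n_bins)))
  bm$values <- bm$values[, cols, drop = FALSE]
  bm$missing <- bm$missing[, cols, drop = FALSE]
  bm$features <- feats
  bm
}

#' Fit the reference construct model (PCA with eigenvector transfer)
#'
#' Fits a PCA on a reference cohort's binned matrix: missing cells are
#' imputed by column mean, columns standardised to mean 0 / sd 1
#' (zero-variance columns dropped and recorded), and the top
#' `n_components` eigenvectors retained with a deterministic sign
#' convention (the largest-magnitude loading of each component is
#' positive). The stored means/sds/eigenvectors are later applied
#' unchanged to a target cohort, so no target statistic ever enters the
#' standardisation or the rotation.
#'
#' @param bm a `binned_matrix` from the reference cohort.
#' @param n_components components to retain (default 3, the headline
#'   biometric constructs).
#' @return object of class `construct_model`: list with `columns`
#'   (kept column names), `dropped` (zero-variance columns), `means`,
#'   `sds`, `rotation` (columns x components), `explained_variance`
#'   (ratios, non-increasing), `component_variance`, `n_components`,
#'   `modality` feature set.
#' @export
fit_reference <- function(bm, n_components = 3) {
  stopifnot(inherits(bm, "binned_matrix"))
  X <- bm$values
  n <- nrow(X)
  if (n < n_components) stop("fit_reference: fewer rows than components")
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- cm[j]
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 1e-12
  dropped <- colnames(X)[!keep]
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sds[keep], "/")
  sv <- svd(Z, nu = 0, nv = n_components)
  rot <- sv$v
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  rownames(rot) <- colnames(Z)
  colnames(rot) <- paste0("MBC", seq_len(n_components))
  ev <- sv$d^2 / (n - 1)
  structure(list(
    columns = colnames(Z), dropped = dropped,
    means = mu[keep], sds = sds[keep], rotation = rot,
    explained_variance = ev[seq_len(n_components)] / sum(ev),
    component_variance = ev[seq_len(n_components)],
    n_components = n_components, features = bm$features, n_bins = bm$n_bins
  ), class = "construct_model")
}

#' Project a binned matrix onto a fitted construct model
#'
#' Scores = ((X - reference means) / reference sds) %*% eigenvectors.
#' Only the reference model's statistics are used; the target cohort's
#' means and variances never enter. Missing cells are imputed with the
#' reference column means (i.e., contribute 0 after centring). Columns
#' recorded as zero-variance at fit time are ignored; any other mismatch
#' between matrix and model columns is an error.
#'
#' @param model a `construct_model` from [fit_reference()].
#' @param bm a `binned_matrix` with the same feature set.
#' @param modality label recorded in the output (defaults from the
#'   model's feature set).
#' @return a `construct_scores` data frame: participant_id, game,
#'   challenge_index, modality, MBC1..MBCk.
#' @export
project_constructs <- function(model, bm, modality = NULL) {
  stopifnot(inherits(model, "construct_model"), inherits(bm, "binned_matrix"))
  have <- setdiff(colnames(bm$values), model$dropped)
  if (!identical(have, model$columns)) {
    bad <- c(setdiff(model$columns, have), setdiff(have, model$columns))
    stop("project_constructs: column mismatch: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  X <- bm$values[, model$columns, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- model$means[j]
  }
  Z <- sweep(sweep(X, 2, model$means), 2, model$sds, "/")
  scores <- Z %*% model$rotation
  if (is.null(modality)) {
    modality <- if (length(model$features) == 16) "multimodal"
      else if (all(startsWith(model$features, "gaze"))) "eye"
      else if (all(startsWith(model$features, "touch"))) "touch"
      else "emotion"
  }
  out <- cbind(bm$rows, modality = modality, as.data.frame(scores))
  rownames(out) <- NULL
  class(out) <- c("construct_scores", "data.frame")
  out
}

#' Serialise / restore a construct model as JSON
#'
#' @param model a `construct_model`.
#' @param path JSON file path.
#' @export
write_construct_model <- function(model, path) {
  stopifnot(inherits(model, "construct_model"))
  obj <- unclass(model)
  obj$rotation <- as.data.frame(obj$rotation)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' @rdname write_construct_model
#' @return `read_construct_model()`: the restored `construct_model`.
#' @export
read_construct_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- as.matrix(obj$rotation)
  rownames(rot) <- obj$columns
  obj$rotation <- rot
  obj$means <- stats::setNames(as.numeric(obj$means), obj$columns)
  obj$sds <- stats::setNames(as.numeric(obj$sds), obj$columns)
  obj$dropped <- as.character(obj$dropped)
  structure(obj, class = "construct_model")
}

#' @export
print.construct_model <- function(x, ...) {
  cat("<construct_model> ", length(x$columns), " columns, ",
      x$n_components, " components; explained variance ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
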