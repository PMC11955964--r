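#' Mean absolute error of an association model
#'
#' Mean over evaluation rows of |observed z - predicted z|, where the
#' prediction uses the fixed effects plus the estimated challenge
#' effects (BLUPs for the mixed model, indicator coefficients for the
#' robust model). With no `newdata` the model's own rows are used
#' (in-sample MAE, the default throughout the modality comparison).
#'
#' @param fit an `association_fit`.
#' @param newdata optional evaluation rows (must carry the construct and
#'   challenge columns plus `z`).
#' @return the MAE.
#' @export
prediction_mae <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "association_fit"))
  if (is.null(newdata)) {
    d <- fit$data
    pred <- if (is.null(fit$model)) d$z else stats::fitted(fit$model)
  } else {
    if (nrow(newdata) == 0) stop("prediction_mae: empty evaluation set")
    d <- newdata
    pred <- if (inherits(fit$model, "merMod")) {
      stats::predict(fit$model, newdata = d, allow.new.levels = TRUE)
    } else {
      stats::predict(fit$model, newdata = d)
    }
  }
  if (length(d$z) == 0) stop("prediction_mae: empty evaluation set")
  mean(abs(d$z - pred))
}

#' Unimodal vs multimodal model comparison by MAE
#'
#' For every measure, fits one association model per modality set
#' (multimodal, eye, touch, emotion) on constructs built with reference
#' eigenvector transfer, and reports each unimodal model's in-sample MAE
#' as a percent change relative to the multimodal baseline:
#' 100 (MAE_unimodal - MAE_multimodal) / MAE_multimodal. The baseline
#' itself is indexed as 1. Positive values mean the unimodal model
#' predicts worse than the multimodal one.
#'
#' @param cohort target `bm_cohort` (must carry norms and raw scores).
#' @param reference reference `bm_cohort` for the PCA fit.
#' @param game "Rocket" or "Connect".
#' @param measures measures to compare (default: all with raw scores).
#' @param flavour "mixed" (default) or "robust".
#' @param n_components constructs per modality (default 3).
#' @param config an [ivt_config()].
#' @return a `comparison_table` data frame: game, measure, modality,
#'   mae, baseline (1 for the multimodal row), pct_change (exact, 0 at
#'   equality), pct_change_rounded (integer, as printed in reports).
#'   A modality whose features cannot support a construct fit is omitted
#'   with a warning.
#' @export
compare_modalities <- function(cohort, reference, game, measures = NULL,
                               flavour = "mixed", n_components = 3,
                               config = ivt_config()) {
  game <- canonical_game(game)
  if (is.null(measures)) {
    measures <- intersect(target_measures(), names(cohort$participants))
  }
  adjusted <- z_adjust(cohort$participants, cohort$norms, measures)
  fitter <- if (flavour == "mixed") fit_mixed else fit_robust
  modalities <- c("multimodal", "touch", "emotion", "eye")
  ref_all <- assemble_matrix(reference, game, "multimodal", config = config)
  coh_all <- assemble_matrix(cohort, game, "multimodal", config = config)
  scores <- list()
  for (mod in modalities) {
    sc <- tryCatch({
      model <- fit_reference(subset_modality(ref_all, mod), n_components)
      project_constructs(model, subset_modality(coh_all, mod), mod)
    }, error = function(e) {
      warning("omitting modality ", mod, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(sc)) scores[[mod]] <- sc
  }
  if (is.null(scores$multimodal)) stop("multimodal constructs unavailable")
  rows <- list()
  for (m in measures) {
    target <- adjusted[adjusted$measure == m, , drop = FALSE]
    maes <- vapply(scores, function(sc) prediction_mae(fitter(sc, target)),
                   numeric(1))
    base <- maes[["multimodal"]]
    pct <- 100 * (maes - base) / base
    rows[[m]] <- data.frame(
      game = game, measure = m, modality = names(maes), mae = unname(maes),
      baseline = ifelse(names(maes) == "multimodal", 1, NA_real_),
      pct_change = unname(pct),
      pct_change_rounded = as.integer(round(unname(pct))),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Format a comparison table in report layout
#'
#' Wide layout with one row per measure: the multimodal baseline printed
#' as "1" and each unimodal model as its rounded percent change.
#'
#' @param tbl a `comparison_table`.
#' @return character data frame: measure, multimodal, touch, emotion, eye.
#' @export
format_comparison <- function(tbl) {
  ms <- unique(tbl$measure)
  out <- data.frame(measure = ms)
  for (mod in c("multimodal", "touch", "emotion", "eye")) {
    sub <- tbl[tbl$modality == mod, , drop = FALSE]
    col <- if (mod == "multimodal") rep("1", length(ms)) else {
      sprintf("%d%%", sub$pct_change_rounded[match(ms, sub$measure)])
    }
    out[[mod]] <- col
  }
  out
}
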