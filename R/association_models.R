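#' Age- and sex-adjusted z-scores
#'
#' Converts raw assessment scores to z-scores against a normative table:
#' z = (raw - normative mean for the participant's sex and age band) /
#' normative sd. Biometric features are never adjusted; only the target
#' measures are.
#'
#' @param participants participant data frame (participant_id, age, sex,
#'   plus raw measure columns).
#' @param norms normative table (measure, sex, age_lo, age_hi, mean, sd);
#'   bands are half-open [lo, hi), the last band closed at 15.
#' @param measures which measures to adjust (default: every registry
#'   measure present in `participants`).
#' @return long data frame: participant_id, measure, raw, z. Missing raw
#'   scores propagate as NA. A participant whose (measure, sex, age band)
#'   has no normative cell is an error naming the cell.
#' @export
z_adjust <- function(participants, norms, measures = NULL) {
  if (is.null(measures)) {
    measures <- intersect(target_measures(), names(participants))
  }
  out <- vector("list", length(measures))
  for (k in seq_along(measures)) {
    m <- measures[k]
    nm <- norms[norms$measure == m, , drop = FALSE]
    z <- raw <- rep(NA_real_, nrow(participants))
    for (i in seq_len(nrow(participants))) {
      raw[i] <- participants[[m]][i]
      if (is.na(raw[i])) next
      sx <- participants$sex[i]; age <- participants$age[i]
      cell <- nm[nm$sex == sx &
                   nm$age_lo <= age &
                   (age < nm$age_hi | (nm$age_hi >= 15 & age <= nm$age_hi)), ,
                 drop = FALSE]
      if (nrow(cell) == 0) {
        stop("z_adjust: no normative cell for (", m, ", ", sx, ", age ",
             age, ")")
      }
      z[i] <- (raw[i] - cell$mean[1]) / cell$sd[1]
    }
    out[[k]] <- data.frame(participant_id = participants$participant_id,
                           measure = m, raw = raw, z = z)
  }
  do.call(rbind, out)
}

#' Mixed-model association of constructs with one measure
#'
#' Fits `z ~ MBC1 + ... + MBCk + (1 | challenge)` by REML: the gamified
#' task's challenges enter as a random intercept and each biometric
#' construct as a fixed effect. Wald (normal-approximation) p-values are
#' reported per fixed effect, together with variance components, log
#' likelihood, an R-squared (squared correlation of fitted and observed),
#' and residual diagnostics (Shapiro-Wilk normality p; homoscedasticity
#' screened by the Spearman correlation of absolute residuals with fitted
#' values). A singular fit (random-effect variance on the boundary) is
#' flagged, not discarded: with 6-11 challenge levels boundary estimates
#' are expected.
#'
#' @param scores a `construct_scores` data frame for one game/modality.
#' @param target data frame with `participant_id` and `z` for one
#'   measure (e.g. one measure's rows from [z_adjust()]).
#' @return object of class `association_fit`: coefficient table,
#'   variance components, fit statistics, diagnostics and the underlying
#'   model object (used for prediction).
#' @export
fit_mixed <- function(scores, target) {
  d <- merge_scores_target(scores, target)
  comps <- grep("^MBC", names(scores), value = TRUE)
  form <- stats::as.formula(paste("z ~", paste(comps, collapse = " + "),
                                  "+ (1 | challenge)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  stat <- est / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranvar <- vc$vcov[vc$grp == "challenge"]
  resvar <- vc$vcov[vc$grp == "Residual"]
  res <- stats::residuals(fit)
  fitted_v <- stats::fitted(fit)
  structure(list(
    flavour = "mixed",
    coefficients = data.frame(
      term = rownames(co), estimate = unname(est), se = unname(se),
      statistic = unname(stat), p = 2 * stats::pnorm(-abs(unname(stat)))),
    random_variance = if (singular) 0 else ranvar,
    residual_variance = resvar,
    logLik = as.numeric(stats::logLik(fit)),
    r_squared = if (stats::sd(d$z) > 0) stats::cor(fitted_v, d$z)^2 else NA_real_,
    singular = singular,
    diagnostics = residual_diagnostics(res, fitted_v),
    data = d, model = fit
  ), class = "association_fit")
}

#' Robust-regression association of constructs with one measure
#'
#' Huber M-estimation of `z ~ MBC1 + ... + MBCk + challenge indicators`.
#' Because robust mixed models are not standard, challenges enter as
#' fixed indicator terms; this is the robust counterpart of
#' [fit_mixed()]. P-values are two-sided t on n - p residual degrees of
#' freedom. A constant target returns zero construct coefficients.
#'
#' @inheritParams fit_mixed
#' @return an `association_fit` with flavour "robust".
#' @export
fit_robust <- function(scores, target) {
  d <- merge_scores_target(scores, target)
  comps <- grep("^MBC", names(scores), value = TRUE)
  if (stats::sd(d$z) == 0) {
    co <- data.frame(term = c("(Intercept)", comps),
                     estimate = c(d$z[1], rep(0, length(comps))),
                     se = 0, statistic = NA_real_, p = NA_real_)
    return(structure(list(flavour = "robust", coefficients = co,
                          random_variance = 0, residual_variance = 0,
                          logLik = NA_real_, r_squared = NA_real_,
                          singular = FALSE,
                          diagnostics = list(shapiro_p = NA_real_,
                                             heteroscedasticity_p = NA_real_),
                          data = d, fitted = d$z, model = NULL),
                     class = "association_fit"))
  }
  use_chal <- length(unique(d$challenge)) > 1
  form <- stats::as.formula(paste(
    "z ~", paste(comps, collapse = " + "),
    if (use_chal) "+ factor(challenge)" else ""))
  fit <- MASS::rlm(form, data = d, psi = MASS::psi.huber, maxit = 200)
  co <- summary(fit)$coefficients
  df <- length(d$z) - nrow(co)
  keep <- rownames(co) %in% c("(Intercept)", comps)
  est <- co[keep, "Value"]; se <- co[keep, "Std. Error"]
  stat <- est / se
  res <- stats::residuals(fit); fitted_v <- stats::fitted(fit)
  structure(list(
    flavour = "robust",
    coefficients = data.frame(
      term = rownames(co)[keep], estimate = unname(est), se = unname(se),
      statistic = unname(stat),
      p = 2 * stats::pt(-abs(unname(stat)), df = max(df, 1))),
    random_variance = NA_real_,
    residual_variance = summary(fit)$sigma^2,
    logLik = NA_real_,
    r_squared = stats::cor(fitted_v, d$z)^2,
    singular = FALSE,
    diagnostics = residual_diagnostics(res, fitted_v),
    data = d, model = fit
  ), class = "association_fit")
}

merge_scores_target <- function(scores, target) {
  stopifnot(is.data.frame(scores), is.data.frame(target),
            "participant_id" %in% names(target), "z" %in% names(target))
  by <- intersect(c("participant_id", "game", "challenge_index"),
                  names(target))
  d <- merge(as.data.frame(scores), target[, c(by, "z")], by = by)
  d <- d[!is.na(d$z), , drop = FALSE]
  if (nrow(d) == 0) stop("no joinable rows between scores and target")
  if (length(unique(d$challenge_index)) < 2) {
    stop("need at least 2 challenges")
  }
  if (length(unique(d$participant_id)) < 2) {
    stop("need at least 2 participants")
  }
  d$challenge <- factor(paste0(d$game, "_", d$challenge_index))
  d
}

residual_diagnostics <- function(res, fitted_v) {
  shapiro_p <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  het_p <- if (stats::sd(res) > 0 && stats::sd(fitted_v) > 0) {
    suppressWarnings(stats::cor.test(abs(res), fitted_v,
                                     method = "spearman")$p.value)
  } else NA_real_
  list(shapiro_p = shapiro_p, heteroscedasticity_p = het_p)
}

#' @export
print.association_fit <- function(x, ...) {
  cat("<association_fit> flavour=", x$flavour,
      if (isTRUE(x$singular)) " (singular)" else "", "\n", sep = "")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' Sequentially rejective Bonferroni adjustment: with p-values sorted
#' ascending, adjusted_(i) = max_{j <= i} min(1, (m - j + 1) p_(j));
#' hypotheses are rejected while the adjusted value stays at or below
#' alpha. Adjusted values always dominate the raw ones.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) return(list(adjusted = numeric(), reject = logical()))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("holm_bonferroni: p-values must be in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvalues, method = "holm")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Cohen's D standardised mean difference
#'
#' (mean_a - mean_b) / pooled sd, pooling by degrees-of-freedom
#' weighting.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return the effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("cohens_d: zero pooled sd")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Group comparison of participant characteristics
#'
#' Compares every measure between two groups (by sex by default):
#' continuous variables get Student's t-test when both groups pass a
#' Shapiro-Wilk normality screen at 0.05, otherwise a Mann-Whitney U
#' test; categorical (non-numeric) variables get a chi-squared test.
#' Groups of fewer than 2 observations for a continuous measure, or a
#' single shared categorical level, are skipped with a warning.
#'
#' @param participants participant data frame.
#' @param by grouping column (default "sex"); must have exactly 2 levels.
#' @param variables columns to compare (default: everything except the
#'   id and grouping columns).
#' @return data frame: variable, test ("t", "mann-whitney",
#'   "chi-squared"), statistic, p, mean or count summaries per group.
#' @export
group_compare <- function(participants, by = "sex", variables = NULL) {
  g <- participants[[by]]
  lev <- unique(g[!is.na(g)])
  if (length(lev) != 2) stop("group_compare: grouping must have 2 levels")
  if (is.null(variables)) {
    variables <- setdiff(names(participants), c("participant_id", by))
  }
  rows <- list()
  for (v in variables) {
    x <- participants[[v]]
    a <- x[g == lev[1] & !is.na(x)]
    b <- x[g == lev[2] & !is.na(x)]
    if (is.numeric(x)) {
      if (length(a) < 2 || length(b) < 2) {
        warning("group_compare: skipping ", v, " (group with < 2 values)")
        next
      }
      normal <- function(u) {
        if (stats::sd(u) == 0) return(FALSE)
        stats::shapiro.test(u)$p.value > 0.05
      }
      if (normal(a) && normal(b)) {
        tt <- stats::t.test(a, b, var.equal = TRUE)
        rows[[v]] <- data.frame(variable = v, test = "t",
                                statistic = unname(tt$statistic),
                                p = tt$p.value,
                                group_a = mean(a), group_b = mean(b))
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b))
        rows[[v]] <- data.frame(variable = v, test = "mann-whitney",
                                statistic = unname(wt$statistic),
                                p = wt$p.value,
                                group_a = mean(a), group_b = mean(b))
      }
    } else {
      tab <- table(factor(g[!is.na(x)]), x[!is.na(x)])
      if (ncol(tab) < 2) {
        warning("group_compare: skipping ", v, " (single categorical level)")
        next
      }
      ct <- suppressWarnings(stats::chisq.test(tab))
      rows[[v]] <- data.frame(variable = v, test = "chi-squared",
                              statistic = unname(ct$statistic),
                              p = ct$p.value,
                              group_a = NA_real_, group_b = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(variable = character(), test = character(),
                                      statistic = numeric(), p = numeric(),
                                      group_a = numeric(), group_b = numeric())
  names(out)[names(out) == "group_a"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "group_b"] <- paste0("mean_", lev[2])
  rownames(out) <- NULL
  out
}

#' Association screen across measures
#'
#' Fits one association model per measure, collects the construct fixed
#' effects, applies the Holm-Bonferroni correction across the whole
#' (measure x component) family of one game and model flavour, and
#' attaches a Cohen's D per significant component (target z compared
#' between rows above and below the component's median score).
#'
#' @param scores `construct_scores` for one game and modality set.
#' @param adjusted long output of [z_adjust()].
#' @param measures measures to screen (default: all present).
#' @param flavour "mixed" or "robust".
#' @param alpha family-wise error rate for the Holm correction.
#' @return data frame with one row per (measure, component): estimates,
#'   standard errors, raw and adjusted p-values, rejection flags,
#'   Cohen's D for rejected components, variance components and fit
#'   statistics.
#' @export
run_associations <- function(scores, adjusted, measures = NULL,
                             flavour = c("mixed", "robust"), alpha = 0.05) {
  flavour <- match.arg(flavour)
  if (is.null(measures)) measures <- unique(adjusted$measure)
  fitter <- if (flavour == "mixed") fit_mixed else fit_robust
  rows <- list(); fits <- list()
  for (m in measures) {
    target <- adjusted[adjusted$measure == m, , drop = FALSE]
    fit <- fitter(scores, target)
    fits[[m]] <- fit
    co <- fit$coefficients
    co <- co[grepl("^MBC", co$term), , drop = FALSE]
    rows[[m]] <- cbind(game = scores$game[1], measure = m,
                       modality = scores$modality[1], co,
                       random_variance = fit$random_variance,
                       residual_variance = fit$residual_variance,
                       logLik = fit$logLik, r_squared = fit$r_squared,
                       singular = fit$singular, flavour = flavour)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$p)
  out$p_adjusted <- NA_real_; out$reject <- FALSE
  if (any(ok)) {
    hb <- holm_bonferroni(out$p[ok], alpha)
    out$p_adjusted[ok] <- hb$adjusted
    out$reject[ok] <- hb$reject
  }
  out$cohens_d <- NA_real_
  for (i in which(out$reject)) {
    d <- fits[[out$measure[i]]]$data
    s <- d[[out$term[i]]]
    hi <- d$z[s > stats::median(s)]
    lo <- d$z[s <= stats::median(s)]
    out$cohens_d[i] <- if (length(hi) >= 2 && length(lo) >= 2 &&
                           (stats::var(hi) + stats::var(lo)) > 0) {
      cohens_d(hi, lo)
    } else NA_real_
  }
  out
}
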