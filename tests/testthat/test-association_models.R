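# direct construction of construct scores with a known generating model,
# bypassing the stream pipeline: n_part x n_chal rows, random MBCs
make_scores <- function(n_part = 10, n_chal = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- expand.grid(challenge_index = seq_len(n_chal),
                   participant_id = sprintf("P%03d", seq_len(n_part)),
                   stringsAsFactors = FALSE)[, 2:1]
  d$game <- "Connect"
  d$modality <- "multimodal"
  d$MBC1 <- rnorm(nrow(d)); d$MBC2 <- rnorm(nrow(d)); d$MBC3 <- rnorm(nrow(d))
  d[, c("participant_id", "game", "challenge_index", "modality",
        "MBC1", "MBC2", "MBC3")]
}

make_target <- function(scores, beta1 = 0.8, chal_sd = 0.5, noise_sd = 1) {
  u <- rnorm(max(scores$challenge_index), 0, chal_sd)
  z_row <- beta1 * scores$MBC1 + u[scores$challenge_index] +
    rnorm(nrow(scores), 0, noise_sd)
  data.frame(participant_id = scores$participant_id,
             challenge_index = scores$challenge_index, z = z_row)
}

test_that("z_adjust errors on a missing normative cell", {
  norms <- simulate_norms(sim_config(seed = 4))
  norms <- norms[!(norms$measure == "coding" & norms$sex == "boy" &
                     norms$age_lo == 11), ]
  p <- data.frame(participant_id = "X", age = 12, sex = "boy", coding = 40)
  expect_error(z_adjust(p, norms, "coding"), "coding.*boy")
})

test_that("the mixed model recovers a programmed fixed effect and flags singular fits", {
  set.seed(60)
  sc <- make_scores(10, 6)
  tg <- make_target(sc, beta1 = 0.8)
  fit <- fit_mixed(sc, tg)
  co <- fit$coefficients
  b1 <- co[co$term == "MBC1", ]
  expect_lt(abs(b1$estimate - 0.8), 3 * b1$se)
  expect_lt(co$p[co$term == "MBC1"], 0.001)
  expect_gte(fit$random_variance, 0)
  expect_true(all(c("shapiro_p", "heteroscedasticity_p") %in%
                    names(fit$diagnostics)))
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)

  # no challenge effect at all: variance estimate sits near the boundary
  # (median over simulations), and boundary fits are flagged, not dropped
  set.seed(61)
  sims <- replicate(30, {
    sc0 <- make_scores(10, 6)
    tg0 <- make_target(sc0, beta1 = 0.5, chal_sd = 0)
    f <- fit_mixed(sc0, tg0)
    c(ratio = f$random_variance / f$residual_variance,
      singular = f$singular, ranvar = f$random_variance)
  })
  expect_lte(median(sims["ratio", ]), 0.05)
  expect_gt(sum(sims["singular", ]), 0)
  expect_true(all(sims["ranvar", sims["singular", ] == 1] == 0))
})

test_that("mixed-model estimates are unbiased under the generating model", {
  set.seed(62)
  est <- replicate(40, {
    sc <- make_scores(10, 6)
    tg <- make_target(sc, beta1 = 0.8)
    fit <- fit_mixed(sc, tg)
    fit$coefficients$estimate[fit$coefficients$term == "MBC1"]
  })
  expect_lt(abs(mean(est) - 0.8), 0.08)
})

test_that("robust regression agrees with the mixed fit on clean data and resists outliers", {
  set.seed(63)
  sc <- make_scores(12, 6)
  tg <- make_target(sc, beta1 = 1, chal_sd = 0.3, noise_sd = 0.5)
  fm <- fit_mixed(sc, tg)
  fr <- fit_robust(sc, tg)
  b_m <- fm$coefficients$estimate[fm$coefficients$term == "MBC1"]
  b_r <- fr$coefficients$estimate[fr$coefficients$term == "MBC1"]
  expect_lt(abs(b_r - b_m) / abs(b_m), 0.05)

  # 10% gross outliers: robust stays closer to truth than ordinary lm
  set.seed(64)
  wins <- replicate(20, {
    sc2 <- make_scores(10, 6)
    tg2 <- make_target(sc2, beta1 = 1, chal_sd = 0, noise_sd = 0.5)
    out <- sample(nrow(tg2), 6)
    tg2$z[out] <- tg2$z[out] + sample(c(-1, 1), 6, TRUE) * runif(6, 8, 15)
    d <- merge(sc2, tg2, by = c("participant_id", "challenge_index"))
    b_lm <- coef(lm(z ~ MBC1 + MBC2 + MBC3, data = d))[["MBC1"]]
    b_rb <- fit_robust(sc2, tg2)$coefficients
    b_rb <- b_rb$estimate[b_rb$term == "MBC1"]
    abs(b_rb - 1) < abs(b_lm - 1)
  })
  expect_gte(sum(wins), 15)

  # constant target: zero construct coefficients
  tgc <- data.frame(participant_id = sc$participant_id,
                    challenge_index = sc$challenge_index, z = 2)
  frc <- fit_robust(sc, tgc)
  expect_equal(frc$coefficients$estimate[frc$coefficients$term != "(Intercept)"],
               c(0, 0, 0))
})

test_that("Holm-Bonferroni reproduces the worked step-down example", {
  r <- holm_bonferroni(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_equal(r$adjusted, c(0.03, 0.06, 0.06))
  expect_equal(r$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(0.02)$adjusted, 0.02)
  all1 <- holm_bonferroni(rep(1, 5))
  expect_equal(all1$adjusted, rep(1, 5))
  expect_false(any(all1$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("Holm adjustment matches brute-force step-down on random p-vectors", {
  set.seed(65)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    r <- holm_bonferroni(p)
    expect_equal(r$adjusted, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(r$adjusted >= p - 1e-12))
  }
})

test_that("Cohen's D matches its definition and a programmed shift", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(66)
  a <- rnorm(500); b <- rnorm(500, -1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.15)
  d <- cohens_d(rnorm(200, 0.5), rnorm(200, 0))
  expect_lt(abs(d - 0.5), 0.15)
  expect_error(cohens_d(c(2, 2), c(2, 2)), "pooled sd")
})

test_that("group comparison picks the right test and handles degenerate input", {
  set.seed(67)
  p <- data.frame(participant_id = sprintf("P%02d", 1:60),
                  sex = rep(c("girl", "boy"), each = 30))
  p$normal_gap <- rnorm(60) + ifelse(p$sex == "girl", 2, 0)  # 2 pooled sds
  p$skewed <- exp(rnorm(60, sd = 1.2))
  p$handed <- sample(c("left", "right"), 60, TRUE)
  r <- group_compare(p, by = "sex")
  expect_equal(r$test[r$variable == "normal_gap"], "t")
  expect_lt(r$p[r$variable == "normal_gap"], 0.05)
  expect_equal(r$test[r$variable == "skewed"], "mann-whitney")
  expect_equal(r$test[r$variable == "handed"], "chi-squared")

  p$solo <- "right"
  expect_warning(group_compare(p, by = "sex"), "single categorical")
  p$solo <- NULL
  p$sparse <- c(rnorm(30), 1, rep(NA, 29))
  expect_warning(group_compare(p, by = "sex"), "< 2 values")
})

test_that("group comparison is calibrated under the null", {
  set.seed(68)
  rejections <- replicate(40, {
    p <- data.frame(sex = rep(c("girl", "boy"), each = 25), v = rnorm(50))
    group_compare(p, by = "sex", variables = "v")$p < 0.05
  })
  expect_lte(mean(rejections), 0.15)
})

test_that("the full association grid runs with family-wide Holm correction", {
  tc <- test_cohort()
  ref_bm <- assemble_matrix(tc$ref$cohort, "Connect", "multimodal")
  sc <- project_constructs(fit_reference(ref_bm),
                           assemble_matrix(tc$sim$cohort, "Connect",
                                           "multimodal"))
  adj <- z_adjust(tc$sim$cohort$participants, tc$sim$cohort$norms)
  res <- run_associations(sc, adj)
  expect_equal(nrow(res), 15 * 3)
  expect_true(all(res$p_adjusted >= res$p - 1e-12, na.rm = TRUE))
  ok <- !is.na(res$p)
  expect_equal(res$p_adjusted[ok], oracle_holm(res$p[ok]), tolerance = 1e-12)
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  expect_true(all(is.finite(res$cohens_d[res$reject]) |
                    is.na(res$cohens_d[res$reject])))
  res_r <- run_associations(sc, adj, measures = c("coding", "digit_span"),
                            flavour = "robust")
  expect_equal(unique(res_r$flavour), "robust")
  expect_equal(nrow(res_r), 6)
})
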