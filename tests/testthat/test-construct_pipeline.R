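test_that("causal moving average matches hand computations", {
  expect_equal(smooth_series(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(smooth_series(rep(7, 10), 4), rep(7, 10))
  expect_equal(smooth_series(c(0, 10), 2), c(0, 5))
  expect_equal(smooth_series(c(1, 2, 3, 4), 3), c(1, 1.5, 2, 3))
  expect_error(smooth_series(1:3, 0), "window")
})

test_that("binning follows the stated fill rules", {
  # constant series with every bin populated
  t <- seq(0.005, 0.995, by = 0.005)
  b <- bin_series(t, rep(4.2, length(t)), duration = 1)
  expect_equal(b$values, rep(4.2, 100))
  expect_false(any(b$missing))

  # single observation mid-challenge: carried to every bin
  b1 <- bin_series(0.5, 3.3, duration = 1)
  expect_equal(b1$values, rep(3.3, 100))
  expect_equal(sum(!b1$missing), 1)

  # dense linear ramp: monotone bin means with analytic endpoints
  tr <- seq(0, 10, by = 0.001)
  br <- bin_series(tr, tr / 10, duration = 10)
  expect_true(all(diff(br$values) > 0))
  expect_lt(br$values[1], 0.02)
  expect_gt(br$values[100], 0.98)

  # interior gap: linear interpolation between nearest non-empty bins
  bg <- bin_series(c(0.005, 0.995), c(0, 1), duration = 1)
  expect_equal(bg$values[50], 49 / 99, tolerance = 1e-9)
  expect_equal(sum(bg$missing), 98)

  # all-empty series: all missing
  b0 <- bin_series(numeric(), numeric(), duration = 1)
  expect_true(all(b0$missing))
  expect_true(all(is.na(b0$values)))
  expect_error(bin_series(0.1, 1, duration = 0), "duration")
})

test_that("assembled matrices have the documented shape and canonical order", {
  tc <- test_cohort()
  bm <- assemble_matrix(tc$sim$cohort, "Connect", "multimodal")
  expect_equal(dim(bm$values), c(6 * 6, 16 * 100))
  expect_equal(length(bm$features), 16)
  bm_eye <- assemble_matrix(tc$sim$cohort, "Connect", "eye")
  expect_equal(ncol(bm_eye$values), 400)
  bm_r <- assemble_matrix(tc$sim$cohort, "Rocket", "touch")
  expect_equal(dim(bm_r$values), c(6 * 11, 500))
  # feature-major column order
  expect_equal(colnames(bm$values)[1], "gaze_angular_distance_bin001")
  expect_equal(colnames(bm$values)[101], "gaze_total_angular_distance_bin001")
  # canonical row sort regardless of input order
  shuf <- tc$sim$cohort
  shuf$challenges <- rev(shuf$challenges)
  bm2 <- assemble_matrix(shuf, "Connect", "multimodal")
  expect_identical(bm2$values, bm$values)
  # a participant missing a challenge yields an all-missing row + warning
  drop1 <- tc$sim$cohort
  drop1$challenges <- Filter(function(ch) {
    !(ch$participant_id == "P001" & ch$game == "Connect" &
        ch$challenge_index == 2)
  }, drop1$challenges)
  expect_warning(bm3 <- assemble_matrix(drop1, "Connect", "eye"), "missing")
  i <- which(bm3$rows$participant_id == "P001" & bm3$rows$challenge_index == 2)
  expect_true(all(is.na(bm3$values[i, ])))
})

test_that("reference PCA concentrates variance on a constructed low-rank matrix", {
  set.seed(50)
  n <- 30; p <- 60
  basis <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  scores <- matrix(rnorm(n * 3, sd = c(6, 4, 2)), n, 3, byrow = TRUE)
  X <- scores %*% t(basis) + matrix(rnorm(n * p, sd = 0.05), n, p)
  model <- fit_reference(as_binned(X), n_components = 3)
  expect_gt(sum(model$explained_variance), 0.95)
  expect_true(all(diff(model$explained_variance) <= 0))
  # orthonormal eigenvectors
  g <- t(model$rotation) %*% model$rotation
  expect_equal(g, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic: refitting gives the identical model
  expect_identical(fit_reference(as_binned(X), 3), model)
  expect_error(fit_reference(as_binned(X[1:2, ]), 3), "fewer rows")
})

test_that("zero-variance columns are dropped and recorded, not fatal", {
  set.seed(51)
  X <- matrix(rnorm(20 * 10), 20, 10)
  X[, 4] <- 1.5
  bm <- as_binned(X)
  model <- fit_reference(bm, 2)
  expect_equal(model$dropped, colnames(bm$values)[4])
  sc <- project_constructs(model, bm)
  expect_true(all(is.finite(as.matrix(sc[, c("MBC1", "MBC2")]))))
})

test_that("projection reproduces the PCA identity on the training matrix", {
  set.seed(52)
  X <- matrix(rnorm(40 * 25), 40, 25)
  bm <- as_binned(X)
  model <- fit_reference(bm, 3)
  sc <- as.matrix(project_constructs(model, bm)[, c("MBC1", "MBC2", "MBC3")])
  cv <- stats::cov(sc)
  expect_equal(cv[upper.tri(cv)], rep(0, 3), tolerance = 1e-6)
  expect_equal(diag(cv), model$component_variance, tolerance = 1e-6,
               ignore_attr = TRUE)
  # a row equal to the reference column means scores exactly zero
  mbm <- as_binned(rbind(model$means, model$means))
  sc0 <- project_constructs(model, mbm)
  expect_equal(unlist(sc0[1, c("MBC1", "MBC2", "MBC3")]), c(0, 0, 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  # permuted columns are a contract violation
  bad <- as_binned(X[, c(2:25, 1)])
  colnames(bad$values) <- colnames(X)[c(2:25, 1)]
  expect_error(project_constructs(model, bad), "column mismatch")
})

test_that("reference transfer never leaks target statistics", {
  tc <- test_cohort()
  ref_bm <- assemble_matrix(tc$ref$cohort, "Connect", "multimodal")
  model <- fit_reference(ref_bm)
  bm <- assemble_matrix(tc$sim$cohort, "Connect", "multimodal")
  sc <- project_constructs(model, bm)
  # permuting target rows permutes scores identically
  perm <- sample(nrow(bm$values))
  bmp <- bm; bmp$values <- bm$values[perm, ]; bmp$missing <- bm$missing[perm, ]
  bmp$rows <- bm$rows[perm, ]
  scp <- project_constructs(model, bmp)
  key <- function(d) paste(d$participant_id, d$challenge_index)
  expect_equal(scp$MBC1[order(key(scp))], sc$MBC1[order(key(sc))],
               tolerance = 1e-12)
  # subsetting target rows leaves retained scores untouched
  bms <- bm; keep <- 1:10
  bms$values <- bm$values[keep, ]; bms$missing <- bm$missing[keep, ]
  bms$rows <- bm$rows[keep, ]
  scs <- project_constructs(model, bms)
  expect_equal(scs$MBC2, sc$MBC2[keep], tolerance = 1e-12)
})

test_that("construct models serialise to JSON and back", {
  set.seed(53)
  model <- fit_reference(as_binned(matrix(rnorm(15 * 8), 15, 8)), 2)
  path <- tempfile(fileext = ".json")
  write_construct_model(model, path)
  back <- read_construct_model(path)
  expect_equal(back$rotation, model$rotation, tolerance = 1e-12)
  expect_equal(back$means, model$means, tolerance = 1e-12)
  expect_equal(back$explained_variance, model$explained_variance,
               tolerance = 1e-12)
})
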