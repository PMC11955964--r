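# Independent oracles used across the suite. These deliberately use
# plain loops / enumeration, never the package's own code paths.

# brute-force I-VT: per-interval threshold compare, explicit run scan,
# then the minimum-fixation-duration filter
oracle_ivt <- function(t0, t1, velocity, threshold = 100, min_fix = 0.070) {
  lab <- character(length(velocity))
  for (i in seq_along(velocity)) {
    lab[i] <- if (velocity[i] >= threshold) "saccade" else "fixation"
  }
  events <- list()
  i <- 1
  while (i <= length(lab)) {
    j <- i
    while (j < length(lab) && lab[j + 1] == lab[i]) j <- j + 1
    events[[length(events) + 1]] <- list(type = lab[i], start = t0[i],
                                         end = t1[j], i = i, j = j)
    i <- j + 1
  }
  for (e in events) {
    if (e$type == "fixation" && (e$end - e$start) < min_fix) {
      for (k in e$i:e$j) lab[k] <- "undefined"
    }
  }
  types <- vapply(events, function(e) {
    if (e$type == "fixation" && (e$end - e$start) < min_fix) "undefined"
    else e$type
  }, "")
  list(labels = lab,
       events = data.frame(
         type = types,
         start = vapply(events, function(e) e$start, 0),
         end = vapply(events, function(e) e$end, 0)))
}

# random kinematics table for oracle comparisons (not the package simulator)
random_kinematics <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:60, 1)
  dt <- runif(n, 0.01, 0.1)
  t <- cumsum(c(0, dt))
  v <- runif(n, 0, 300)
  data.frame(t = (t[-(n + 1)] + t[-1]) / 2, t0 = t[-(n + 1)], t1 = t[-1],
             angular_distance = v * dt, angular_velocity = v,
             total_angular_distance = cumsum(v * dt))
}

# gift-wrapping (Jarvis march) convex hull + triangle-fan area
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    best <- cand[1]
    for (q in cand[-1]) {
      cr <- (pts[best, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
        (pts[best, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      if (cr < 0 ||
          (cr == 0 && sum((pts[q, ] - pts[p, ])^2) > sum((pts[best, ] - pts[p, ])^2))) {
        best <- q
      }
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("oracle hull failed")
  }
  if (length(hull) < 3) return(0)
  a <- 0
  for (k in 2:(length(hull) - 1)) {
    p1 <- pts[hull[1], ]; p2 <- pts[hull[k], ]; p3 <- pts[hull[k + 1], ]
    a <- a + ((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                (p2[2] - p1[2]) * (p3[1] - p1[1])) / 2
  }
  unname(abs(a))
}

# literal step-down evaluation of the Holm-Bonferroni definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(i)
    for (j in seq_len(i)) vals[j] <- min(1, (m - j + 1) * p[o[j]])
    adj_sorted[i] <- max(vals)
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# small cohorts, cached per session so several test files can share them
.cohort_cache <- new.env(parent = emptyenv())
test_cohort <- function(key = "default", ...) {
  if (!exists(key, envir = .cohort_cache)) {
    args <- list(...)
    if (is.null(args$n_participants)) args$n_participants <- 6
    if (is.null(args$n_reference)) args$n_reference <- 8
    if (is.null(args$seed)) args$seed <- 2024
    if (is.null(args$rocket_duration)) args$rocket_duration <- 6
    if (is.null(args$connect_duration)) args$connect_duration <- 8
    cfg <- do.call(sim_config, args)
    assign(key, list(sim = simulate_cohort(cfg),
                     ref = simulate_reference(cfg), cfg = cfg),
           envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# wrap a bare matrix as a binned_matrix (for PCA-level tests)
as_binned <- function(values, n_bins = NULL) {
  n_feat <- 1
  if (is.null(n_bins)) n_bins <- ncol(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f_bin", sprintf("%03d", seq_len(ncol(values))))
  }
  structure(list(values = values,
                 missing = matrix(FALSE, nrow(values), ncol(values),
                                  dimnames = dimnames(values)),
                 rows = data.frame(
                   participant_id = sprintf("P%03d", seq_len(nrow(values))),
                   game = "Connect",
                   challenge_index = rep_len(1:6, nrow(values))),
                 features = "f", n_bins = n_bins),
            class = "binned_matrix")
}
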