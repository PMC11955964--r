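#' Kinematic features of one touch gesture
#'
#' Computes the five digit-tracking features of a gesture given its
#' point-by-point trajectory:
#' \describe{
#'   \item{speed}{mean over inter-point intervals of segment length / dt,
#'     in pixels/s; zero-dt repeated samples are collapsed first.}
#'   \item{area}{area of the minimal convex polygon (convex hull) over
#'     the gesture's points, in pixels squared; 0 with fewer than 3
#'     non-collinear points.}
#'   \item{distance}{sum of point-by-point Euclidean segment lengths,
#'     in pixels.}
#'   \item{duration}{last t minus first t, in seconds.}
#'   \item{height}{vertical extent max(y) - min(y), in pixels.}
#' }
#' A single-point gesture yields all-zero features.
#'
#' @param points data frame with columns `t` (seconds, non-decreasing),
#'   `x`, `y` (pixels, finite); at least one row.
#' @return named numeric vector `c(speed, area, distance, duration, height)`.
#' @export
touch_features <- function(points) {
  stopifnot(is.data.frame(points), all(c("t", "x", "y") %in% names(points)),
            nrow(points) >= 1)
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    stop("touch_features: non-finite coordinates")
  }
  if (is.unsorted(points$t)) stop("touch_features: decreasing timestamps")
  n <- nrow(points)
  if (n == 1) {
    return(c(speed = 0, area = 0, distance = 0, duration = 0, height = 0))
  }
  seg <- sqrt(diff(points$x)^2 + diff(points$y)^2)
  distance <- sum(seg)
  duration <- points$t[n] - points$t[1]
  height <- max(points$y) - min(points$y)
  # collapse zero-dt intervals before speed (100 Hz streams duplicate stamps)
  dt <- diff(points$t)
  keep <- dt > 0
  speed <- if (any(keep)) mean(seg[keep] / dt[keep]) else 0
  c(speed = speed, area = hull_area(points$x, points$y),
    distance = distance, duration = duration, height = height)
}

#' Convex-hull area of a point set
#'
#' Shoelace area over the convex-hull vertex cycle; 0 when the hull is
#' degenerate (fewer than 3 non-collinear points).
#'
#' @param x,y coordinate vectors of equal length.
#' @return area (same squared units as the coordinates).
#' @export
hull_area <- function(x, y) {
  stopifnot(length(x) == length(y))
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  k <- length(h)
  if (k < 3) return(0)
  abs(sum(hx * hy[c(2:k, 1)] - hx[c(2:k, 1)] * hy)) / 2
}

#' Touch feature series for one challenge
#'
#' Computes per-gesture features for every gesture in a challenge and
#' arranges them as one time series per feature, indexed by the gesture's
#' midpoint time (mean of first and last timestamp) and sorted by time.
#' A challenge with no touch events yields an empty series; the binning
#' stage's missing-data rule handles it.
#'
#' @param touch data frame with columns `gesture_id`, `t`, `x`, `y`
#'   (possibly zero rows).
#' @return data frame with columns `feature`, `t`, `value`.
#' @export
aggregate_touch <- function(touch) {
  empty <- data.frame(feature = character(), t = numeric(), value = numeric())
  if (is.null(touch) || nrow(touch) == 0) return(empty)
  stopifnot(all(c("gesture_id", "t", "x", "y") %in% names(touch)))
  by_g <- split(touch[, c("t", "x", "y")], touch$gesture_id)
  feats <- t(vapply(by_g, function(g) {
    g <- g[order(g$t), , drop = FALSE]
    c(mid = (g$t[1] + g$t[nrow(g)]) / 2, touch_features(g))
  }, numeric(6)))
  feats <- feats[order(feats[, "mid"]), , drop = FALSE]
  fnames <- c(speed = "touch_speed", area = "touch_area",
              distance = "touch_distance", duration = "touch_duration",
              height = "touch_height")
  do.call(rbind, lapply(names(fnames), function(f) {
    data.frame(feature = fnames[[f]], t = feats[, "mid"],
               value = feats[, f], row.names = NULL)
  }))
}
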