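# Quantitative chemotaxis statistics for the microfluidic channel assay:
# chemotaxis index, slice profiles, population center of mass, mean speed
# and the Rayleigh endpoint test.
#
# Geometry convention: the channel runs along x with the chemo-effector
# reservoir at x = 0; region 2 is the third of the channel nearest the
# chemo-effector, region 0 the third nearest the cell reservoir.

#' Chemotaxis index
#'
#' CI = (cells in region 2 / cells in region 1) divided by the same ratio
#' for cells kept 4 hours in the vehicle control. The 4-hour control
#' measured against itself gives CI = 1. Scaling all counts in both the
#' treatment and the control by a common factor leaves CI unchanged.
#'
#' @param region_counts data.frame with columns `condition`, `time_h`,
#'   `n0`, `n1`, `n2` (one row per condition x time point).
#' @param control_ratio_4h Positive n2/n1 ratio of the 4-hour vehicle
#'   control.
#' @return The input with `ratio` (n2/n1) and `ci` columns appended.
#' @examples
#' rc <- data.frame(condition = "pep", time_h = 4, n0 = 20, n1 = 10, n2 = 30)
#' chemotaxis_index(rc, control_ratio_4h = 1.5)$ci  # 2
#' @export
chemotaxis_index <- function(region_counts, control_ratio_4h) {
  need <- c("condition", "time_h", "n0", "n1", "n2")
  if (!is.data.frame(region_counts) || !all(need %in% names(region_counts)))
    stop("region_counts needs columns condition, time_h, n0, n1, n2",
         call. = FALSE)
  if (any(region_counts[, c("n0", "n1", "n2")] < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (!is.numeric(control_ratio_4h) || control_ratio_4h <= 0)
    stop("CI undefined: control ratio must be positive", call. = FALSE)
  if (any(region_counts$n1 == 0))
    stop("CI undefined: n1 is zero for at least one row", call. = FALSE)
  region_counts$ratio <- region_counts$n2 / region_counts$n1
  region_counts$ci <- region_counts$ratio / control_ratio_4h
  region_counts
}

#' Slice occupancy profile
#'
#' Ratio of the cell count in each channel slice to the count in slice 0
#' (the slice at the cell-reservoir end); slice 0 has ratio 1 exactly. The
#' study imaged 19 slices covering the 50-mm channel.
#'
#' @param counts Nonnegative numeric vector of per-slice counts, ordered
#'   slice 0 first; `counts[1]` must be positive.
#' @return Numeric vector of ratios, same length as `counts`.
#' @export
slice_profile <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 1L || any(counts < 0))
    stop("counts must be a nonnegative numeric vector", call. = FALSE)
  if (counts[1L] == 0)
    stop("profile undefined: slice 0 count is zero", call. = FALSE)
  counts / counts[1L]
}

#' Population center of mass, mean speed and endpoint uniformity
#'
#' The center of mass (COM) is the mean over cells of the endpoint
#' displacement vector (final minus initial position), making it invariant
#' to translation of absolute coordinates. Mean speed is the mean over
#' cells of path length / track duration. Endpoint direction uniformity is
#' assessed with the Rayleigh endpoint test on atan2 displacement angles
#' (cells with zero net displacement contribute no angle).
#'
#' @param trajectories data.frame with columns `cell`, `t` (s), `x`, `y`
#'   (um), sampled at fixed intervals; tracks with fewer than 2 samples are
#'   skipped with a warning.
#' @return list with `com` (named vector, um), `mean_speed` (um/s),
#'   `rayleigh_p` (NA when fewer than 5 usable angles) and `n_cells`.
#' @export
population_com <- function(trajectories) {
  need <- c("cell", "t", "x", "y")
  if (!is.data.frame(trajectories) || !all(need %in% names(trajectories)))
    stop("trajectories needs columns cell, t, x, y", call. = FALSE)
  split_tr <- split(trajectories, trajectories$cell)
  disp <- matrix(NA_real_, length(split_tr), 2L)
  speed <- rep(NA_real_, length(split_tr))
  skipped <- 0L
  for (i in seq_along(split_tr)) {
    g <- split_tr[[i]][order(split_tr[[i]]$t), ]
    if (nrow(g) < 2L) { skipped <- skipped + 1L; next }
    if (any(diff(g$t) <= 0))
      stop("time samples must be strictly increasing within a track",
           call. = FALSE)
    disp[i, ] <- c(g$x[nrow(g)] - g$x[1L], g$y[nrow(g)] - g$y[1L])
    steps <- sqrt(diff(g$x)^2 + diff(g$y)^2)
    speed[i] <- sum(steps) / (g$t[nrow(g)] - g$t[1L])
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d track(s) with < 2 samples", skipped),
            call. = FALSE)
  ok <- !is.na(speed)
  if (!any(ok)) stop("no usable trajectories", call. = FALSE)
  disp <- disp[ok, , drop = FALSE]
  moved <- rowSums(disp^2) > 0
  angles <- atan2(disp[moved, 2L], disp[moved, 1L])
  p <- if (length(angles) >= 5L) rayleigh_test(angles) else NA_real_
  list(com = c(x = mean(disp[, 1L]), y = mean(disp[, 2L])),
       mean_speed = mean(speed[ok]),
       rayleigh_p = p,
       n_cells = sum(ok))
}

#' Rayleigh test of circular uniformity
#'
#' Tests endpoint directions against the uniform circular distribution.
#' With resultant length R = |sum of unit vectors| and Z = R^2 / n, the
#' p-value uses the standard series approximation
#' p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)),
#' clamped to (0, 1]. Small p indicates directed movement.
#'
#' @param angles Numeric vector of at least 5 angles in radians.
#' @return p-value in (0, 1].
#' @export
rayleigh_test <- function(angles) {
  if (!is.numeric(angles) || length(angles) < 5L)
    stop("rayleigh_test requires at least 5 angles", call. = FALSE)
  n <- length(angles)
  R <- Mod(sum(exp(1i * angles)))
  Z <- R^2 / n
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  min(max(p, .Machine$double.xmin), 1)
}
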