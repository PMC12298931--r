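#' Gait event annotations
#'
#' Ordered foot-contact (heel-strike) and toe-off times for one leg. Each
#' toe-off must fall strictly between consecutive foot contacts.
#'
#' @param foot_contacts Strictly increasing contact times, seconds.
#' @param toe_offs Strictly increasing toe-off times, seconds.
#' @param side `"left"` or `"right"`.
#' @return Object of class `gait_events`.
#' @export
gait_events <- function(foot_contacts, toe_offs, side = "right") {
  foot_contacts <- as.numeric(foot_contacts)
  toe_offs <- as.numeric(toe_offs)
  if (is.unsorted(foot_contacts, strictly = TRUE) ||
      is.unsorted(toe_offs, strictly = TRUE)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  for (to in toe_offs) {
    k <- findInterval(to, foot_contacts)
    if (k < 1 || k >= length(foot_contacts) ||
        to <= foot_contacts[k] || to >= foot_contacts[k + 1]) {
      stop(sprintf("toe-off at %.3f s does not lie between consecutive contacts",
                   to), call. = FALSE)
    }
  }
  structure(list(foot_contacts = foot_contacts, toe_offs = toe_offs,
                 side = match.arg(side, c("right", "left"))),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %s leg: %d contacts, %d toe-offs\n",
              x$side, length(x$foot_contacts), length(x$toe_offs)))
  invisible(x)
}

#' Detect gait events from the sagittal shank angular velocity
#'
#' Heuristic event detector for records without external annotations. During
#' walking, the shank's sagittal angular velocity shows one large mid-swing
#' peak per cycle (rapid forward rotation) flanked by troughs: the trough
#' before the peak marks toe-off and the trough after it marks the next foot
#' contact. The detector (i) checks for periodicity with a dominant cadence
#' in 0.5-2 Hz, (ii) standardises the polarity so the mid-swing extremum is
#' positive, (iii) picks the per-cycle swing peaks, and (iv) localises the
#' flanking minima. Externally supplied annotations should always take
#' precedence over this heuristic (see [run_pipeline()]).
#'
#' @param gyro_sagittal Sagittal (knee flexion/extension axis) angular
#'   velocity, rad/s.
#' @param dt Sampling interval, seconds.
#' @param t0 Time of the first sample, seconds.
#' @param side Leg label for the returned events.
#' @return A [gait_events()].
#' @export
detect_gait_events <- function(gyro_sagittal, dt, t0 = 0, side = "right") {
  x <- as.numeric(gyro_sagittal)
  n <- length(x)
  if (n < 4 / dt) stop("record too short for event detection", call. = FALSE)
  xc <- x - mean(x)
  if (stats::sd(xc) < 1e-6) {
    stop("no periodicity detected (constant signal); supply a manual events file",
         call. = FALSE)
  }
  # dominant frequency by autocorrelation peak in the 0.5-2 Hz band
  max_lag <- floor(1 / (0.5 * dt))
  ac <- stats::acf(xc, lag.max = max_lag, plot = FALSE)$acf[-1]
  lags <- seq_along(ac)
  band <- lags >= floor(1 / (2 * dt)) & lags <= max_lag
  if (!any(band) || max(ac[band]) < 0.3) {
    stop("no periodicity detected in the 0.5-2 Hz band; supply a manual events file",
         call. = FALSE)
  }
  period <- lags[band][which.max(ac[band])]
  # polarity: make the global extremum (the mid-swing peak) positive
  s <- if (abs(max(xc)) >= abs(min(xc))) 1 else -1
  xs <- s * xc
  # swing peaks: local maxima above half the global max, separated >= 0.6 period
  thr <- 0.5 * max(xs)
  cand <- which(xs > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[xs[cand] >= xs[cand - 1] & xs[cand] >= xs[cand + 1]]
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) == 0 || i - peaks[length(peaks)] >= 0.6 * period) {
      peaks <- c(peaks, i)
    } else if (xs[i] > xs[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  if (length(peaks) < 2) {
    stop("fewer than two gait cycles detected; supply a manual events file",
         call. = FALSE)
  }
  half <- floor(0.5 * period)
  contacts <- vapply(peaks, function(p) {
    win <- seq(p, min(n, p + half))
    win[which.min(xs[win])]
  }, integer(1))
  toe_offs <- vapply(peaks, function(p) {
    win <- seq(max(1, p - half), p)
    win[which.min(xs[win])]
  }, integer(1))
  # assemble: keep contacts; toe-offs that fall strictly inside contact pairs
  contacts <- sort(unique(contacts))
  toe_offs <- sort(unique(toe_offs))
  keep <- vapply(toe_offs, function(to) {
    k <- findInterval(to, contacts)
    k >= 1 && k < length(contacts) && to > contacts[k] && to < contacts[k + 1]
  }, logical(1))
  toe_offs <- toe_offs[keep]
  gait_events(t0 + (contacts - 1) * dt, t0 + (toe_offs - 1) * dt, side = side)
}

#' Time-normalize a record onto the 0-100% gait-cycle grid
#'
#' Cuts the record into complete cycles (contact to next contact), expresses
#' each cycle's toe-off as a percentage, and linearly resamples the stance
#' (contact to toe-off) and swing (toe-off to next contact) portions
#' independently onto the grid segments `[0, avg_toe_off]` and
#' `[avg_toe_off, 100]`, anchoring every cycle's toe-off at the average
#' toe-off percentage. Pointwise mean and sample standard deviation
#' (denominator n-1) are computed across cycles.
#'
#' @param series Numeric vector or n x k matrix of channel values.
#' @param t Sample times, seconds (same length as the series).
#' @param events A [gait_events()].
#' @param grid_points Number of grid points (default 101: 0-100% at 1%).
#' @return Object of class `gait_ensemble`: `grid` (percent), `cycles`
#'   (n_cycles x grid x k array), `mean` and `sd` (grid x k matrices),
#'   `toe_off_pct` (average, plus per-cycle values), `n_cycles`, `channels`.
#' @export
normalize_to_gait_cycle <- function(series, t, events, grid_points = 101) {
  stopifnot(inherits(events, "gait_events"))
  x <- if (is.null(dim(series))) matrix(series, ncol = 1) else as.matrix(series)
  if (nrow(x) != length(t)) stop("series and t lengths differ", call. = FALSE)
  ch <- colnames(x) %||% paste0("ch", seq_len(ncol(x)))
  fc <- events$foot_contacts
  usable <- list()
  for (k in seq_len(length(fc) - 1)) {
    to <- events$toe_offs[events$toe_offs > fc[k] & events$toe_offs < fc[k + 1]]
    if (length(to) == 1 && fc[k] >= t[1] && fc[k + 1] <= t[length(t)]) {
      usable[[length(usable) + 1]] <- c(fc[k], to, fc[k + 1])
    }
  }
  if (length(usable) == 0) {
    stop("no complete gait cycle (contact-toe_off-contact) inside the record",
         call. = FALSE)
  }
  to_pct <- vapply(usable, function(cyc) 100 * (cyc[2] - cyc[1]) / (cyc[3] - cyc[1]),
                   numeric(1))
  avg_to <- mean(to_pct)
  grid <- seq(0, 100, length.out = grid_points)
  n_cyc <- length(usable)
  cycles <- array(NA_real_, c(n_cyc, grid_points, ncol(x)),
                  dimnames = list(NULL, NULL, ch))
  for (i in seq_len(n_cyc)) {
    cyc <- usable[[i]]
    stance <- grid <= avg_to
    # map [0, avg_to] -> [contact, toe_off], (avg_to, 100] -> (toe_off, next contact]
    tq <- numeric(grid_points)
    tq[stance] <- cyc[1] + (grid[stance] / avg_to) * (cyc[2] - cyc[1])
    tq[!stance] <- cyc[2] + ((grid[!stance] - avg_to) / (100 - avg_to)) *
      (cyc[3] - cyc[2])
    for (j in seq_len(ncol(x))) {
      cycles[i, , j] <- stats::approx(t, x[, j], xout = tq, rule = 2)$y
    }
  }
  st <- ensemble_stats(lapply(seq_len(n_cyc), function(i) cycles[i, , , drop = FALSE][1, , ]))
  structure(
    list(grid = grid, cycles = cycles,
         mean = matrix(st$mean, grid_points, ncol(x), dimnames = list(NULL, ch)),
         sd = matrix(st$sd, grid_points, ncol(x), dimnames = list(NULL, ch)),
         toe_off_pct = avg_to, toe_off_pct_cycles = to_pct,
         n_cycles = n_cyc, channels = ch),
    class = "gait_ensemble"
  )
}

#' @export
print.gait_ensemble <- function(x, ...) {
  cat(sprintf(
    "<gait_ensemble> %d cycles x %d grid points, %d channel(s); toe-off %.1f%%\n",
    x$n_cycles, length(x$grid), length(x$channels), x$toe_off_pct))
  invisible(x)
}

#' Pointwise ensemble mean and standard deviation
#'
#' @param cycles List of equal-length numeric vectors or matrices (one per
#'   cycle).
#' @return List with `mean` and `sd` (sample SD, denominator n-1; reported as
#'   0 with a warning when only one cycle is supplied).
#' @export
ensemble_stats <- function(cycles) {
  if (length(cycles) == 0) stop("no cycles supplied", call. = FALSE)
  arr <- simplify2array(cycles)    # dims of one cycle x n_cycles
  nd <- length(dim(arr))
  if (is.null(dim(arr))) arr <- matrix(arr, nrow = 1)
  n_cyc <- dim(arr)[length(dim(arr))]
  mu <- apply(arr, seq_len(length(dim(arr)) - 1), mean)
  if (n_cyc == 1) {
    warning("single cycle: standard deviation reported as 0")
    sd_out <- mu * 0
  } else {
    sd_out <- apply(arr, seq_len(length(dim(arr)) - 1), stats::sd)
  }
  list(mean = mu, sd = sd_out)
}

#' Per-phase agreement statistics between two channels
#'
#' Pearson correlation and RMSE between two cycle-normalised channels,
#' evaluated over the grid points of a gait-phase window, per cycle, then
#' summarised as mean and sample SD across cycles. Windows are percent-cycle
#' intervals; `"stance"` is `[0, avg_toe_off]` and `"swing"`
#' `(avg_toe_off, 100]`.
#'
#' @param ensemble A `gait_ensemble` holding both channels.
#' @param channel_a,channel_b Channel names or indices.
#' @param phase `"stance"`, `"swing"`, or a numeric `c(lo, hi)` window in
#'   percent of the gait cycle.
#' @return Object of class `phase_stats`: `r_mean`, `r_sd`, `rmse_mean`,
#'   `rmse_sd`, plus per-cycle values. Correlations are `NA` (with a warning)
#'   for cycles where either channel is constant in the window.
#' @export
phase_component_stats <- function(ensemble, channel_a, channel_b,
                                  phase = "stance") {
  stopifnot(inherits(ensemble, "gait_ensemble"))
  win <- phase_window(phase, ensemble$toe_off_pct)
  idx <- which(ensemble$grid >= win[1] & ensemble$grid <= win[2])
  if (length(idx) < 2) stop("phase window contains fewer than 2 grid points",
                            call. = FALSE)
  a <- ensemble$cycles[, idx, channel_a, drop = FALSE]
  b <- ensemble$cycles[, idx, channel_b, drop = FALSE]
  n_cyc <- dim(a)[1]
  r <- rmse <- numeric(n_cyc)
  for (i in seq_len(n_cyc)) {
    ai <- a[i, , 1]; bi <- b[i, , 1]
    rmse[i] <- sqrt(mean((ai - bi)^2))
    if (stats::sd(ai) == 0 || stats::sd(bi) == 0) {
      r[i] <- NA_real_
    } else {
      r[i] <- stats::cor(ai, bi)
    }
  }
  if (anyNA(r)) warning("correlation undefined for cycles with a constant channel")
  structure(
    list(phase = if (is.character(phase)) phase else "custom", window = win,
         r = r, rmse = rmse,
         r_mean = mean(r, na.rm = TRUE), r_sd = stats::sd(r[!is.na(r)]),
         rmse_mean = mean(rmse), rmse_sd = stats::sd(rmse),
         n_cycles = n_cyc),
    class = "phase_stats"
  )
}

phase_window <- function(phase, toe_off_pct) {
  if (is.numeric(phase)) {
    if (length(phase) != 2 || phase[1] >= phase[2]) {
      stop("numeric phase window must be c(lo, hi) with lo < hi", call. = FALSE)
    }
    return(phase)
  }
  switch(match.arg(phase, c("stance", "swing")),
         stance = c(0, toe_off_pct),
         swing = c(toe_off_pct + 1e-9, 100))
}

#' @export
print.phase_stats <- function(x, ...) {
  cat(sprintf("<phase_stats> %s [%.1f, %.1f]%%: r = %.2f +/- %.2f, RMSE = %.2f +/- %.2f (%d cycles)\n",
              x$phase, x$window[1], x$window[2],
              x$r_mean, x$r_sd, x$rmse_mean, x$rmse_sd, x$n_cycles))
  invisible(x)
}
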