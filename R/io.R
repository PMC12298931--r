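#' Read a 9-axis IMU record from CSV
#'
#' Expects a comma-separated file with header columns
#' `t, gx, gy, gz, ax, ay, az, mx, my, mz` (any column order; units s, rad/s,
#' m/s^2, arbitrary magnetometer units). Timestamps must be uniform to within
#' 1% of the median step; malformed numeric cells are reported with their
#' line numbers.
#'
#' @param path Path to the CSV file.
#' @return An [imu_series()].
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  required <- c("t", "gx", "gy", "gz", "ax", "ay", "az", "mx", "my", "mz")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[required]
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad <- which(!apply(df, 1, function(r) all(is.finite(r))))
  if (length(bad) > 0) {
    stop(sprintf("malformed numeric data in %s at line(s) %s (1 = first data row)",
                 path, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  dt_steps <- diff(df$t)
  dt <- stats::median(dt_steps)
  off <- which(abs(dt_steps - dt) > 0.01 * dt)
  if (length(off) > 0) {
    stop(sprintf(
      "non-uniform sampling in %s: step after data row %d is %.6f s (expected %.6f s)",
      path, off[1], dt_steps[off[1]], dt), call. = FALSE)
  }
  imu_series(gyro = as.matrix(df[c("gx", "gy", "gz")]),
             accel = as.matrix(df[c("ax", "ay", "az")]),
             mag = as.matrix(df[c("mx", "my", "mz")]),
             dt = dt, t0 = df$t[1])
}

#' Write a 9-axis IMU record to CSV
#'
#' @param imu An [imu_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(imu, path) {
  stopifnot(inherits(imu, "imu_series"))
  df <- data.frame(t = imu$t,
                   gx = imu$gyro[, 1], gy = imu$gyro[, 2], gz = imu$gyro[, 3],
                   ax = imu$accel[, 1], ay = imu$accel[, 2], az = imu$accel[, 3],
                   mx = imu$mag[, 1], my = imu$mag[, 2], mz = imu$mag[, 3])
  write_csv_full(df, path)
  invisible(path)
}

# full double precision, deterministic text output
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write an estimated pose trajectory to CSV
#'
#' Columns `t, roll_deg, pitch_deg, yaw_deg` (angles in degrees at the file
#' boundary; radians in memory).
#'
#' @param poses A `pose_series`.
#' @param path Output path.
#' @param diagnostics Optionally also write `<path base>_diagnostics.csv`
#'   with per-step innovations and log-likelihood contributions.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(poses, path, diagnostics = FALSE) {
  stopifnot(inherits(poses, "pose_series"))
  df <- data.frame(t = poses$t,
                   roll_deg = rad2deg(poses$rpy[, 1]),
                   pitch_deg = rad2deg(poses$rpy[, 2]),
                   yaw_deg = rad2deg(poses$rpy[, 3]))
  write_csv_full(df, path)
  if (diagnostics) {
    ll <- innovation_log_likelihood(poses)
    dd <- data.frame(t = poses$t,
                     innovation_yaw = poses$diagnostics$V[, 1],
                     innovation_ax = poses$diagnostics$V[, 2],
                     innovation_ay = poses$diagnostics$V[, 3],
                     innovation_az = poses$diagnostics$V[, 4],
                     loglik_step = ll$per_step)
    write_csv_full(dd, sub("\\.csv$", "_diagnostics.csv", path))
  }
  invisible(path)
}

#' Read a pose trajectory written by [write_pose_csv()]
#'
#' @param path Path to the pose CSV.
#' @return An n x 3 matrix of (roll, pitch, yaw) in radians with attribute
#'   `t`.
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "roll_deg", "pitch_deg", "yaw_deg")
  if (!all(need %in% names(df))) {
    stop(sprintf("pose file %s must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  rpy <- cbind(roll = deg2rad(df$roll_deg), pitch = deg2rad(df$pitch_deg),
               yaw = deg2rad(df$yaw_deg))
  attr(rpy, "t") <- df$t
  rpy
}

#' Write decomposed acceleration components to CSV
#'
#' Columns `t, grav_x..z, cen_x..z, tan_x..z, tra_x..z, raw_x..z`, m/s^2.
#'
#' @param comp An `accel_components`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_components_csv <- function(comp, path) {
  stopifnot(inherits(comp, "accel_components"))
  df <- data.frame(t = comp$t)
  for (part in c("grav", "cen", "tan", "tra", "raw")) {
    m <- comp[[part]]
    df[[paste0(part, "_x")]] <- m[, 1]
    df[[paste0(part, "_y")]] <- m[, 2]
    df[[paste0(part, "_z")]] <- m[, 3]
  }
  write_csv_full(df, path)
  invisible(path)
}

#' Read or write gait-event annotation files
#'
#' Events files are CSV with columns `time_s, event`, where `event` is
#' `contact` or `toe_off`.
#'
#' @param path Path to the events CSV.
#' @param side Leg label.
#' @return [read_events_csv()]: a [gait_events()].
#' @export
read_events_csv <- function(path, side = "right") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "event") %in% names(df))) {
    stop(sprintf("events file %s must have columns time_s, event", path),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$event), c("contact", "toe_off"))
  if (length(bad) > 0) {
    stop(sprintf("unknown event type(s) in %s: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  gait_events(df$time_s[df$event == "contact"],
              df$time_s[df$event == "toe_off"], side = side)
}

#' @rdname read_events_csv
#' @param events A [gait_events()].
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  df <- rbind(data.frame(time_s = events$foot_contacts, event = "contact"),
              data.frame(time_s = events$toe_offs, event = "toe_off"))
  df <- df[order(df$time_s), ]
  write_csv_full(df, path)
  invisible(path)
}

#' Write a gait-cycle ensemble to CSV
#'
#' Columns `pct`, then `<channel>_mean` and `<channel>_sd` per channel.
#'
#' @param ensemble A `gait_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "gait_ensemble"))
  df <- data.frame(pct = ensemble$grid)
  for (j in seq_along(ensemble$channels)) {
    ch <- ensemble$channels[j]
    df[[paste0(ch, "_mean")]] <- ensemble$mean[, j]
    df[[paste0(ch, "_sd")]] <- ensemble$sd[, j]
  }
  write_csv_full(df, path)
  invisible(path)
}

#' Write phase-statistics rows to CSV
#'
#' Columns `channel_pair, phase, r_mean, r_sd, rmse_mean, rmse_sd`.
#'
#' @param stats_list Named list of `phase_stats` (names become
#'   `channel_pair`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats_list, path) {
  rows <- lapply(names(stats_list), function(nm) {
    s <- stats_list[[nm]]
    data.frame(channel_pair = nm, phase = s$phase,
               r_mean = s$r_mean, r_sd = s$r_sd,
               rmse_mean = s$rmse_mean, rmse_sd = s$rmse_sd)
  })
  write_csv_full(do.call(rbind, rows), path)
  invisible(path)
}
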