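#' Define a cylindrical channel region
#'
#' The channel is a finite cylinder along the membrane normal (+z): a water is
#' inside when its lateral (x,y) minimum-image distance to the axis is at most
#' `radius` and `z_min <= z <= z_max`. The channel length `L = z_max - z_min`
#' is the normalization of the collective coordinate, so one water moving the
#' full length of the channel changes n(t) by exactly one.
#'
#' @param channel_id identifier string.
#' @param center_xy length-2 numeric, Angstrom: the pore axis position.
#' @param z_min,z_max channel extent along z, Angstrom (`z_max > z_min`).
#' @param radius cylinder radius, Angstrom (default 4, roughly an aquaporin
#'   monomer pore).
#' @return An `aqp_channel` list; `L` is stored as `z_max - z_min`.
#' @export
channel_spec <- function(channel_id, center_xy, z_min, z_max, radius = 4) {
  if (length(center_xy) != 2L || !is.numeric(center_xy))
    stop("channel '", channel_id, "': center_xy must be a numeric 2-vector")
  if (!isTRUE(z_max > z_min))
    stop("channel '", channel_id, "': z_max must be > z_min")
  if (!isTRUE(radius > 0))
    stop("channel '", channel_id, "': radius must be > 0")
  structure(list(channel_id = as.character(channel_id),
                 center_xy = as.numeric(center_xy),
                 z_min = z_min, z_max = z_max, radius = radius,
                 L = z_max - z_min),
            class = "aqp_channel")
}

# lateral minimum-image distance^2 of selected atoms to the channel axis,
# matrices [n_atoms, n_frames]
.lateral_dist2 <- function(traj, rows, channel) {
  n <- length(rows)
  dx <- matrix(traj$coords[rows, 1L, ], nrow = n) - channel$center_xy[1]
  dy <- matrix(traj$coords[rows, 2L, ], nrow = n) - channel$center_xy[2]
  if (!is.null(traj$box)) {
    lx <- traj$box[, 1L]; ly <- traj$box[, 2L]
    dx <- dx - sweep(round(sweep(dx, 2L, lx, "/")), 2L, lx, "*")
    dy <- dy - sweep(round(sweep(dy, 2L, ly, "/")), 2L, ly, "*")
  }
  dx * dx + dy * dy
}

#' Per-frame channel occupancy
#'
#' @param traj an [trajectory()].
#' @param water_ids 0-based indices of water oxygen atoms (nonempty).
#' @param channel an [channel_spec()].
#' @return An `aqp_occupancy` list: `water_ids`, `inside` (logical matrix
#'   `[n_waters, n_frames]`), `count` (per-frame number inside), `time_ps`.
#' @export
occupancy <- function(traj, water_ids, channel) {
  if (length(water_ids) == 0L) stop("empty water selection")
  rows <- as.integer(water_ids) + 1L
  d2 <- .lateral_dist2(traj, rows, channel)
  z <- matrix(traj$coords[rows, 3L, ], nrow = length(rows))
  inside <- d2 <= channel$radius^2 & z >= channel$z_min & z <= channel$z_max
  structure(list(water_ids = as.integer(water_ids), inside = inside,
                 count = colSums(inside), time_ps = frame_times(traj),
                 channel_id = channel$channel_id),
            class = "aqp_occupancy")
}

#' Occupancy count time series
#'
#' @param occ an [occupancy()] result.
#' @return data.frame with columns `time_ps`, `channel_id`, `count`.
#' @export
occupancy_count_series <- function(occ) {
  data.frame(time_ps = occ$time_ps, channel_id = occ$channel_id,
             count = occ$count, stringsAsFactors = FALSE)
}

#' Collective coordinate n(t) of water motion through a channel
#'
#' Accumulates `dn = sum_i dz_i / L` over the waters in the channel, where
#' `dz_i` are minimum-image-unwrapped z displacements and `L` the channel
#' length. An interval's displacement is counted only for waters inside the
#' channel at *both* of its endpoint frames — symmetric bookkeeping that
#' avoids double-counting entry and exit and preserves the identity that one
#' full traversal contributes exactly +1 (or -1). `n(0) = 0`.
#'
#' @inheritParams occupancy
#' @return An `aqp_ccseries` list: `time_ps`, `n` (length `n_frames`,
#'   `n[1] == 0`), `count`, `channel_id`, `dt_frame`.
#' @export
collective_coordinate <- function(traj, water_ids, channel) {
  if (traj$n_frames < 2L)
    stop("insufficient data: at least 2 frames are required")
  if (channel$L <= 0) stop("channel length L must be > 0")
  occ <- occupancy(traj, water_ids, channel)
  disp <- unwrapped_dz(traj, water_ids)
  nf <- traj$n_frames
  both <- occ$inside[, -nf, drop = FALSE] & occ$inside[, -1L, drop = FALSE]
  dn <- colSums(disp$dz * both) / channel$L
  structure(list(time_ps = occ$time_ps, n = c(0, cumsum(dn)),
                 count = occ$count, channel_id = channel$channel_id,
                 dt_frame = traj$dt_frame),
            class = "aqp_ccseries")
}

#' @export
print.aqp_ccseries <- function(x, ...) {
  cat(sprintf("<aqp_ccseries> channel %s: %d frames, n(final) = %.4f, mean occupancy = %.2f\n",
              x$channel_id, length(x$n), x$n[length(x$n)], mean(x$count)))
  invisible(x)
}

#' Tabulate collective coordinates of several channels
#'
#' @param cc_list list of [collective_coordinate()] results.
#' @return data.frame with columns `time_ps`, `channel_id`, `n`,
#'   `occupancy_count` (long format, one row per frame per channel).
#' @export
cc_table <- function(cc_list) {
  do.call(rbind, lapply(cc_list, function(cc)
    data.frame(time_ps = cc$time_ps, channel_id = cc$channel_id, n = cc$n,
               occupancy_count = cc$count, stringsAsFactors = FALSE)))
}
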