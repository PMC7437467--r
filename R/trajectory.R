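#' Construct a trajectory
#'
#' A trajectory holds per-frame Cartesian coordinates (Angstrom) for a fixed
#' atom set, per-frame orthorhombic box lengths and the time between stored
#' frames. Coordinates are stored as a 3-d array `[n_atoms, 3, n_frames]`.
#'
#' @param coords numeric array `[n_atoms, 3, n_frames]`, or an `n_atoms x 3`
#'   matrix for a single frame. Angstrom.
#' @param box per-frame box lengths: an `n_frames x 3` matrix of
#'   `(Lx, Ly, Lz)` in Angstrom, a length-3 vector recycled over frames, or
#'   `NULL` if no box information exists.
#' @param dt_frame time between stored frames, ps. Must be supplied by the
#'   caller: trajectory-file time headers are not trusted.
#' @return An `aqp_trajectory` list with elements `coords`, `box`, `dt_frame`,
#'   `n_atoms`, `n_frames`.
#' @export
trajectory <- function(coords, box = NULL, dt_frame = 1) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (!is.numeric(dt_frame) || length(dt_frame) != 1L || dt_frame <= 0)
    stop("dt_frame must be a single positive number (ps)")
  nf <- dim(coords)[3]
  if (!is.null(box)) {
    if (is.vector(box) && length(box) == 3L)
      box <- matrix(box, nf, 3L, byrow = TRUE)
    box <- as.matrix(box)
    stopifnot(ncol(box) == 3L, nrow(box) == nf)
    if (any(box <= 0)) stop("all box lengths must be > 0")
  }
  structure(list(coords = coords, box = box, dt_frame = dt_frame,
                 n_atoms = dim(coords)[1], n_frames = nf),
            class = "aqp_trajectory")
}

#' @export
print.aqp_trajectory <- function(x, ...) {
  cat(sprintf("<aqp_trajectory> %d atoms x %d frames, dt = %g ps, box: %s\n",
              x$n_atoms, x$n_frames, x$dt_frame,
              if (is.null(x$box)) "none" else
                paste(signif(x$box[1, ], 5), collapse = " x ")))
  invisible(x)
}

#' Frame times in ps
#' @param traj an [trajectory()].
#' @return Numeric vector `0, dt, 2*dt, ...` of length `n_frames`.
#' @export
frame_times <- function(traj) (seq_len(traj$n_frames) - 1) * traj$dt_frame

#' Per-interval unwrapped z-displacements
#'
#' Computes the frame-to-frame z displacement of each selected atom, corrected
#' for periodic wrapping by the minimum-image convention along z:
#' `dz <- dz - Lz * round(dz / Lz)`. Valid as long as no atom moves more than
#' `Lz/2` between stored frames.
#'
#' @param traj an [trajectory()] with at least 2 frames and box information.
#' @param atom_ids 0-based atom indices.
#' @return A list of class `aqp_displacement`: `atom_ids` and `dz`, a numeric
#'   matrix `[n_atoms, n_frames - 1]` of unwrapped displacements in Angstrom.
#' @examples
#' tr <- trajectory(array(c(0, 0, 9.9, 0, 0, 0.1), c(1, 3, 2)), box = c(10, 10, 10))
#' unwrapped_dz(tr, 0L)$dz  # +0.2: the atom crossed the periodic boundary
#' @export
unwrapped_dz <- function(traj, atom_ids) {
  if (traj$n_frames < 2L)
    stop("insufficient data: at least 2 frames are required for displacements")
  if (is.null(traj$box)) stop("trajectory has no box; Lz is required to unwrap z")
  rows <- as.integer(atom_ids) + 1L
  if (any(rows < 1L | rows > traj$n_atoms)) stop("atom_ids out of range")
  z <- matrix(traj$coords[rows, 3L, ], nrow = length(rows))
  dz <- z[, -1L, drop = FALSE] - z[, -ncol(z), drop = FALSE]
  lz <- traj$box[-1L, 3L]  # Lz of the later frame of each interval
  dz <- dz - sweep(round(sweep(dz, 2L, lz, "/")), 2L, lz, "*")
  structure(list(atom_ids = as.integer(atom_ids), dz = dz),
            class = "aqp_displacement")
}
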