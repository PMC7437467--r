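# Selectivity-filter "central area": per frame, one representative atom per
# filter residue (the atom closest to the joint center), projected onto the
# plane perpendicular to the channel axis; the quadrilateral area follows from
# angular vertex ordering plus the shoelace formula.

#' Pick one representative atom per filter residue
#'
#' The center point is the mean of the four residues' centroids (all atoms by
#' default; pass Calpha-only atom sets for a Calpha-based center); for each
#' residue the atom closest to that center is selected, ties broken by the
#' lowest atom index.
#'
#' @param traj an [trajectory()].
#' @param residue_atoms list of four integer vectors of 0-based atom indices,
#'   one per filter residue.
#' @param frame frame number (1-based).
#' @return A list: `atom_ids` (length 4, 0-based), `center` (length-3 numeric).
#' @export
pick_filter_atoms <- function(traj, residue_atoms, frame = 1L) {
  if (length(residue_atoms) != 4L)
    stop("exactly four residues define the selectivity filter")
  if (any(vapply(residue_atoms, length, 1L) == 0L))
    stop("a filter residue has no atoms")
  centroids <- t(vapply(residue_atoms, function(ids)
    colMeans(matrix(traj$coords[as.integer(ids) + 1L, , frame], ncol = 3L)),
    numeric(3)))
  center <- colMeans(centroids)
  atom_ids <- vapply(residue_atoms, function(ids) {
    ids <- sort(as.integer(ids))
    xyz <- matrix(traj$coords[ids + 1L, , frame], ncol = 3L)
    d2 <- rowSums(sweep(xyz, 2L, center)^2)
    ids[which.min(d2)]  # which.min takes the first = lowest index on ties
  }, 1L)
  list(atom_ids = atom_ids, center = center)
}

# orthonormal basis of the plane perpendicular to a unit axis
.plane_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  u <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(e1, e2)
}

#' Area of the quadrilateral spanned by four points, projected along an axis
#'
#' The points are projected onto the plane perpendicular to `axis`, ordered by
#' polar angle about their projected centroid (guaranteeing a simple, i.e.
#' non-self-intersecting, quadrilateral regardless of input order), and the
#' area evaluated by the shoelace formula. Collinear projections give area 0.
#'
#' @param points4 a 4 x 3 numeric matrix, Angstrom.
#' @param axis channel axis (need not be normalized); default +z.
#' @return Area in Angstrom^2 (>= 0).
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' central_area(sq)                  # exactly 1
#' central_area(sq[c(3, 1, 4, 2), ]) # vertex order does not matter
#' @export
central_area <- function(points4, axis = c(0, 0, 1)) {
  points4 <- as.matrix(points4)
  if (!all(dim(points4) == c(4L, 3L))) stop("points4 must be 4 x 3")
  p2 <- points4 %*% .plane_basis(axis)
  ctr <- colMeans(p2)
  ord <- order(atan2(p2[, 2] - ctr[2], p2[, 1] - ctr[1]))
  p2 <- p2[ord, ]
  nxt <- c(2:4, 1)
  abs(sum(p2[, 1] * p2[nxt, 2] - p2[nxt, 1] * p2[, 2])) / 2
}

#' Per-frame central area of a selectivity filter
#'
#' @param traj an [trajectory()].
#' @param residue_atoms list of four 0-based atom-index vectors (see
#'   [pick_filter_atoms()]).
#' @param axis channel axis; default +z (the membrane normal).
#' @param repick if `TRUE` (default) the representative atom is re-picked every
#'   frame; if `FALSE` the frame-1 atoms are reused throughout.
#' @return An `aqp_area_series` data.frame: `time_ps`, `area_A2`, plus the four
#'   chosen 0-based atom ids per frame as attribute `atom_ids` (matrix
#'   `[n_frames, 4]`).
#' @export
filter_area_series <- function(traj, residue_atoms, axis = c(0, 0, 1),
                               repick = TRUE) {
  nf <- traj$n_frames
  ids <- matrix(NA_integer_, nf, 4L)
  area <- numeric(nf)
  fixed <- if (!repick) pick_filter_atoms(traj, residue_atoms, 1L)$atom_ids
  for (k in seq_len(nf)) {
    aid <- if (repick) pick_filter_atoms(traj, residue_atoms, k)$atom_ids else fixed
    ids[k, ] <- aid
    area[k] <- central_area(matrix(traj$coords[aid + 1L, , k], ncol = 3L), axis)
  }
  out <- data.frame(time_ps = frame_times(traj), area_A2 = area)
  attr(out, "atom_ids") <- ids
  class(out) <- c("aqp_area_series", "data.frame")
  out
}

#' Relative-frequency histogram of filter areas
#'
#' Bin edges start at 0 with the given width; bin masses sum to 1.
#'
#' @param areas numeric vector of areas (Angstrom^2), or an
#'   [filter_area_series()] result.
#' @param bin_width bin width in Angstrom^2 (default 0.5).
#' @return data.frame with columns `bin_left`, `bin_right`, `rel_freq`.
#' @export
area_histogram <- function(areas, bin_width = 0.5) {
  if (inherits(areas, "aqp_area_series")) areas <- areas$area_A2
  if (!isTRUE(bin_width > 0)) stop("bin_width must be > 0")
  if (length(areas) == 0L) stop("no area values")
  n_bins <- max(1L, ceiling((max(areas) + 1e-12) / bin_width))
  edges <- (0:n_bins) * bin_width
  cnt <- tabulate(pmin(floor(areas / bin_width) + 1L, n_bins), nbins = n_bins)
  data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1L],
             rel_freq = cnt / length(areas))
}

#' Locate local maxima (modes) of an area histogram
#'
#' A bin is a mode when its mass exceeds both neighbors'; returns bin centers
#' sorted by decreasing mass.
#'
#' @param hist an [area_histogram()] result.
#' @param n_modes how many modes to return.
#' @return Numeric vector of bin centers (Angstrom^2), strongest first.
#' @export
histogram_modes <- function(hist, n_modes = 2L) {
  f <- c(0, hist$rel_freq, 0)
  i <- which(f[2:(length(f) - 1)] > f[1:(length(f) - 2)] &
             f[2:(length(f) - 1)] >= f[3:length(f)])
  ctr <- (hist$bin_left[i] + hist$bin_right[i]) / 2
  ctr[order(hist$rel_freq[i], decreasing = TRUE)][seq_len(min(n_modes, length(i)))]
}
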