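# Bilayer hydrophobic thickness as the phosphorus-to-phosphorus (P-P) leaflet
# distance, the protein-adjacent deformed thickness, and their difference
# delta = d_origin - d_deform (positive when the adjacent shell is compressed).

#' Assign phosphorus atoms to leaflets
#'
#' The bilayer midplane is the mean z of all selected P atoms in the frame;
#' leaflet membership follows the sign of `z - midplane`.
#'
#' @param traj an [trajectory()].
#' @param p_ids 0-based indices of phosphorus atoms (>= 2).
#' @param frame frame number (1-based).
#' @return A list: `leaflet` (character, `"upper"`/`"lower"`, aligned with
#'   `p_ids`), `midplane_z`.
#' @export
assign_leaflets <- function(traj, p_ids, frame = 1L) {
  if (length(p_ids) < 2L) stop("at least 2 phosphorus atoms are required")
  z <- traj$coords[as.integer(p_ids) + 1L, 3L, frame]
  mid <- mean(z)
  if (any(z == mid))
    stop("phosphorus atom exactly on the bilayer midplane; cannot assign leaflet")
  leaf <- ifelse(z > mid, "upper", "lower")
  if (length(unique(leaf)) < 2L)
    stop("degenerate bilayer: all phosphorus atoms on one side of the midplane")
  list(leaflet = leaf, midplane_z = mid)
}

#' P-P hydrophobic thickness of a frame
#'
#' Thickness is the difference between the mean z of upper-leaflet and
#' lower-leaflet phosphorus atoms inside `region` (leaflets assigned from all
#' `p_ids`). The leaflet-mean definition stays robust when the region holds
#' only a handful of lipids, which a nearest-neighbor pairing would not.
#'
#' @inheritParams assign_leaflets
#' @param region 0-based subset of `p_ids` to average over (default: all).
#' @return Thickness in Angstrom.
#' @export
thickness <- function(traj, p_ids, frame = 1L, region = NULL) {
  p_ids <- as.integer(p_ids)
  la <- assign_leaflets(traj, p_ids, frame)
  if (is.null(region)) region <- p_ids
  keep <- p_ids %in% as.integer(region)
  if (!any(keep)) stop("region selects no phosphorus atoms")
  z <- traj$coords[p_ids + 1L, 3L, frame]
  up <- keep & la$leaflet == "upper"
  lo <- keep & la$leaflet == "lower"
  if (!any(up) || !any(lo))
    stop("region has an empty leaflet (", sum(up), " upper / ", sum(lo),
         " lower P atoms)")
  mean(z[up]) - mean(z[lo])
}

#' Protein-adjacent phosphorus shell
#'
#' Selects the P atoms whose minimum lateral (x,y, minimum-image) distance to
#' any protein atom is at most `cutoff` — the "lipids contiguous to the
#' protein" whose thinning quantifies hydrophobic mismatch.
#'
#' @inheritParams assign_leaflets
#' @param protein_ids 0-based protein atom indices (nonempty).
#' @param cutoff shell cutoff, Angstrom (default 5).
#' @return 0-based subset of `p_ids`; empty with a warning if no P atom is
#'   within the cutoff.
#' @export
adjacent_shell <- function(traj, p_ids, protein_ids, cutoff = 5, frame = 1L) {
  if (length(protein_ids) == 0L) stop("empty protein selection")
  p <- traj$coords[as.integer(p_ids) + 1L, 1:2, frame, drop = FALSE]
  q <- traj$coords[as.integer(protein_ids) + 1L, 1:2, frame, drop = FALSE]
  dim(p) <- dim(p)[1:2]; dim(q) <- dim(q)[1:2]
  dx <- outer(p[, 1], q[, 1], "-")
  dy <- outer(p[, 2], q[, 2], "-")
  if (!is.null(traj$box)) {
    lx <- traj$box[frame, 1]; ly <- traj$box[frame, 2]
    dx <- dx - lx * round(dx / lx)
    dy <- dy - ly * round(dy / ly)
  }
  dmin <- sqrt(apply(dx^2 + dy^2, 1L, min))
  out <- as.integer(p_ids)[dmin <= cutoff]
  if (length(out) == 0L)
    warning("adjacent shell is empty at cutoff ", cutoff, " Angstrom")
  out
}

# block-average thickness at schedule centers: frames with |t - center| <=
# spacing/2 contribute; requires >= 1 frame per block
.scheduled_thickness <- function(traj, p_ids, region_fun, n_points, spacing_ns) {
  t_ns <- frame_times(traj) / 1000
  centers <- seq_len(n_points) * spacing_ns
  half <- spacing_ns / 2
  if (max(t_ns) < centers[n_points] - half)
    stop("insufficient data: trajectory spans ", signif(max(t_ns), 4),
         " ns but the schedule needs ", centers[n_points] - half, " ns")
  vapply(centers, function(ct) {
    fr <- which(abs(t_ns - ct) <= half + 1e-9)
    mean(vapply(fr, function(k)
      thickness(traj, p_ids, frame = k, region = region_fun(k)), 0.0))
  }, 0.0)
}

#' Protein-adjacent thickness change on the per-nanosecond schedule
#'
#' Computes the deformed thickness `d_deform` on the protein-adjacent shell
#' and the undeformed reference `d_origin`, each evaluated on a schedule of
#' `n_points` block averages spaced `spacing_ns` apart (default: five values,
#' one per nanosecond over the initial 5 ns, each a block average of the
#' frames within half a spacing of the evaluation time), and their difference
#' `delta_adj = d_origin - d_deform`. Compression of the adjacent bilayer
#' yields `delta_adj > 0`.
#'
#' @param traj protein-containing bilayer [trajectory()].
#' @param p_ids 0-based phosphorus indices in `traj`.
#' @param protein_ids 0-based protein atom indices in `traj`.
#' @param cutoff adjacent-shell cutoff, Angstrom.
#' @param reference either a list `list(trajectory =, p_ids =)` for a
#'   protein-free reference bilayer, or a single number taken as a constant
#'   `d_origin` in Angstrom.
#' @param n_points,spacing_ns the averaging schedule.
#' @return An `aqp_thickness` list: `d_origin`, `d_deform`, `delta_adj`
#'   (`= d_origin - d_deform`), per-point vectors `d_origin_ns`, `d_deform_ns`,
#'   `delta_ns`, and `cutoff`.
#' @export
delta_thickness <- function(traj, p_ids, protein_ids, cutoff = 5, reference,
                            n_points = 5L, spacing_ns = 1) {
  d_def <- .scheduled_thickness(
    traj, p_ids,
    function(k) adjacent_shell(traj, p_ids, protein_ids, cutoff, frame = k),
    n_points, spacing_ns)
  if (is.numeric(reference) && length(reference) == 1L) {
    d_org <- rep(reference, n_points)
  } else if (is.list(reference) && inherits(reference$trajectory, "aqp_trajectory")) {
    d_org <- .scheduled_thickness(reference$trajectory, reference$p_ids,
                                  function(k) NULL, n_points, spacing_ns)
  } else stop("reference must be a constant d_origin or list(trajectory=, p_ids=)")
  structure(list(d_origin = mean(d_org), d_deform = mean(d_def),
                 delta_adj = mean(d_org) - mean(d_def),
                 d_origin_ns = d_org, d_deform_ns = d_def,
                 delta_ns = d_org - d_def, cutoff = cutoff),
            class = "aqp_thickness")
}

#' @export
print.aqp_thickness <- function(x, ...) {
  cat(sprintf("<aqp_thickness> d_origin = %.3f A, d_deform = %.3f A, delta_adj = %.3f A (cutoff %g A, %d points)\n",
              x$d_origin, x$d_deform, x$delta_adj, x$cutoff, length(x$delta_ns)))
  invisible(x)
}
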