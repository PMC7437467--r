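# From n(t) to D_n and osmotic permeability: non-overlapping windows, pooled
# MSD over segments, ordinary least squares for the slope, unit conversion.

#' Cut a collective-coordinate series into equal non-overlapping windows
#'
#' The series is divided into consecutive segments spanning `window_ps` each
#' (segments share their boundary frame, so intervals are disjoint), re-based
#' so every segment starts at 0; a trailing remainder shorter than the window
#' is discarded. Treating each segment as an independent 1D random walk is
#' what turns one long n(t) series into many short ones for the MSD.
#'
#' @param cc an [collective_coordinate()] result, or any numeric vector plus
#'   `dt_frame`.
#' @param window_ps segment length in ps; must be an integer multiple of the
#'   frame spacing.
#' @param dt_frame frame spacing in ps (taken from `cc` when it is an
#'   `aqp_ccseries`).
#' @return An `aqp_segments` list: `segments` (matrix `[window/dt + 1, n_segments]`,
#'   first row all zero), `tau_ps` (lags 0..window), `window_ps`.
#' @export
segment_series <- function(cc, window_ps, dt_frame = NULL) {
  if (inherits(cc, "aqp_ccseries")) {
    n <- cc$n; dt <- cc$dt_frame
  } else {
    n <- as.numeric(cc); dt <- dt_frame
    if (is.null(dt)) stop("dt_frame is required for a bare numeric series")
  }
  k <- window_ps / dt
  if (abs(k - round(k)) > 1e-9)
    stop("window_ps (", window_ps, ") must be an integer multiple of dt_frame (",
         dt, ")")
  k <- as.integer(round(k))
  nseg <- (length(n) - 1L) %/% k
  if (nseg < 1L)
    stop("insufficient data: series spans ", (length(n) - 1L) * dt,
         " ps but the window is ", window_ps, " ps")
  idx <- outer(0:k, (seq_len(nseg) - 1L) * k, "+") + 1L
  seg <- matrix(n[idx], k + 1L, nseg)
  seg <- sweep(seg, 2L, seg[1L, ], "-")
  structure(list(segments = seg, tau_ps = (0:k) * dt, window_ps = window_ps),
            class = "aqp_segments")
}

#' Pool segment lists from several channels
#' @param ... `aqp_segments` objects with identical lag grids.
#' @return One `aqp_segments` with all segments side by side.
#' @export
pool_segments <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "aqp_segments"))
    xs <- xs[[1]]
  tau <- xs[[1]]$tau_ps
  for (x in xs) if (!isTRUE(all.equal(x$tau_ps, tau)))
    stop("cannot pool segments with different lag grids")
  structure(list(segments = do.call(cbind, lapply(xs, `[[`, "segments")),
                 tau_ps = tau, window_ps = xs[[1]]$window_ps),
            class = "aqp_segments")
}

#' Mean-squared displacement of pooled segments
#'
#' `MSD(tau) = mean over segments of (n(t0 + tau) - n(t0))^2`, with lags from
#' 0 to the window length. For an ideal 1D random walk the Einstein relation
#' `<n^2(t)> = 2 D_n t` makes this linear with slope `2 D_n`.
#'
#' @param segs an [segment_series()] or [pool_segments()] result.
#' @return An `aqp_msd` list: `tau_ps`, `msd`, `n_segments`.
#' @export
msd <- function(segs) {
  if (!inherits(segs, "aqp_segments")) stop("msd() expects aqp_segments")
  if (ncol(segs$segments) < 1L) stop("no segments to average")
  structure(list(tau_ps = segs$tau_ps,
                 msd = rowMeans(segs$segments^2),
                 n_segments = ncol(segs$segments)),
            class = "aqp_msd")
}

#' Fit the diffusion constant of n(t) from an MSD curve
#'
#' Ordinary least squares of MSD on lag time over `fit_range`, with a free
#' intercept (guards against short-time artifacts); `D_n` is half the slope.
#'
#' @param curve an [msd()] result.
#' @param fit_range length-2 numeric `(tau_lo, tau_hi)` in ps; default the full
#'   lag range.
#' @return A list: `D_n` (1/ps), `stderr` (half the slope standard error),
#'   `intercept`, `fit_range`, `n_lags`.
#' @export
fit_diffusivity <- function(curve, fit_range = NULL) {
  if (is.null(fit_range)) fit_range <- range(curve$tau_ps)
  keep <- curve$tau_ps >= fit_range[1] & curve$tau_ps <= fit_range[2]
  tau <- curve$tau_ps[keep]; y <- curve$msd[keep]
  if (length(tau) < 3L) stop("fit range contains fewer than 3 lags")
  if (diff(range(tau)) == 0) stop("degenerate fit: constant lag values")
  fit <- stats::lm(y ~ tau)
  # summary() warns on exactly linear input (zero residuals); that case is
  # legitimate here and its stderr of 0 is correct
  sm <- suppressWarnings(summary(fit))$coefficients
  list(D_n = unname(sm["tau", "Estimate"]) / 2,
       stderr = unname(sm["tau", "Std. Error"]) / 2,
       intercept = unname(sm["(Intercept)", "Estimate"]),
       fit_range = fit_range, n_lags = length(tau))
}

#' Convert D_n to osmotic permeabilities
#'
#' `p_u,mon = v_w * D_n` converted from Angstrom^3/ps to cm^3/s (factor 1e-12),
#' and `p_u,tet = 4 * p_u,mon` for the four-monomer tetramer. A negative fitted
#' slope is reported as zero permeability with a warning; the raw `D_n` is
#' retained in the output.
#'
#' @param D_n diffusion constant of n(t), 1/ps.
#' @param v_w average volume of a water molecule, Angstrom^3. Default 29.9
#'   (bulk molar volume 18.07 cm^3/mol over Avogadro's number).
#' @param stderr optional standard error of `D_n` (propagated linearly).
#' @param n_segments,window_ps optional provenance fields copied into the result.
#' @return An `aqp_permeability` list with `D_n`, `stderr`, `v_w`,
#'   `p_u_mon_cm3_s`, `p_u_tet_cm3_s` (`= 4 * p_u_mon` exactly), and provenance.
#' @export
permeability <- function(D_n, v_w = 29.9, stderr = NA_real_,
                         n_segments = NA_integer_, window_ps = NA_real_) {
  if (!isTRUE(v_w > 0)) stop("v_w must be > 0")
  D_eff <- D_n
  if (D_n < 0) {
    warning("fitted D_n is negative (", signif(D_n, 4),
            "); reporting zero permeability, raw slope retained")
    D_eff <- 0
  }
  p_mon <- v_w * D_eff * 1e-12
  structure(list(D_n = D_n, stderr = stderr, v_w = v_w,
                 p_u_mon_cm3_s = p_mon, p_u_tet_cm3_s = 4 * p_mon,
                 n_segments = n_segments, window_ps = window_ps),
            class = "aqp_permeability")
}

#' @export
print.aqp_permeability <- function(x, ...) {
  cat(sprintf("<aqp_permeability> D_n = %.4g /ps (se %.2g), p_u,mon = %.3g cm^3/s, p_u,tet = %.3g cm^3/s\n",
              x$D_n, x$stderr, x$p_u_mon_cm3_s, x$p_u_tet_cm3_s))
  invisible(x)
}

#' Permeability pipeline: trajectory to permeability estimate
#'
#' Convenience wrapper running [collective_coordinate()] per channel,
#' windowing each series, pooling all channels' segments into one MSD
#' (a 50-ns series per channel at 200-ps windows gives 250 segments per
#' channel, 1000 over a tetramer), fitting `D_n` and converting to
#' permeability.
#'
#' @param traj an [trajectory()].
#' @param water_ids 0-based water oxygen indices.
#' @param channels list of [channel_spec()]s.
#' @param window_ps window length, ps (default 200).
#' @param v_w water molecular volume, Angstrom^3.
#' @param fit_range passed to [fit_diffusivity()].
#' @return An `aqp_permeability` with attributes `msd` (the pooled curve) and
#'   `cc` (per-channel series list).
#' @export
estimate_permeability <- function(traj, water_ids, channels, window_ps = 200,
                                  v_w = 29.9, fit_range = NULL) {
  cc <- lapply(channels, function(ch) collective_coordinate(traj, water_ids, ch))
  segs <- pool_segments(lapply(cc, segment_series, window_ps = window_ps))
  curve <- msd(segs)
  fit <- fit_diffusivity(curve, fit_range)
  out <- permeability(fit$D_n, v_w = v_w, stderr = fit$stderr,
                      n_segments = curve$n_segments, window_ps = window_ps)
  attr(out, "msd") <- curve
  attr(out, "cc") <- cc
  out
}
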