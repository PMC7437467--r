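# System-level prediction: protein areal density, the p_f trend rho/delta,
# the Pearson statistic linking p_u,tet to 1/delta, and the printed-ratio
# cost arithmetic.

#' Channel proteins per square centimeter of membrane
#'
#' @param n_proteins number of channel proteins in the patch.
#' @param box_xy_area_A2 membrane cross-sectional area in Angstrom^2
#'   (typically the time average of `Lx * Ly` over analyzed frames).
#' @return Density in proteins / cm^2 (1 Angstrom^2 = 1e-16 cm^2).
#' @examples
#' protein_density(1, 100 * 100)  # 1e12 proteins per cm^2
#' @export
protein_density <- function(n_proteins, box_xy_area_A2) {
  if (!isTRUE(box_xy_area_A2 > 0)) stop("box area must be > 0")
  if (!isTRUE(n_proteins > 0)) stop("protein count must be > 0")
  n_proteins / (box_xy_area_A2 * 1e-16)
}

#' Time-averaged membrane cross-sectional area
#' @param traj an [trajectory()] with box information.
#' @return Mean of `Lx * Ly` over frames, Angstrom^2.
#' @export
box_xy_area <- function(traj) {
  if (is.null(traj$box)) stop("trajectory has no box information")
  mean(traj$box[, 1] * traj$box[, 2])
}

#' System permeability trend rho_prot / delta_adj
#'
#' The osmotic permeability of the whole membrane is proportional to the
#' protein density over the adjacent-shell thickness mismatch,
#' `p_f proportional to rho_prot / delta_adj`. The proportionality is stated
#' only for compressive mismatch, so `delta_adj <= 0` yields `NA` with a
#' flag rather than a negative "permeability".
#'
#' @param rho protein density, proteins/cm^2.
#' @param delta adjacent-shell thickness mismatch, Angstrom.
#' @return A list: `trend` (proteins/(cm^2 Angstrom), `NA` when undefined),
#'   `defined` (logical).
#' @export
pf_trend <- function(rho, delta) {
  if (!isTRUE(delta > 0)) {
    warning("delta_adj <= 0: p_f trend is undefined for non-compressive mismatch")
    return(list(trend = NA_real_, defined = FALSE))
  }
  list(trend = rho / delta, defined = TRUE)
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' Sample Pearson r with the p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t distribution with
#' `n - 2` degrees of freedom, two-sided — the standard test of zero
#' correlation.
#'
#' @param x,y paired finite numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @return A list: `r`, `p_two_sided`, `t`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p_two_sided = 0, t = Inf * sign(r), n = n))
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p_two_sided = 2 * stats::pt(-abs(tt), df = n - 2), t = tt, n = n)
}

#' Permutation p-value for the Pearson correlation
#'
#' Monte-Carlo two-sided p: the fraction of label permutations whose |r|
#' reaches the observed |r| (with the +1 correction that keeps the estimate
#' strictly positive). Offered as a small-sample cross-check of the t-based p.
#'
#' @inheritParams pearson_with_p
#' @param n_perm number of random permutations.
#' @return A list: `r`, `p_two_sided`, `n_perm`.
#' @export
pearson_permutation_p <- function(x, y, n_perm = 10000L) {
  r_obs <- stats::cor(x, y)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  r_perm <- vapply(seq_len(n_perm), function(i)
    sum(xc[sample.int(length(x))] * yc) / denom, 0.0)
  list(r = r_obs,
       p_two_sided = (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Relative protein cost and permeability gain between two compositions
#'
#' For liposomes of the same size, reports how much more protein system A
#' needs than system B and how much more permeability it delivers, both in
#' percent: `100 * (rho_a / rho_b - 1)` and `100 * (p_a / p_b - 1)`.
#'
#' @param rho_a,rho_b protein densities of systems A and B (same units).
#' @param p_a,p_b permeabilities (or permeability trends) of A and B.
#' @return A list: `protein_pct_more`, `permeability_pct_more`.
#' @export
relative_cost_comparison <- function(rho_a, p_a, rho_b, p_b) {
  if (!isTRUE(rho_b > 0) || !isTRUE(p_b > 0)) stop("reference values must be > 0")
  if (!isTRUE(rho_a > 0) || !isTRUE(p_a > 0)) stop("inputs must be > 0")
  list(protein_pct_more = 100 * (rho_a / rho_b - 1),
       permeability_pct_more = 100 * (p_a / p_b - 1))
}

#' Ranked prediction report across compositions
#'
#' Combines per-composition protein densities and adjacent-shell mismatches
#' into the `rho/delta` trend, ranks the compositions, and (when per-case
#' tetramer permeabilities are supplied) reports the Pearson correlation of
#' `p_u,tet` with `1/delta`.
#'
#' @param cases data.frame with columns `label`, `n_proteins`,
#'   `box_xy_area_A2`, `delta_adj`, and optionally `p_u_tet`.
#' @return An `aqp_prediction` list: `table` (per-case rho, inverse delta,
#'   trend, rank; undefined trends are unranked) and `pearson` (list or `NULL`).
#' @export
prediction_report <- function(cases) {
  need <- c("label", "n_proteins", "box_xy_area_A2", "delta_adj")
  miss <- setdiff(need, names(cases))
  if (length(miss)) stop("cases is missing columns: ", paste(miss, collapse = ", "))
  rho <- mapply(protein_density, cases$n_proteins, cases$box_xy_area_A2)
  trend <- ifelse(cases$delta_adj > 0, rho / cases$delta_adj, NA_real_)
  rank_out <- rep(NA_integer_, nrow(cases))
  ok <- !is.na(trend)
  rank_out[ok] <- as.integer(rank(-trend[ok], ties.method = "first"))
  tab <- data.frame(label = cases$label, rho_prot_per_cm2 = rho,
                    delta_adj_A = cases$delta_adj,
                    inverse_delta_per_A = ifelse(cases$delta_adj != 0,
                                                 1 / cases$delta_adj, NA_real_),
                    pf_trend = trend, rank = rank_out,
                    stringsAsFactors = FALSE)
  pear <- NULL
  if ("p_u_tet" %in% names(cases) && sum(ok) >= 3L)
    pear <- pearson_with_p(cases$p_u_tet[ok], 1 / cases$delta_adj[ok])
  structure(list(table = tab[order(is.na(tab$rank), tab$rank), ],
                 pearson = pear),
            class = "aqp_prediction")
}

#' @export
print.aqp_prediction <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.null(x$pearson))
    cat(sprintf("Pearson r(p_u,tet, 1/delta) = %.3f, two-sided p = %.4g, n = %d\n",
                x$pearson$r, x$pearson$p_two_sided, x$pearson$n))
  invisible(x)
}
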