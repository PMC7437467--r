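# Synthetic trajectory generators with analytically known ground truth.
# These are first-class, tested code: every analysis stage in the package is
# validated against the closed forms planted here.

#' Generate channel waters performing 1D Brownian motion
#'
#' Each channel holds `n_waters` independent waters whose z coordinates follow
#' Brownian motion with diffusion constant `D_w` (per-step increments
#' `Normal(0, 2 D_w dt)`), plus lateral jitter inside the pore radius. Because
#' the waters are independent and always inside, the collective coordinate's
#' increment variance is additive and its diffusion constant has the exact
#' closed form `D_n = n_waters * D_w / L^2`.
#'
#' Boundary modes: `"periodic"` (default) wraps z with period `L` and sets the
#' box height to `L`, so the minimum-image unwrapping recovers every true
#' increment and the closed form holds at all lag times; `"reflective"` folds
#' z at the channel ends, which confines each water and saturates its MSD at
#' `L^2/6` — with fast waters or long windows the fitted slope then falls
#' below the closed form (see the methods vignette), so reflective mode is for
#' qualitative use only.
#'
#' @param n_channels number of channels (default 4, a tetramer).
#' @param n_waters waters per channel (default 8).
#' @param L channel length, Angstrom (default 20).
#' @param radius pore radius, Angstrom (default 4).
#' @param D_w water diffusion constant along z, Angstrom^2/ps (default 0.2).
#' @param dt_frame frame spacing, ps (default 1).
#' @param n_frames number of frames.
#' @param boundary `"periodic"` or `"reflective"`.
#' @param seed RNG seed; the output is reproducible given (config, seed).
#' @return A list: `topology`, `trajectory`, `channels` (list of
#'   [channel_spec()], one per channel), `water_ids` (0-based), and `truth`
#'   with `D_n_expected = n_waters * D_w / L^2` (1/ps) and the config.
#' @export
gen_channel_water <- function(n_channels = 4L, n_waters = 8L, L = 20,
                              radius = 4, D_w = 0.2, dt_frame = 1,
                              n_frames = 1000L,
                              boundary = c("periodic", "reflective"),
                              seed = 42L) {
  boundary <- match.arg(boundary)
  stopifnot(n_channels >= 1L, n_waters >= 1L, L > 0, radius > 0, D_w >= 0,
            dt_frame > 0, n_frames >= 2L)
  set.seed(seed)
  spacing <- max(6 * radius, 20)
  box <- c(n_channels * spacing, spacing, L)
  na <- n_channels * n_waters
  coords <- array(NA_real_, c(na, 3L, n_frames))
  channels <- vector("list", n_channels)
  step_sd <- sqrt(2 * D_w * dt_frame)

  for (ch in seq_len(n_channels)) {
    cx <- (ch - 0.5) * spacing; cy <- spacing / 2
    channels[[ch]] <- channel_spec(paste0("ch", ch), c(cx, cy),
                                   z_min = 0, z_max = L, radius = radius)
    z0 <- stats::runif(n_waters, 0, L)
    steps <- matrix(stats::rnorm((n_frames - 1L) * n_waters, 0, step_sd),
                    n_frames - 1L, n_waters)
    cs <- apply(steps, 2L, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, 1L)
    z <- rbind(z0, sweep(cs, 2L, z0, "+"))
    if (boundary == "periodic") {
      z <- z %% L
    } else {
      z <- z %% (2 * L)
      z <- ifelse(z > L, 2 * L - z, z)
    }
    r <- 0.9 * radius * sqrt(stats::runif(n_frames * n_waters))
    th <- stats::runif(n_frames * n_waters, 0, 2 * pi)
    rows <- (ch - 1L) * n_waters + seq_len(n_waters)
    coords[rows, 1L, ] <- t(matrix(cx + r * cos(th), n_frames, n_waters))
    coords[rows, 2L, ] <- t(matrix(cy + r * sin(th), n_frames, n_waters))
    coords[rows, 3L, ] <- t(z)
  }
  top <- topology(rep("OH2", na), rep("TIP3", na), seq_len(na),
                  rep(LETTERS[seq_len(n_channels)], each = n_waters),
                  rep("O", na))
  list(topology = top,
       trajectory = trajectory(coords, box = box, dt_frame = dt_frame),
       channels = channels,
       water_ids = top$atom_index,
       truth = list(D_n_expected = n_waters * D_w / L^2,
                    n_channels = n_channels, n_waters = n_waters, L = L,
                    D_w = D_w, boundary = boundary, seed = seed))
}

#' Generate a two-leaflet phosphorus bilayer with a protein-adjacent dimple
#'
#' Phosphorus atoms sit on square lattices at `z = +/- d0/2`; lattice sites
#' under the protein footprint are removed. Around a ring of dummy protein
#' atoms of radius `r_prot`, both leaflets are displaced inward by
#' `(A/2) * exp(-u^2 / (2 sigma^2))` with `u` the lateral distance to the
#' protein surface, i.e. the local thickness is reduced by the full
#' `A * exp(-u^2/(2 sigma^2))`; independent Gaussian z-noise of sd `sigma_z`
#' is added per atom per frame. A protein-free reference bilayer (same
#' lattice, no exclusion, no deformation) is generated alongside.
#'
#' @param lipids_per_leaflet target lipid count per leaflet; rounded to a
#'   square lattice (default 256 = 16 x 16 at 8 Angstrom spacing, a realistic
#'   area per lipid of 64 Angstrom^2).
#' @param spacing lattice constant, Angstrom.
#' @param d0 unperturbed P-P thickness, Angstrom (default 38, typical POPC).
#' @param r_prot protein cylinder radius, Angstrom (default 20, an aquaporin
#'   tetramer footprint); must be less than half the box edge.
#' @param A deformation amplitude (total local thinning at the protein
#'   surface), Angstrom; `0 <= A < d0`.
#' @param sigma lateral decay width of the deformation, Angstrom.
#' @param sigma_z per-frame Gaussian z-noise sd, Angstrom.
#' @param n_frames frames (default 50).
#' @param dt_frame frame spacing, ps (default 100, so 50 frames span 5 ns).
#' @param n_ring number of dummy protein atoms on the ring.
#' @param seed RNG seed.
#' @return A list: `topology`, `trajectory`, `reference`
#'   (`list(topology, trajectory, p_ids)`), `p_ids`, `protein_ids` (0-based),
#'   and `truth`: a data.frame per P atom with `atom_index`, `dist_to_protein`
#'   (min lateral distance to a protein atom, Angstrom) and `thinning`
#'   (imposed local thickness reduction, Angstrom), plus
#'   `delta_expected(cutoff)`, the shell average of the imposed profile.
#' @export
gen_bilayer <- function(lipids_per_leaflet = 256L, spacing = 8, d0 = 38,
                        r_prot = 20, A = 4, sigma = 3, sigma_z = 0.5,
                        n_frames = 50L, dt_frame = 100, n_ring = 24L,
                        seed = 42L) {
  stopifnot(d0 > A, A >= 0, sigma > 0, sigma_z >= 0, n_frames >= 1L)
  n_side <- round(sqrt(lipids_per_leaflet))
  box_l <- n_side * spacing
  if (r_prot >= box_l / 2)
    stop("protein radius (", r_prot, ") must be < half the box edge (",
         box_l, ")")
  set.seed(seed)
  ctr <- box_l / 2
  g <- (seq_len(n_side) - 0.5) * spacing
  lat <- as.matrix(expand.grid(x = g, y = g))
  r_axis <- sqrt((lat[, 1] - ctr)^2 + (lat[, 2] - ctr)^2)

  # protein ring (same in every frame)
  ang <- (seq_len(n_ring) - 1) * 2 * pi / n_ring
  prot_xy <- cbind(ctr + r_prot * cos(ang), ctr + r_prot * sin(ang))

  build <- function(keep, deform) {
    xy <- lat[keep, , drop = FALSE]
    n_leaf <- nrow(xy)
    u <- pmax(0, r_axis[keep] - r_prot)
    thin <- if (deform) A * exp(-u^2 / (2 * sigma^2)) else rep(0, n_leaf)
    z_up <- d0 / 2 - thin / 2
    z_lo <- -d0 / 2 + thin / 2
    na <- 2L * n_leaf
    coords <- array(NA_real_, c(na, 3L, n_frames))
    for (k in seq_len(n_frames)) {
      noise <- stats::rnorm(na, 0, sigma_z)
      coords[, , k] <- cbind(rbind(xy, xy), c(z_up, z_lo) + noise)
    }
    list(coords = coords, n_leaf = n_leaf, thin = thin, u = u)
  }

  keep <- r_axis > r_prot          # no lipids under the protein footprint
  sys <- build(keep, deform = TRUE)
  n_p <- 2L * sys$n_leaf
  p_top <- topology(
    c(rep("P", n_p), rep("CA", n_ring)),
    c(rep("POPC", n_p), rep("PRT", n_ring)),
    c(seq_len(n_p), n_p + seq_len(n_ring)),
    c(rep(c("U", "L"), each = sys$n_leaf), rep("P", n_ring)),
    c(rep("P", n_p), rep("C", n_ring)))
  coords <- array(NA_real_, c(n_p + n_ring, 3L, n_frames))
  coords[seq_len(n_p), , ] <- sys$coords
  for (k in seq_len(n_frames))
    coords[n_p + seq_len(n_ring), , k] <- cbind(prot_xy, 0)
  box <- c(box_l, box_l, d0 + 40)
  traj <- trajectory(coords, box = box, dt_frame = dt_frame)

  ref <- build(rep(TRUE, nrow(lat)), deform = FALSE)
  n_ref <- 2L * ref$n_leaf
  ref_top <- topology(rep("P", n_ref), rep("POPC", n_ref), seq_len(n_ref),
                      rep(c("U", "L"), each = ref$n_leaf), rep("P", n_ref))
  ref_traj <- trajectory(ref$coords, box = box, dt_frame = dt_frame)

  # exact imposed profile per P atom, with an independent distance computation
  p_xy <- rbind(lat[keep, , drop = FALSE], lat[keep, , drop = FALSE])
  dmin <- vapply(seq_len(n_p), function(i) {
    dx <- p_xy[i, 1] - prot_xy[, 1]; dy <- p_xy[i, 2] - prot_xy[, 2]
    dx <- dx - box_l * round(dx / box_l); dy <- dy - box_l * round(dy / box_l)
    sqrt(min(dx^2 + dy^2))
  }, 0.0)
  truth_df <- data.frame(atom_index = seq_len(n_p) - 1L,
                         dist_to_protein = dmin,
                         thinning = c(sys$thin, sys$thin))
  delta_expected <- function(cutoff) {
    sel <- truth_df$dist_to_protein <= cutoff
    if (!any(sel)) stop("no P atom within cutoff ", cutoff)
    mean(truth_df$thinning[sel])
  }
  list(topology = p_top, trajectory = traj,
       reference = list(topology = ref_top, trajectory = ref_traj,
                        p_ids = ref_top$atom_index),
       p_ids = p_top$atom_index[seq_len(n_p)],
       protein_ids = p_top$atom_index[n_p + seq_len(n_ring)],
       truth = list(per_atom = truth_df, delta_expected = delta_expected,
                    d0 = d0, A = A, sigma = sigma, seed = seed))
}

#' Generate a two-state fluctuating selectivity-filter quadrilateral
#'
#' Four filter residues, each with an inner marker atom on a square of area
#' `A1` or `A2` (two-state symmetric Markov switching with per-frame switch
#' probability `p_switch`) plus a decoy atom farther from the center, so the
#' closest-atom picking rule is exercised every frame. Gaussian jitter of sd
#' `jitter` is added to every atom coordinate per frame.
#'
#' @param A1,A2 the two target areas, Angstrom^2 (defaults 5 and 9, the two
#'   occupied modes of a flexible filter).
#' @param p_switch per-frame state-switch probability in `[0, 1]`.
#' @param jitter vertex jitter sd, Angstrom.
#' @param n_frames frames.
#' @param dt_frame frame spacing, ps.
#' @param seed RNG seed.
#' @return A list: `topology` (residues PHE43, HIS174, THR183, ARG189 of
#'   chain A, two atoms each), `trajectory`, `residue_atoms` (list of four
#'   0-based index vectors), and `truth` with per-frame `state` (1 or 2),
#'   `areas = c(A1, A2)` and the config.
#' @export
gen_filter <- function(A1 = 5, A2 = 9, p_switch = 0.02, jitter = 0.1,
                       n_frames = 2000L, dt_frame = 10, seed = 42L) {
  stopifnot(A1 > 0, A2 > 0, p_switch >= 0, p_switch <= 1, jitter >= 0,
            n_frames >= 1L)
  set.seed(seed)
  state <- integer(n_frames)
  state[1] <- 1L
  if (n_frames > 1L) {
    flip <- stats::runif(n_frames - 1L) < p_switch
    for (k in 2:n_frames) state[k] <- if (flip[k - 1L]) 3L - state[k - 1L] else state[k - 1L]
  }
  areas <- c(A1, A2)
  ctr <- c(20, 20, 20)
  corner_dir <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)) / 2

  resno <- c(43L, 174L, 183L, 189L)
  resnm <- c("PHE", "HIS", "THR", "ARG")
  # atoms: per residue an inner marker (CZ/NE2/OG1/NH1-like, here "C1") and an
  # outer decoy ("C2") at 1.8x the corner radius
  top <- topology(rep(c("C1", "C2"), 4L),
                  rep(resnm, each = 2L),
                  rep(resno, each = 2L),
                  rep("A", 8L), rep("C", 8L))
  coords <- array(NA_real_, c(8L, 3L, n_frames))
  for (k in seq_len(n_frames)) {
    s <- sqrt(areas[state[k]])
    inner <- cbind(corner_dir * s, 0)
    outer <- cbind(corner_dir * s * 1.8, 0)
    xyz <- matrix(NA_real_, 8L, 3L)
    xyz[seq(1, 8, 2), ] <- inner
    xyz[seq(2, 8, 2), ] <- outer
    xyz <- sweep(xyz, 2L, ctr, "+") +
      matrix(stats::rnorm(24L, 0, jitter), 8L, 3L)
    coords[, , k] <- xyz
  }
  residue_atoms <- lapply(seq_len(4L), function(i)
    top$atom_index[top$residue_number == resno[i]])
  list(topology = top,
       trajectory = trajectory(coords, box = c(40, 40, 40),
                               dt_frame = dt_frame),
       residue_atoms = residue_atoms,
       truth = list(state = state, areas = areas, p_switch = p_switch,
                    jitter = jitter, seed = seed))
}
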