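# P-P thickness, the protein-adjacent shell, and delta_adj recovery.

flat_bilayer <- function(n_per_leaf = 9, z = 15, noise = 0, nf = 1,
                         box = c(30, 30, 60), seed = 1) {
  set.seed(seed)
  g <- (seq_len(sqrt(n_per_leaf)) - 0.5) * (box[1] / sqrt(n_per_leaf))
  xy <- as.matrix(expand.grid(g, g))
  frames <- replicate(nf, rbind(cbind(xy, z), cbind(xy, -z)) +
                        cbind(0, 0, rnorm(2 * nrow(xy), 0, noise)),
                      simplify = FALSE)
  list(traj = traj_from_frames(frames, box = box, dt_frame = 1000),
       p_ids = 0:(2 * nrow(xy) - 1))
}

test_that("leaflet assignment splits a bilayer and rejects degenerate input", {
  b <- flat_bilayer()
  la <- assign_leaflets(b$traj, b$p_ids)
  expect_equal(sum(la$leaflet == "upper"), 9)
  expect_equal(sum(la$leaflet == "lower"), 9)
  expect_equal(la$midplane_z, 0)
  expect_error(assign_leaflets(b$traj, 0L), "at least 2")
  # a single flat layer: every atom sits on the mean-z midplane, which is
  # the only degenerate monolayer detectable from the P atoms alone
  one_side <- traj_from_frames(list(cbind(1:4, 1, 8)), box = c(10, 10, 20))
  expect_error(assign_leaflets(one_side, 0:3), "midplane|degenerate")
})

test_that("leaflet labels match the generator's construction exactly", {
  g <- gen_bilayer(lipids_per_leaflet = 64L, n_frames = 2, seed = 13)
  la <- assign_leaflets(g$trajectory, g$p_ids)
  truth <- g$topology$chain_id[g$p_ids + 1]
  expect_equal(la$leaflet, ifelse(truth == "U", "upper", "lower"))
})

test_that("thickness is exact on noiseless bilayers and unbiased under noise", {
  b <- flat_bilayer(z = 15)
  expect_equal(thickness(b$traj, b$p_ids), 30)

  # Gaussian z-noise: estimate within 3 sigma/sqrt(N) of truth (CLT)
  bn <- flat_bilayer(n_per_leaf = 400, z = 15, noise = 1.0, seed = 2,
                     box = c(160, 160, 60))
  d <- thickness(bn$traj, bn$p_ids)
  se <- 1.0 * sqrt(1 / 400 + 1 / 400)
  expect_lt(abs(d - 30), 3 * se)

  # region with an empty leaflet errors
  upper_only <- b$p_ids[1:9]
  expect_error(thickness(b$traj, b$p_ids, region = upper_only), "leaflet")
})

test_that("adjacent_shell matches geometry and a brute-force oracle", {
  # P ring at lateral 12 A from a protein ring of radius 10: cutoff 5 keeps all
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  prot <- cbind(50 + 10 * cos(ang), 50 + 10 * sin(ang), 0)
  pring <- cbind(50 + 12 * cos(ang + 0.1), 50 + 12 * sin(ang + 0.1),
                 rep(c(15, -15), 6))
  tr <- traj_from_frames(list(rbind(pring, prot)), box = c(100, 100, 60))
  p_ids <- 0:11; prot_ids <- 12:23
  expect_setequal(adjacent_shell(tr, p_ids, prot_ids, cutoff = 5), p_ids)
  expect_warning(sh0 <- adjacent_shell(tr, p_ids, prot_ids, cutoff = 0), "empty")
  expect_length(sh0, 0)

  # brute-force all-pairs agreement on a random system
  set.seed(14)
  g <- gen_bilayer(lipids_per_leaflet = 100L, n_frames = 1, seed = 14)
  got <- adjacent_shell(g$trajectory, g$p_ids, g$protein_ids, cutoff = 6)
  xyz <- g$trajectory$coords[, , 1]
  lx <- g$trajectory$box[1, 1]; ly <- g$trajectory$box[1, 2]
  brute <- integer(0)
  for (i in g$p_ids) {
    dmin <- Inf
    for (j in g$protein_ids) {
      dx <- xyz[i + 1, 1] - xyz[j + 1, 1]; dy <- xyz[i + 1, 2] - xyz[j + 1, 2]
      dx <- dx - lx * round(dx / lx); dy <- dy - ly * round(dy / ly)
      dmin <- min(dmin, sqrt(dx^2 + dy^2))
    }
    if (dmin <= 6) brute <- c(brute, i)
  }
  expect_equal(got, brute)
})

test_that("delta_thickness recovers the planted deformation profile", {
  g <- gen_bilayer(A = 4, sigma = 3, sigma_z = 0.5, n_frames = 50, seed = 42)
  rec <- delta_thickness(g$trajectory, g$p_ids, g$protein_ids, cutoff = 5,
                         reference = g$reference)
  expect_length(rec$delta_ns, 5L)
  expect_equal(rec$delta_adj, rec$d_origin - rec$d_deform)
  expect_lt(abs(rec$delta_adj - g$truth$delta_expected(5)), 0.2)

  # a localized deformation dilutes as the shell widens
  rec15 <- delta_thickness(g$trajectory, g$p_ids, g$protein_ids, cutoff = 15,
                           reference = g$reference)
  expect_gt(abs(rec$delta_adj), abs(rec15$delta_adj))
  expect_gt(g$truth$delta_expected(5), g$truth$delta_expected(15))

  # trajectory shorter than the schedule errors
  short <- trajectory(g$trajectory$coords[, , 1:10],
                      box = g$trajectory$box[1:10, ], dt_frame = 100)
  expect_error(delta_thickness(short, g$p_ids, g$protein_ids, 5,
                               reference = g$reference), "insufficient")
})

test_that("undeformed control gives delta compatible with zero", {
  g0 <- gen_bilayer(A = 0, sigma = 3, sigma_z = 0.5, n_frames = 50, seed = 42)
  rec <- delta_thickness(g0$trajectory, g0$p_ids, g0$protein_ids, cutoff = 5,
                         reference = g0$reference)
  n_shell <- length(adjacent_shell(g0$trajectory, g0$p_ids, g0$protein_ids, 5))
  se <- 0.5 * sqrt(2) * sqrt(2 / n_shell) / sqrt(50)  # generous per-leaflet SE
  expect_lt(abs(rec$delta_adj), 3 * max(se, 0.05))
})

test_that("delta_adj is invariant under rigid z-translation", {
  g <- gen_bilayer(lipids_per_leaflet = 100L, n_frames = 10, seed = 15)
  shifted <- g$trajectory
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 7.3
  rec0 <- delta_thickness(g$trajectory, g$p_ids, g$protein_ids, 5,
                          reference = g$reference, n_points = 2, spacing_ns = 0.4)
  rec1 <- delta_thickness(shifted, g$p_ids, g$protein_ids, 5,
                          reference = g$reference, n_points = 2, spacing_ns = 0.4)
  expect_equal(rec1$delta_adj, rec0$delta_adj, tolerance = 1e-10)
})
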