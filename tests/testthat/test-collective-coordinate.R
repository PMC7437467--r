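# Channel occupancy and the collective coordinate n(t).

make_channel <- function(radius = 4, L = 20)
  channel_spec("ch", c(5, 5), z_min = 0, z_max = L, radius = radius)

test_that("occupancy applies the cylinder test with a sharp boundary", {
  ch <- make_channel()
  frames <- list(rbind(c(5, 5, 10),        # on axis, mid-channel
                       c(5 + 4.001, 5, 10),  # just outside the radius
                       c(5, 5 + 4, 10),      # exactly on the radius
                       c(5, 5, 20.001),      # just above z_max
                       c(5, 5, 0)))          # exactly at z_min
  tr <- traj_from_frames(frames, box = c(100, 100, 100))
  occ <- occupancy(tr, 0:4, ch)
  expect_equal(as.logical(occ$inside[, 1]), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(occ$count, 3)
  expect_error(occupancy(tr, integer(0), ch), "empty")
})

test_that("occupancy equals a brute-force all-atoms scan on random frames", {
  set.seed(31)
  ch <- make_channel()
  nf <- 12; na <- 40
  frames <- replicate(nf, cbind(runif(na, 0, 20), runif(na, 0, 20),
                                runif(na, -5, 25)), simplify = FALSE)
  tr <- traj_from_frames(frames, box = c(20, 20, 40))
  occ <- occupancy(tr, 0:(na - 1), ch)
  for (k in seq_len(nf)) {
    xyz <- frames[[k]]
    inside <- logical(na)
    for (i in seq_len(na)) {
      dx <- xyz[i, 1] - 5; dy <- xyz[i, 2] - 5
      dx <- dx - 20 * round(dx / 20); dy <- dy - 20 * round(dy / 20)
      inside[i] <- sqrt(dx^2 + dy^2) <= 4 && xyz[i, 3] >= 0 && xyz[i, 3] <= 20
    }
    expect_equal(as.logical(occ$inside[, k]), inside)
  }
  cnt <- occupancy_count_series(occ)
  expect_equal(cnt$count, colSums(occ$inside))
})

test_that("a full traversal contributes exactly one to n(t)", {
  ch <- make_channel(L = 20)
  z <- seq(0, 20, length.out = 101)
  tr <- traj_from_frames(lapply(z, function(zz) cbind(5, 5, zz)),
                         box = c(100, 100, 100))
  cc <- collective_coordinate(tr, 0L, ch)
  expect_equal(cc$n[1], 0)
  expect_equal(cc$n[101], 1, tolerance = 1e-9)
  # and no water inside ever means n is identically zero
  tr_out <- traj_from_frames(lapply(z, function(zz) cbind(50, 50, zz)),
                             box = c(100, 100, 100))
  expect_equal(collective_coordinate(tr_out, 0L, ch)$n, rep(0, 101))
})

test_that("n(t) on confined Brownian paths equals a direct summation oracle", {
  set.seed(32)
  ch <- make_channel()
  na <- 8; nf <- 300
  # waters stay inside: positions near the axis, z within (1, 19)
  frames <- replicate(nf, cbind(5 + runif(na, -2, 2), 5 + runif(na, -2, 2),
                                NA), simplify = FALSE)
  z <- matrix(9 + 2 * sin(outer(seq_len(nf) / 17, seq_len(na))) +
                matrix(rnorm(nf * na, 0, 0.3), nf), nf, na)
  z <- pmin(pmax(z, 1), 19)
  for (k in seq_len(nf)) frames[[k]][, 3] <- z[k, ]
  tr <- traj_from_frames(frames, box = c(100, 100, 100))
  cc <- collective_coordinate(tr, 0:(na - 1), ch)
  oracle <- c(0, cumsum(rowSums(diff(z)) / 20))
  expect_equal(cc$n, oracle, tolerance = 1e-10)
})

test_that("n(t) increments are antisymmetric, additive, and scale with 1/L", {
  set.seed(33)
  g <- gen_channel_water(n_channels = 1, n_waters = 6, n_frames = 400, seed = 33)
  ch <- g$channels[[1]]
  cc <- collective_coordinate(g$trajectory, g$water_ids, ch)

  # antisymmetry under frame-order reversal
  rev_tr <- trajectory(g$trajectory$coords[, , g$trajectory$n_frames:1],
                       box = g$trajectory$box[g$trajectory$n_frames:1, ],
                       dt_frame = g$trajectory$dt_frame)
  cc_rev <- collective_coordinate(rev_tr, g$water_ids, ch)
  expect_equal(cc_rev$n[length(cc_rev$n)], -cc$n[length(cc$n)],
               tolerance = 1e-10)

  # additivity over halves (split shares the boundary frame)
  h1 <- trajectory(g$trajectory$coords[, , 1:200],
                   box = g$trajectory$box[1:200, ], dt_frame = 1)
  h2 <- trajectory(g$trajectory$coords[, , 200:400],
                   box = g$trajectory$box[200:400, ], dt_frame = 1)
  n1 <- collective_coordinate(h1, g$water_ids, ch)$n
  n2 <- collective_coordinate(h2, g$water_ids, ch)$n
  expect_equal(n1[length(n1)] + n2[length(n2)], cc$n[length(cc$n)],
               tolerance = 1e-10)

  # doubling L halves every increment
  ch2 <- channel_spec("wide", ch$center_xy, ch$z_min, ch$z_min + 2 * ch$L,
                      radius = ch$radius)
  cc2 <- collective_coordinate(g$trajectory, g$water_ids, ch2)
  expect_equal(diff(cc2$n), diff(cc$n) / 2, tolerance = 1e-10)
})

test_that("entering and leaving through the same end contributes net zero", {
  ch <- make_channel(L = 20)
  # water dips 5 A into the channel from above and retreats the same way
  z <- c(25, 22, 19, 17, 15, 17, 19, 22, 25)
  tr <- traj_from_frames(lapply(z, function(zz) cbind(5, 5, zz)),
                         box = c(100, 100, 100))
  cc <- collective_coordinate(tr, 0L, ch)
  expect_equal(cc$n[length(cc$n)], 0, tolerance = 1e-12)
})
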