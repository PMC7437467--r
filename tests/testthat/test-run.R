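# Subcommand runner: config validation, artifacts, determinism.

test_that("synth channel-water then permeability yields a D_n report", {
  d1 <- withr::local_tempdir()
  cfg <- list(type = "channel-water", n_channels = 2L, n_waters = 4L,
              n_frames = 3000L, seed = 42L)
  gen <- aqp_run("synth", cfg, out_dir = d1)
  expect_true(file.exists(file.path(d1, "channel_water.pdb")))
  expect_true(file.exists(file.path(d1, "channel_water.dcd")))
  truth <- jsonlite::read_json(file.path(d1, "channel_water_truth.json"))
  expect_equal(truth$D_n_expected, 4 * 0.2 / 400)

  d2 <- withr::local_tempdir()
  pcfg <- list(topology = file.path(d1, "channel_water.pdb"),
               trajectory = file.path(d1, "channel_water.dcd"),
               dt_frame = 1,
               channels = truth$channels,
               window_ps = 200)
  names(pcfg$channels[[1]])  # channels carried over from the truth sidecar
  aqp_run("permeability", pcfg, out_dir = d2)
  rep <- jsonlite::read_json(file.path(d2, "permeability.json"))
  expect_true(is.numeric(rep$D_n))
  expect_equal(rep$p_u_tet_cm3_s, 4 * rep$p_u_mon_cm3_s)
  expect_true(file.exists(file.path(d2, "collective_coordinate.tsv")))
  expect_true(file.exists(file.path(d2, "run_manifest.json")))
})

test_that("thickness subcommand works end to end from files", {
  d1 <- withr::local_tempdir()
  aqp_run("synth", list(type = "bilayer", lipids_per_leaflet = 100L,
                        r_prot = 12, n_frames = 20L, seed = 42L),
          out_dir = d1)
  d2 <- withr::local_tempdir()
  cfg <- list(topology = file.path(d1, "bilayer.pdb"),
              trajectory = file.path(d1, "bilayer.dcd"),
              dt_frame = 100,
              protein_selection = list(residue_name = "PRT"),
              cutoff = 5,
              reference = list(topology = file.path(d1, "bilayer_reference.pdb"),
                               trajectory = file.path(d1, "bilayer_reference.dcd"),
                               dt_frame = 100),
              schedule_n_points = 2L, schedule_spacing_ns = 0.5)
  aqp_run("thickness", cfg, out_dir = d2)
  rep <- jsonlite::read_json(file.path(d2, "thickness.json"))
  expect_equal(rep$delta_adj, rep$d_origin - rep$d_deform, tolerance = 1e-9)
  expect_gt(rep$delta_adj, 0)  # compression planted by the generator
})

test_that("filter-area subcommand writes series and histogram", {
  d1 <- withr::local_tempdir()
  aqp_run("synth", list(type = "filter", n_frames = 300L, seed = 42L),
          out_dir = d1)
  d2 <- withr::local_tempdir()
  cfg <- list(topology = file.path(d1, "filter.pdb"),
              trajectory = file.path(d1, "filter.dcd"),
              dt_frame = 10,
              residues = list(list(chain = "A", residue_number = 43),
                              list(chain = "A", residue_number = 174),
                              list(chain = "A", residue_number = 183),
                              list(chain = "A", residue_number = 189)))
  aqp_run("filter-area", cfg, out_dir = d2)
  ser <- read.delim(file.path(d2, "filter_area.tsv"))
  expect_equal(nrow(ser), 300L)
  hist <- read.delim(file.path(d2, "filter_area_histogram.tsv"))
  expect_equal(sum(hist$rel_freq), 1, tolerance = 1e-9)
})

test_that("predict ranks four synthetic conditions by rho/delta", {
  d <- withr::local_tempdir()
  cfg <- list(cases = list(
    list(label = "1:50", n_proteins = 9, box_xy_area_A2 = 2250, delta_adj = 2.0,
         p_u_tet = 2.9e-13),
    list(label = "1:75", n_proteins = 9, box_xy_area_A2 = 4000, delta_adj = 2.4,
         p_u_tet = 2.4e-13),
    list(label = "1:100", n_proteins = 9, box_xy_area_A2 = 6760, delta_adj = 1.2,
         p_u_tet = 4.1e-13),
    list(label = "1:150", n_proteins = 9, box_xy_area_A2 = 14440, delta_adj = 2.8,
         p_u_tet = 3.0e-13)))
  aqp_run("predict", cfg, out_dir = d)
  tab <- read.delim(file.path(d, "prediction.tsv"))
  expect_equal(nrow(tab), 4L)
  rho <- 9 / (c(2250, 4000, 6760, 14440) * 1e-16)
  planted <- c("1:50", "1:75", "1:100", "1:150")[
    order(-(rho / c(2.0, 2.4, 1.2, 2.8)))]
  expect_equal(tab$label, planted)
  stats <- jsonlite::read_json(file.path(d, "prediction_stats.json"))
  expect_equal(stats$n, 4L)
})

test_that("invalid configs fail with messages naming the offending field", {
  d <- withr::local_tempdir()
  bad <- list(topology = "x.pdb", trajectory = "x.dcd", dt_frame = 1,
              channels = list(list(center_xy = c(0, 0), z_min = 10, z_max = 5)))
  expect_error(aqp_run("permeability", bad, out_dir = d), "z_max")
  expect_error(aqp_run("nonsense", list(), out_dir = d), "unknown subcommand")
  expect_error(aqp_run("predict", list(cases = list(list(label = "a"))),
                       out_dir = d), "delta_adj|n_proteins")
})

test_that("identical config and seed give byte-identical result tables", {
  run_once <- function() {
    d <- withr::local_tempdir()
    aqp_run("synth", list(type = "filter", n_frames = 200L, seed = 5L),
            out_dir = d)
    cfg <- list(topology = file.path(d, "filter.pdb"),
                trajectory = file.path(d, "filter.dcd"), dt_frame = 10,
                residues = list(list(chain = "A", residue_number = 43),
                                list(chain = "A", residue_number = 174),
                                list(chain = "A", residue_number = 183),
                                list(chain = "A", residue_number = 189)))
    o <- withr::local_tempdir()
    aqp_run("filter-area", cfg, out_dir = o)
    list(series = readBin(file.path(o, "filter_area.tsv"), "raw", 1e6),
         hist = readBin(file.path(o, "filter_area_histogram.tsv"), "raw", 1e6))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$series, b$series)
  expect_identical(a$hist, b$hist)
})
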