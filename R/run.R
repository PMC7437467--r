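# Reproducible runs: YAML config validation, subcommand dispatch, TSV/JSON
# outputs and a run manifest. `inst/exec/aqpflux` is a thin shell wrapper
# around aqp_run() for command-line use.

.req <- function(cfg, field, where = "config") {
  v <- cfg[[field]]
  if (is.null(v)) stop("missing required field '", field, "' in ", where)
  v
}

.channel_from_cfg <- function(ch, i) {
  where <- sprintf("channels[%d]", i)
  channel_spec(
    channel_id = if (is.null(ch$id)) paste0("ch", i) else ch$id,
    center_xy = unlist(.req(ch, "center_xy", where)),
    z_min = .req(ch, "z_min", where),
    z_max = .req(ch, "z_max", where),
    radius = if (is.null(ch$radius)) 4 else ch$radius)
}

.load_system <- function(cfg, where = "config") {
  top_path <- .req(cfg, "topology", where)
  trj_path <- .req(cfg, "trajectory", where)
  dt <- .req(cfg, "dt_frame", where)
  pdb <- read_pdb(top_path, dt_frame = dt)
  traj <- if (grepl("\\.dcd$", trj_path, ignore.case = TRUE))
    read_dcd(trj_path, pdb$topology, dt_frame = dt)
  else read_pdb(trj_path, dt_frame = dt)$trajectory
  list(topology = pdb$topology, trajectory = traj)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

.manifest <- function(out_dir, subcommand, cfg) {
  .write_json(list(subcommand = subcommand,
                   package = "aqpflux",
                   version = as.character(utils::packageVersion("aqpflux")),
                   config = cfg),
              file.path(out_dir, "run_manifest.json"))
}

.run_synth <- function(cfg, out_dir) {
  type <- .req(cfg, "type", "synth config")
  seed <- if (is.null(cfg$seed)) 42L else as.integer(cfg$seed)
  gen <- switch(type,
    "channel-water" = gen_channel_water(
      n_channels = cfg$n_channels %||% 4L, n_waters = cfg$n_waters %||% 8L,
      L = cfg$L %||% 20, radius = cfg$radius %||% 4, D_w = cfg$D_w %||% 0.2,
      dt_frame = cfg$dt_frame %||% 1, n_frames = cfg$n_frames %||% 1000L,
      boundary = cfg$boundary %||% "periodic", seed = seed),
    "bilayer" = gen_bilayer(
      lipids_per_leaflet = cfg$lipids_per_leaflet %||% 256L,
      d0 = cfg$d0 %||% 38, r_prot = cfg$r_prot %||% 20, A = cfg$A %||% 4,
      sigma = cfg$sigma %||% 3, sigma_z = cfg$sigma_z %||% 0.5,
      n_frames = cfg$n_frames %||% 50L, dt_frame = cfg$dt_frame %||% 100,
      seed = seed),
    "filter" = gen_filter(
      A1 = cfg$A1 %||% 5, A2 = cfg$A2 %||% 9,
      p_switch = cfg$p_switch %||% 0.02, jitter = cfg$jitter %||% 0.1,
      n_frames = cfg$n_frames %||% 2000L, dt_frame = cfg$dt_frame %||% 10,
      seed = seed),
    stop("unknown synth type '", type,
         "' (expected channel-water, bilayer or filter)"))
  prefix <- file.path(out_dir, gsub("-", "_", type))
  write_pdb(gen$topology, trajectory(gen$trajectory$coords[, , 1L, drop = FALSE],
                                     box = gen$trajectory$box[1L, ],
                                     dt_frame = gen$trajectory$dt_frame),
            paste0(prefix, ".pdb"))
  write_dcd(gen$trajectory, paste0(prefix, ".dcd"))
  truth <- gen$truth
  truth$per_atom <- NULL; truth$delta_expected <- NULL  # JSON-serializable core
  if (identical(type, "bilayer")) {
    write_pdb(gen$reference$topology,
              trajectory(gen$reference$trajectory$coords[, , 1L, drop = FALSE],
                         box = gen$reference$trajectory$box[1L, ],
                         dt_frame = gen$reference$trajectory$dt_frame),
              paste0(prefix, "_reference.pdb"))
    write_dcd(gen$reference$trajectory, paste0(prefix, "_reference.dcd"))
  }
  if (identical(type, "channel-water"))
    truth$channels <- lapply(gen$channels, function(ch)
      list(id = ch$channel_id, center_xy = ch$center_xy, z_min = ch$z_min,
           z_max = ch$z_max, radius = ch$radius))
  .write_json(truth, paste0(prefix, "_truth.json"))
  invisible(gen)
}

.run_permeability <- function(cfg, out_dir) {
  chs <- .req(cfg, "channels")  # validate the channel specs before any I/O
  channels <- lapply(seq_along(chs), function(i) .channel_from_cfg(chs[[i]], i))
  sys <- .load_system(cfg)
  waters <- select_waters(sys$topology,
                          residue_names = cfg$water_residue_names %||% .water_residues,
                          atom_names = cfg$water_atom_names %||% .water_oxygens)
  if (length(waters) == 0L) stop("water selection matched no atoms")
  est <- estimate_permeability(sys$trajectory, waters, channels,
                               window_ps = cfg$window_ps %||% 200,
                               v_w = cfg$v_w %||% 29.9)
  cc <- attr(est, "cc")
  .write_tsv(cc_table(cc), file.path(out_dir, "collective_coordinate.tsv"))
  curve <- attr(est, "msd")
  .write_tsv(data.frame(tau_ps = curve$tau_ps, msd = curve$msd),
             file.path(out_dir, "msd.tsv"))
  .write_json(list(D_n = est$D_n, stderr = est$stderr, v_w = est$v_w,
                   p_u_mon_cm3_s = est$p_u_mon_cm3_s,
                   p_u_tet_cm3_s = est$p_u_tet_cm3_s,
                   n_segments = est$n_segments, window_ps = est$window_ps),
              file.path(out_dir, "permeability.json"))
  invisible(est)
}

.run_thickness <- function(cfg, out_dir) {
  sys <- .load_system(cfg)
  p_ids <- select_atoms(sys$topology, atom_name = cfg$p_atom_name %||% "P")
  prot <- .req(cfg, "protein_selection")
  protein_ids <- do.call(select_atoms, c(list(sys$topology), prot))
  if (length(protein_ids) == 0L) stop("protein selection matched no atoms")
  ref_cfg <- .req(cfg, "reference")
  reference <- if (is.numeric(ref_cfg) || !is.null(ref_cfg$constant)) {
    if (is.numeric(ref_cfg)) ref_cfg else ref_cfg$constant
  } else {
    ref <- .load_system(ref_cfg, "reference")
    list(trajectory = ref$trajectory,
         p_ids = select_atoms(ref$topology, atom_name = cfg$p_atom_name %||% "P"))
  }
  rec <- delta_thickness(sys$trajectory, p_ids, protein_ids,
                         cutoff = cfg$cutoff %||% 5, reference = reference,
                         n_points = cfg$schedule_n_points %||% 5L,
                         spacing_ns = cfg$schedule_spacing_ns %||% 1)
  .write_tsv(data.frame(time_ns = seq_along(rec$delta_ns) *
                          (cfg$schedule_spacing_ns %||% 1),
                        d_deform = rec$d_deform_ns, d_origin = rec$d_origin_ns,
                        delta = rec$delta_ns),
             file.path(out_dir, "thickness.tsv"))
  .write_json(list(d_origin = rec$d_origin, d_deform = rec$d_deform,
                   delta_adj = rec$delta_adj, cutoff = rec$cutoff),
              file.path(out_dir, "thickness.json"))
  invisible(rec)
}

.run_filter_area <- function(cfg, out_dir) {
  sys <- .load_system(cfg)
  res <- .req(cfg, "residues")  # list of {chain, residue_number}
  if (length(res) != 4L) stop("residues must list exactly 4 filter residues")
  residue_atoms <- lapply(seq_along(res), function(i) {
    ids <- select_atoms(sys$topology,
                        chain_id = .req(res[[i]], "chain", sprintf("residues[%d]", i)),
                        residue_number = .req(res[[i]], "residue_number",
                                              sprintf("residues[%d]", i)))
    if (length(ids) == 0L)
      stop("residues[", i, "] matched no atoms")
    ids
  })
  ser <- filter_area_series(sys$trajectory, residue_atoms,
                            axis = unlist(cfg$axis %||% c(0, 0, 1)))
  .write_tsv(as.data.frame(ser), file.path(out_dir, "filter_area.tsv"))
  hist <- area_histogram(ser, bin_width = cfg$bin_width %||% 0.5)
  .write_tsv(hist, file.path(out_dir, "filter_area_histogram.tsv"))
  invisible(ser)
}

.run_predict <- function(cfg, out_dir) {
  case_cfgs <- .req(cfg, "cases")
  cases <- do.call(rbind, lapply(seq_along(case_cfgs), function(i) {
    cc <- case_cfgs[[i]]
    where <- sprintf("cases[%d]", i)
    delta <- if (!is.null(cc$thickness_json))
      jsonlite::read_json(cc$thickness_json)$delta_adj else .req(cc, "delta_adj", where)
    p_tet <- if (!is.null(cc$permeability_json))
      jsonlite::read_json(cc$permeability_json)$p_u_tet_cm3_s else cc$p_u_tet
    data.frame(label = .req(cc, "label", where),
               n_proteins = .req(cc, "n_proteins", where),
               box_xy_area_A2 = .req(cc, "box_xy_area_A2", where),
               delta_adj = delta,
               p_u_tet = if (is.null(p_tet)) NA_real_ else p_tet,
               stringsAsFactors = FALSE)
  }))
  if (all(is.na(cases$p_u_tet))) cases$p_u_tet <- NULL
  rep <- prediction_report(cases)
  .write_tsv(rep$table, file.path(out_dir, "prediction.tsv"))
  .write_json(if (is.null(rep$pearson)) list(r = NULL) else
                list(r = rep$pearson$r, p = rep$pearson$p_two_sided,
                     n = rep$pearson$n),
              file.path(out_dir, "prediction_stats.json"))
  invisible(rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an analysis subcommand from a configuration
#'
#' Dispatches one of the subcommands `synth`, `permeability`, `thickness`,
#' `filter-area`, `predict` on a validated configuration, writes the module's
#' TSV/JSON outputs plus a run manifest into `out_dir`, and returns the result
#' invisibly. Identical config and seed give byte-identical result tables.
#'
#' @param subcommand one of `"synth"`, `"permeability"`, `"thickness"`,
#'   `"filter-area"`, `"predict"`.
#' @param config a named list, or the path of a YAML file holding one.
#' @param out_dir output directory (created if missing).
#' @return The subcommand's result object, invisibly.
#' @export
aqp_run <- function(subcommand, config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runner <- switch(subcommand,
                   "synth" = .run_synth,
                   "permeability" = .run_permeability,
                   "thickness" = .run_thickness,
                   "filter-area" = .run_filter_area,
                   "predict" = .run_predict,
                   stop("unknown subcommand '", subcommand, "'"))
  res <- runner(config, out_dir)
  .manifest(out_dir, subcommand, config)
  invisible(res)
}
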