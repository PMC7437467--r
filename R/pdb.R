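# Fixed-column PDB I/O with MODEL/ENDMDL multi-frame support and CRYST1 box.
# Column layout follows the wwPDB format; residue names are read from columns
# 18-21 so 4-character CHARMM names (TIP3, POPC) survive a round trip.

.num_field <- function(lines, lineno, first, last, what) {
  txt <- substr(lines, first, last)
  val <- suppressWarnings(as.numeric(txt))
  bad <- which(is.na(val) | !nzchar(trimws(txt)))
  if (length(bad))
    stop(sprintf("parse error at line %d: bad %s field '%s'",
                 lineno[bad[1]], what, txt[bad[1]]))
  val
}

.parse_atom_lines <- function(lines, lineno) {
  short <- which(nchar(lines) < 54)
  if (length(short))
    stop(sprintf("parse error at line %d: ATOM record shorter than 54 columns",
                 lineno[short[1]]))
  list(
    atom_name = trimws(substr(lines, 13, 16)),
    residue_name = trimws(substr(lines, 18, 21)),
    chain_id = trimws(substr(lines, 22, 22)),
    residue_number = as.integer(.num_field(lines, lineno, 23, 26, "residue number")),
    x = .num_field(lines, lineno, 31, 38, "x coordinate"),
    y = .num_field(lines, lineno, 39, 46, "y coordinate"),
    z = .num_field(lines, lineno, 47, 54, "z coordinate"),
    element = trimws(substr(lines, 77, 78))
  )
}

#' Read a PDB file (single- or multi-model)
#'
#' Parses ATOM/HETATM records at fixed column positions. `MODEL`/`ENDMDL`
#' records delimit trajectory frames; a file without `MODEL` records yields a
#' single-frame trajectory. A `CRYST1` record, if present, populates the box
#' (orthorhombic only: all three angles must be 90 degrees).
#'
#' @param path path to a PDB file.
#' @param dt_frame time between models, ps (not stored in PDB; default 1).
#' @return A list with elements `topology` ([topology()]) and `trajectory`
#'   ([trajectory()]).
#' @export
read_pdb <- function(path, dt_frame = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  box <- NULL
  cry <- which(rec == "CRYST1")
  if (length(cry)) {
    l <- lines[cry[1]]
    abc <- .num_field(rep(l, 3), rep(cry[1], 3),
                      c(7, 16, 25), c(15, 24, 33), "CRYST1 length")
    ang <- .num_field(rep(l, 3), rep(cry[1], 3),
                      c(34, 41, 48), c(40, 47, 54), "CRYST1 angle")
    if (any(abs(ang - 90) > 1e-3))
      stop("only orthorhombic boxes are supported; CRYST1 angles are ",
           paste(ang, collapse = " "))
    box <- abc
  }

  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0L) {
    frames <- list(which(is_atom))
  } else {
    ends <- which(rec == "ENDMDL")
    if (length(ends) != length(model_starts))
      stop("structure error: ", length(model_starts), " MODEL but ",
           length(ends), " ENDMDL records")
    frames <- lapply(seq_along(model_starts), function(k) {
      idx <- seq(model_starts[k], ends[k])
      idx[is_atom[idx]]
    })
  }
  n_per <- vapply(frames, length, 1L)
  if (any(n_per == 0L)) stop("structure error: MODEL with no ATOM records")
  if (length(unique(n_per)) != 1L)
    stop("structure error: inconsistent atom count across MODELs: ",
         paste(unique(n_per), collapse = ", "))

  f1 <- .parse_atom_lines(lines[frames[[1]]], frames[[1]])
  top <- topology(f1$atom_name, f1$residue_name, f1$residue_number,
                  f1$chain_id, f1$element)

  nf <- length(frames); na <- n_per[1]
  coords <- array(NA_real_, c(na, 3L, nf))
  coords[, , 1L] <- cbind(f1$x, f1$y, f1$z)
  if (nf > 1L) for (k in 2:nf) {
    fk <- .parse_atom_lines(lines[frames[[k]]], frames[[k]])
    coords[, , k] <- cbind(fk$x, fk$y, fk$z)
  }
  list(topology = top,
       trajectory = trajectory(coords, box = box, dt_frame = dt_frame))
}

.format_atom_lines <- function(top, xyz) {
  name <- ifelse(nchar(top$atom_name) <= 3L,
                 sprintf(" %-3s", top$atom_name),
                 sprintf("%-4s", top$atom_name))
  sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          (seq_len(nrow(top)) - 1L) %% 99999L + 1L, name, top$residue_name,
          substr(top$chain_id, 1, 1), top$residue_number %% 10000L,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element)
}

#' Write a PDB file
#'
#' Multi-frame trajectories are written as `MODEL`/`ENDMDL` blocks; the box of
#' the first frame (if any) becomes a `CRYST1` record. Coordinates are written
#' at the format's `%8.3f` precision, so a round trip is exact to 1e-3 Angstrom.
#'
#' @param top an [topology()].
#' @param traj an [trajectory()] with `n_atoms == nrow(top)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(top, traj, path) {
  if (traj$n_atoms != nrow(top))
    stop("structure error: trajectory has ", traj$n_atoms,
         " atoms but topology has ", nrow(top))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      traj$box[1, 1], traj$box[1, 2], traj$box[1, 3], 90, 90, 90), con)
  if (traj$n_frames == 1L) {
    writeLines(.format_atom_lines(top, traj$coords[, , 1L]), con)
  } else {
    for (k in seq_len(traj$n_frames)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(.format_atom_lines(top, traj$coords[, , k]), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
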