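# CHARMM/NAMD DCD binary trajectory I/O. Fortran unformatted records (4-byte
# length markers before and after each payload), 84-byte "CORD" header block,
# optional per-frame unit-cell record of six doubles. Little-endian written;
# both endiannesses read (detected from the first record marker).

.dcd_record <- function(con, payload) {
  writeBin(length(payload), con, size = 4L, endian = "little")
  writeBin(payload, con, endian = "little")
  writeBin(length(payload), con, size = 4L, endian = "little")
}

#' Write a CHARMM/NAMD DCD trajectory
#'
#' Coordinates are truncated to single precision (the format's native float32);
#' a unit-cell record `(Lx, 90, Ly, 90, 90, Lz)` is written per frame when the
#' trajectory has box information.
#'
#' @param traj an [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  has_cell <- !is.null(traj$box)

  icntrl <- integer(20)
  icntrl[1] <- traj$n_frames      # NSET
  icntrl[2] <- 0L                 # ISTART
  icntrl[3] <- 1L                 # NSAVC
  icntrl[4] <- traj$n_frames      # NSTEP
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L               # CHARMM version flag
  hdr <- c(charToRaw("CORD"),
           writeBin(icntrl[1:9], raw(), size = 4L, endian = "little"),
           writeBin(as.numeric(traj$dt_frame), raw(), size = 4L,
                    endian = "little"),                      # DELTA, float32
           writeBin(icntrl[11:20], raw(), size = 4L, endian = "little"))
  .dcd_record(con, hdr)

  title <- sprintf("%-80s", "written by aqpflux")
  .dcd_record(con, c(writeBin(1L, raw(), size = 4L, endian = "little"),
                     charToRaw(title)))
  .dcd_record(con, writeBin(as.integer(traj$n_atoms), raw(), size = 4L,
                            endian = "little"))

  for (k in seq_len(traj$n_frames)) {
    if (has_cell) {
      cell <- c(traj$box[k, 1], 90, traj$box[k, 2], 90, 90, traj$box[k, 3])
      .dcd_record(con, writeBin(cell, raw(), size = 8L, endian = "little"))
    }
    for (d in 1:3)
      .dcd_record(con, writeBin(as.numeric(traj$coords[, d, k]), raw(),
                                size = 4L, endian = "little"))
  }
  invisible(path)
}

.read_marker <- function(con, endian) {
  m <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (length(m) == 0L) NA_integer_ else m
}

.read_record <- function(con, what, n, size, endian) {
  m1 <- .read_marker(con, endian)
  if (is.na(m1)) return(NULL)
  if (m1 != n * size) return(structure(list(), truncated = TRUE))
  v <- readBin(con, what, n, size = size, endian = endian)
  if (length(v) < n) return(structure(list(), truncated = TRUE))
  m2 <- .read_marker(con, endian)
  if (is.na(m2) || m2 != m1) return(structure(list(), truncated = TRUE))
  v
}

#' Read a CHARMM/NAMD DCD trajectory
#'
#' Validates the `CORD` magic string, reads the 84-byte header, and reads
#' frames until the header's `NSET` or end of file, whichever comes first; a
#' truncated file yields the frames actually present plus a warning. Only
#' orthorhombic unit cells are accepted (angle entries of 90 degrees, or 0 in
#' the cosine convention); triclinic cells raise an error. Frame time headers
#' are ignored: `dt_frame` is supplied by the caller.
#'
#' @param path path to a DCD file.
#' @param top the matching [topology()]; its atom count must equal the file's.
#' @param dt_frame time between stored frames, ps.
#' @return An [trajectory()].
#' @export
read_dcd <- function(path, top, dt_frame = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  endian <- "little"
  m <- .read_marker(con, endian)
  if (is.na(m)) stop("format error: empty DCD file: ", path)
  if (m != 84L) {
    endian <- "big"
    seek(con, 0)
    m <- .read_marker(con, endian)
    if (is.na(m) || m != 84L)
      stop("format error: first record is not an 84-byte DCD header")
  }
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "CORD")
    stop("format error: magic string is '", magic, "', expected 'CORD'")
  icntrl <- readBin(con, "integer", 20L, size = 4L, endian = endian)
  .read_marker(con, endian)
  nset <- icntrl[1]
  has_cell <- icntrl[11] == 1L

  tm <- .read_marker(con, endian)                       # title record
  if (!is.na(tm)) { readBin(con, "raw", tm); .read_marker(con, endian) }
  natom <- .read_record(con, "integer", 1L, 4L, endian)
  if (is.null(natom) || isTRUE(attr(natom, "truncated")))
    stop("format error: missing atom-count record")
  if (natom != nrow(top))
    stop("structure error: DCD has ", natom, " atoms but topology has ",
         nrow(top))

  coords <- vector("list", nset)
  box <- if (has_cell) matrix(NA_real_, nset, 3L) else NULL
  nread <- 0L
  repeat {
    if (nread >= nset) break
    if (has_cell) {
      cell <- .read_record(con, "numeric", 6L, 8L, endian)
      if (is.null(cell)) break
      if (isTRUE(attr(cell, "truncated"))) break
      ang <- cell[c(2, 4, 5)]
      ortho <- all(abs(ang - 90) < 1e-6) || all(abs(ang) < 1e-6)
      if (!ortho)
        stop("only orthorhombic unit cells are supported; got angles ",
             paste(signif(ang, 6), collapse = " "))
    }
    xyz <- lapply(1:3, function(d)
      .read_record(con, "numeric", natom, 4L, endian))
    if (any(vapply(xyz, is.null, TRUE)) ||
        any(vapply(xyz, function(v) isTRUE(attr(v, "truncated")), TRUE)))
      break
    nread <- nread + 1L
    coords[[nread]] <- cbind(xyz[[1]], xyz[[2]], xyz[[3]])
    if (has_cell) box[nread, ] <- cell[c(1, 3, 6)]
  }
  if (nread == 0L) stop("format error: DCD contains no complete frame")
  if (nread < nset)
    warning("DCD header advertises ", nset, " frames but only ", nread,
            " are present; returning the frames actually read")
  arr <- array(NA_real_, c(natom, 3L, nread))
  for (k in seq_len(nread)) arr[, , k] <- coords[[k]]
  trajectory(arr, box = if (has_cell) box[seq_len(nread), , drop = FALSE] else NULL,
             dt_frame = dt_frame)
}
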