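# In-code fixtures shared across test files.

# minimal topology of n identically named atoms
simple_top <- function(n, atom_name = "X", residue_name = "RES",
                       chain_id = "A") {
  topology(rep(atom_name, n), rep(residue_name, n), seq_len(n),
           rep(chain_id, n))
}

# trajectory from a list of n_atoms x 3 frame matrices
traj_from_frames <- function(frames, box = NULL, dt_frame = 1) {
  arr <- array(NA_real_, c(nrow(frames[[1]]), 3L, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  trajectory(arr, box = box, dt_frame = dt_frame)
}

# a single atom moving along a prescribed z path (x = y = 1)
z_path_traj <- function(z, box = c(10, 10, 10), dt_frame = 1) {
  traj_from_frames(lapply(z, function(zz) cbind(1, 1, zz)),
                   box = box, dt_frame = dt_frame)
}

# mixed-species topology: waters, phosphorus, protein residues
mixed_top <- function() {
  topology(
    atom_name = c("OH2", "H1", "H2", "OH2", "P", "P", "CA", "CB", "CA"),
    residue_name = c("TIP3", "TIP3", "TIP3", "HOH", "POPC", "POPC",
                     "PHE", "PHE", "HIS"),
    residue_number = c(1L, 1L, 1L, 2L, 3L, 4L, 43L, 43L, 174L),
    chain_id = c("W", "W", "W", "W", "M", "M", "A", "A", "A"))
}

# rotation matrix about a unit axis by angle (Rodrigues)
rot_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
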