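#' Construct a topology table
#'
#' A topology is a plain `data.frame` (class `aqp_topology`) with one row per
#' atom, in file order. Atom indices are 0-based and contiguous; residue
#' numbers are 1-based as in PDB files.
#'
#' @param atom_name character vector of atom names (e.g. `"OH2"`, `"P"`, `"CA"`).
#' @param residue_name character vector of residue names (e.g. `"TIP3"`, `"POPC"`).
#' @param residue_number integer vector of residue sequence numbers.
#' @param chain_id character vector of chain identifiers.
#' @param element optional character vector of element symbols (`""` if unknown).
#' @return An `aqp_topology` data.frame with columns `atom_index`, `atom_name`,
#'   `residue_name`, `residue_number`, `chain_id`, `element`.
#' @examples
#' top <- topology(c("OH2", "OH2"), c("TIP3", "TIP3"), 1:2, c("W", "W"))
#' @export
topology <- function(atom_name, residue_name, residue_number, chain_id,
                     element = NULL) {
  n <- length(atom_name)
  stopifnot(length(residue_name) == n, length(residue_number) == n,
            length(chain_id) == n)
  if (is.null(element)) element <- rep("", n)
  top <- data.frame(
    atom_index = seq_len(n) - 1L,
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_number = as.integer(residue_number),
    chain_id = as.character(chain_id),
    element = as.character(element),
    stringsAsFactors = FALSE
  )
  class(top) <- c("aqp_topology", "data.frame")
  top
}

#' @export
print.aqp_topology <- function(x, ...) {
  cat(sprintf("<aqp_topology> %d atoms, %d residues, chains: %s\n",
              nrow(x),
              length(unique(paste(x$chain_id, x$residue_number))),
              paste(unique(x$chain_id), collapse = " ")))
  invisible(x)
}

#' Select atoms by conjunction of criteria
#'
#' Returns the 0-based indices (in file order) of atoms matching *all* supplied
#' criteria; each criterion is a set-membership test. An empty result is legal
#' (downstream operations reject empty selections where they need atoms).
#'
#' @param top an [topology()] table.
#' @param atom_name,residue_name,chain_id optional character vectors; an atom
#'   matches if its value is in the set.
#' @param residue_number optional integer vector.
#' @return Integer vector of 0-based atom indices, in file order.
#' @examples
#' top <- topology(c("OH2", "H1", "P"), c("TIP3", "TIP3", "POPC"),
#'                 c(1L, 1L, 2L), c("W", "W", "M"))
#' select_atoms(top, atom_name = "OH2")              # 0
#' select_atoms(top, residue_name = c("TIP3"))       # 0 1
#' @export
select_atoms <- function(top, atom_name = NULL, residue_name = NULL,
                         residue_number = NULL, chain_id = NULL) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(atom_name))      keep <- keep & top$atom_name %in% atom_name
  if (!is.null(residue_name))   keep <- keep & top$residue_name %in% residue_name
  if (!is.null(residue_number)) keep <- keep & top$residue_number %in% as.integer(residue_number)
  if (!is.null(chain_id))       keep <- keep & top$chain_id %in% chain_id
  top$atom_index[keep]
}

# default residue/atom names recognized as water oxygens
.water_residues <- c("TIP3", "HOH", "SOL", "WAT")
.water_oxygens  <- c("OH2", "OW", "O")

#' Select water oxygen atoms
#'
#' Waters are represented by their oxygen atom. Defaults cover the common
#' naming conventions (TIP3/HOH/SOL/WAT with OH2/OW/O).
#'
#' @param top an [topology()] table.
#' @param residue_names,atom_names character vectors overriding the defaults.
#' @return Integer vector of 0-based atom indices of water oxygens.
#' @export
select_waters <- function(top, residue_names = .water_residues,
                          atom_names = .water_oxygens) {
  select_atoms(top, atom_name = atom_names, residue_name = residue_names)
}
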