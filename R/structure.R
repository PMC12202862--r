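#' Read one chain of a PDB structure
#'
#' Parses ATOM records of the requested chain: waters and ligands are
#' excluded, hydrogens are dropped, and for alternate-location duplicates the
#' highest-occupancy copy is kept (ties: first in file order). Chemically
#' modified residues with a known standard parent (MSE, SEC, SEP, ...) are
#' renamed to that parent even when stored as HETATM; other non-standard
#' residues are skipped with a warning. Only the first MODEL of a multi-model
#' file is used. Each heavy atom gets a van-der-Waals radius from the element
#' table (C 1.70, N 1.55, O 1.52, S 1.80, default 1.80 Angstrom).
#'
#' @param path Path to a PDB file.
#' @param chain_id Chain identifier (single character).
#' @param vdw_radii Named vector of van-der-Waals radii per element symbol;
#'   elements not listed get `vdw_default`.
#' @param vdw_default Fallback radius in Angstrom.
#' @return An object of class `rsalor_chain`: a list with `chain_id`,
#'   `atoms` (tibble: `residue_key`, `resno`, `insert`, `resid`, `aa`,
#'   `elety`, `element`, `x`, `y`, `z`, `occ`, `radius`), `residues` (tibble:
#'   `residue_key`, `resno`, `insert`, `aa`, in file order), `sequence`
#'   (one-letter string), and `other_atoms` (heavy atoms of all other chains,
#'   same filtering, for use as extra occluders).
#' @export
read_pdb_chain <- function(path, chain_id,
                           vdw_radii = VDW_RADII, vdw_default = VDW_DEFAULT) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE, multi = FALSE)
  atoms <- as_tibble(pdb$atom)
  chains <- sort(unique(atoms$chain))
  if (!chain_id %in% atoms$chain) {
    abort(sprintf("chain '%s' not found; available chains: %s",
                  chain_id, paste(chains, collapse = ", ")))
  }
  prep <- prepare_atoms(atoms)
  own <- prep[prep$chain == chain_id, , drop = FALSE]
  other <- prep[prep$chain != chain_id, , drop = FALSE]
  if (nrow(own) == 0L) {
    abort(sprintf("chain '%s' has no standard amino-acid residues", chain_id))
  }
  own$radius <- assign_radius(own$element, vdw_radii, vdw_default)
  other$radius <- assign_radius(other$element, vdw_radii, vdw_default)
  residues <- dplyr::distinct(own, .data$residue_key, .data$resno,
                              .data$insert, .data$aa)
  structure(
    list(
      chain_id = chain_id,
      atoms = select(own, -"chain"),
      residues = residues,
      sequence = paste(residues$aa, collapse = ""),
      other_atoms = select(other, -"chain")
    ),
    class = "rsalor_chain"
  )
}

#' @export
print.rsalor_chain <- function(x, ...) {
  cat(sprintf("<rsalor_chain> chain %s: %d residues, %d heavy atoms\n",
              x$chain_id, nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

# Shared ATOM/HETATM filtering: standard + mapped modified residues,
# no hydrogens, highest-occupancy altloc.
prepare_atoms <- function(atoms) {
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  modified <- atoms$resid %in% names(MODIFIED_PARENT)
  atoms$resid[modified] <- MODIFIED_PARENT[atoms$resid[modified]]
  standard <- atoms$resid %in% names(AA_THREE_TO_ONE)
  keep <- (atoms$type == "ATOM" | modified) & standard
  skipped <- atoms$type == "ATOM" & !standard &
    !atoms$resid %in% c("HOH", "WAT", "DOD")
  if (any(skipped)) {
    warn(sprintf("skipping %d atom(s) in unrecognized residue(s): %s",
                 sum(skipped),
                 paste(unique(atoms$resid[skipped]), collapse = ", ")))
  }
  atoms <- atoms[keep, , drop = FALSE]
  element <- atoms$elesy
  fallback <- is.na(element) | element == ""
  element[fallback] <- element_from_name(atoms$elety[fallback])
  atoms$element <- toupper(element)
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  atoms$residue_key <- paste0(atoms$resno, atoms$insert)
  atoms$aa <- unname(AA_THREE_TO_ONE[atoms$resid])
  # altloc resolution: highest occupancy wins, ties go to file order
  atoms$.ord <- seq_len(nrow(atoms))
  atoms <- atoms %>%
    group_by(.data$chain, .data$residue_key, .data$elety) %>%
    dplyr::slice_max(.data$o, n = 1, with_ties = TRUE) %>%
    dplyr::slice_min(.data$.ord, n = 1) %>%
    ungroup() %>%
    arrange(.data$.ord)
  tibble(
    chain = atoms$chain,
    residue_key = atoms$residue_key,
    resno = atoms$resno,
    insert = atoms$insert,
    resid = atoms$resid,
    aa = atoms$aa,
    elety = atoms$elety,
    element = atoms$element,
    x = atoms$x, y = atoms$y, z = atoms$z,
    occ = atoms$o
  )
}

element_from_name <- function(elety) {
  stripped <- gsub("[0-9']", "", elety)
  substr(stripped, 1, 1)
}

assign_radius <- function(element, vdw_radii, vdw_default) {
  r <- unname(vdw_radii[element])
  r[is.na(r)] <- vdw_default
  r
}
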