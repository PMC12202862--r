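# Fixture builders shared across the suite. Everything is generated in code;
# no data files are read from disk.

write_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(mapply(
    function(nm, s) c(paste0(">", nm), s),
    names(records), records,
    SIMPLIFY = FALSE
  ))
  writeLines(lines, path)
  path
}

read_msa_from <- function(records, ...) {
  read_msa(write_fasta(records), ...)
}

# Hand-built frequency table: one row per position, frequencies given as a
# named list per position (unspecified amino acids share the remainder).
make_freqs <- function(rows, gap_freq = 0) {
  aa <- aa_alphabet()
  mat <- t(vapply(rows, function(r) {
    v <- rep((1 - sum(unlist(r))) / (20 - length(r)), 20)
    names(v) <- aa
    v[names(r)] <- unlist(r)
    v
  }, numeric(20)))
  out <- tibble::tibble(
    position = seq_along(rows),
    column = seq_along(rows),
    wt = vapply(rows, function(r) names(r)[1], character(1)),
    gap_freq = rep_len(gap_freq, length(rows)),
    coverage = 1,
    zero_coverage = FALSE
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  class(out) <- c("rsalor_freqs", class(out))
  out
}

# Minimal structure chain built directly from atom coordinates, for
# closed-form SASA tests on arbitrary atom systems.
make_chain <- function(xyz, elements = rep("C", nrow(xyz)),
                       aa = "A", resno = rep(1L, nrow(xyz))) {
  radii_tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  radius <- unname(radii_tab[elements])
  radius[is.na(radius)] <- 1.80
  atoms <- tibble::tibble(
    residue_key = as.character(resno),
    resno = as.integer(resno),
    insert = "",
    resid = "ALA",
    aa = rep_len(aa, nrow(xyz)),
    elety = elements,
    element = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1,
    radius = radius
  )
  residues <- dplyr::distinct(atoms, residue_key, resno, insert, aa)
  structure(
    list(
      chain_id = "A",
      atoms = atoms,
      residues = residues,
      sequence = paste(residues$aa, collapse = ""),
      other_atoms = atoms[0, ]
    ),
    class = "rsalor_chain"
  )
}

# Target whose residues never repeat within any short window (the 20-letter
# alphabet cycled), so window deletions leave no ambiguity (no alignment
# ties) for the structure-mapping round trip.
cyclic_target <- function(n = 50) {
  paste(rep_len(aa_alphabet(), n), collapse = "")
}

rnorm3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_alignment_records <- function(n_records, n_cols, gap_rate = 0.1) {
  aa <- c(aa_alphabet(), "-")
  probs <- c(rep((1 - gap_rate) / 20, 20), gap_rate)
  recs <- vapply(seq_len(n_records), function(i) {
    paste(sample(aa, n_cols, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  # target must not be all gaps
  recs[1] <- paste(sample(aa_alphabet(), n_cols, replace = TRUE),
                   collapse = "")
  names(recs) <- paste0("s", seq_len(n_records))
  recs
}
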