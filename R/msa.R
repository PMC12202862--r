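#' Read an aligned FASTA multiple sequence alignment
#'
#' Parses an aligned FASTA file whose first record is the target protein.
#' Sequences are uppercased, `.` insertion states are converted to `-`, and
#' non-standard residue symbols (`X`, `B`, `Z`, `J`, `U`, `O`) in homolog rows
#' are replaced by gaps so that the internal alphabet is the 20 standard amino
#' acids plus `-`. Non-standard symbols in the target sequence are an error.
#'
#' @param path Path to an aligned FASTA file. The first record is the target.
#' @param gap_chars Characters normalized to the internal gap symbol `-`.
#' @return An object of class `rsalor_msa`: a list with elements
#'   `records` (named character vector of aligned sequences),
#'   `target_sequence` (target with gaps removed), `column_index` (aligned
#'   column of each target position), `weights` (per-record, `NA` until
#'   [msa_weights()] is called), `n_effective`, and `params`.
#' @seealso [curate_msa()], [msa_weights()], [msa_frequencies()]
#' @export
read_msa <- function(path, gap_chars = c("-", ".")) {
  if (!file.exists(path)) abort(paste0("MSA file not found: ", path))
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) == 0L) abort("empty MSA file: no FASTA records found")
  records <- toupper(as.character(aln))
  names(records) <- names(aln)
  for (g in setdiff(gap_chars, GAP)) {
    records <- gsub(g, GAP, records, fixed = TRUE)
  }
  lens <- nchar(records)
  if (length(unique(lens)) != 1L) {
    abort(sprintf(
      "ragged alignment: record lengths differ (%s)",
      paste(unique(lens), collapse = ", ")
    ))
  }
  bad <- grepl(paste0("[^", paste(AA_ORDER, collapse = ""),
                      paste(NONSTANDARD_AA, collapse = ""), "-]"), records)
  if (any(bad)) {
    abort(sprintf("unrecognized symbols in %d record(s), e.g. '%s'",
                  sum(bad), names(records)[which(bad)[1]]))
  }
  target_aln <- records[[1]]
  target <- gsub(GAP, "", target_aln, fixed = TRUE)
  if (nchar(target) == 0L) abort("target sequence (first record) is all gaps")
  if (grepl(paste0("[", paste(NONSTANDARD_AA, collapse = ""), "]"), target)) {
    abort("target sequence contains non-standard residues (X/B/Z/J/U/O)")
  }
  n_nonstd <- sum(vapply(
    NONSTANDARD_AA,
    function(s) sum(lengths(regmatches(records[-1], gregexpr(s, records[-1], fixed = TRUE)))),
    numeric(1)
  ))
  if (length(records) > 1L && n_nonstd > 0) {
    records[-1] <- gsub(paste0("[", paste(NONSTANDARD_AA, collapse = ""), "]"),
                        GAP, records[-1])
    warn(sprintf("%d non-standard residue symbol(s) in homologs treated as gaps",
                 n_nonstd))
  }
  new_msa(records, params = list(path = path))
}

new_msa <- function(records, weights = NULL, params = list()) {
  target_aln <- records[[1]]
  columns <- which(strsplit(target_aln, "", fixed = TRUE)[[1]] != GAP)
  structure(
    list(
      records = records,
      target_sequence = gsub(GAP, "", target_aln, fixed = TRUE),
      column_index = columns,
      weights = weights,
      n_effective = if (is.null(weights)) NA_real_ else sum(weights),
      params = params
    ),
    class = "rsalor_msa"
  )
}

#' @export
print.rsalor_msa <- function(x, ...) {
  cat(sprintf(
    "<rsalor_msa> %d records, aligned length %d, target length %d\n",
    length(x$records), nchar(x$records[[1]]), nchar(x$target_sequence)
  ))
  if (!is.null(x$weights)) {
    cat(sprintf("  weighted: n_effective = %.4f\n", x$n_effective))
  }
  invisible(x)
}

#' @export
length.rsalor_msa <- function(x) length(x$records)

#' Pairwise sequence identity over target-covered columns
#'
#' Identity between two aligned records is the fraction of masked columns in
#' which both carry the same non-gap symbol. The denominator is the number of
#' masked columns (by default, columns where the alignment's target is
#' non-gap), so gap-vs-symbol and gap-vs-gap both count as mismatches. This
#' target-anchored denominator keeps identities comparable across all record
#' pairs of one alignment.
#'
#' @param a,b Aligned sequences (equal-length character strings).
#' @param mask Integer or logical index of the columns to score over.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, mask) {
  if (nchar(a) != nchar(b)) abort("aligned lengths differ")
  ca <- strsplit(a, "", fixed = TRUE)[[1]][mask]
  cb <- strsplit(b, "", fixed = TRUE)[[1]][mask]
  if (length(ca) == 0L) abort("empty column mask")
  bad <- c(GAP, NONSTANDARD_AA)
  sum(ca == cb & !(ca %in% bad)) / length(ca)
}

#' Curate an alignment: deduplicate and drop twilight-zone homologs
#'
#' Removes byte-identical duplicate records (keeping the first occurrence) and
#' homologs whose identity to the target, computed over target-covered columns
#' (see [pairwise_identity()]), falls below `twilight`. The target is always
#' retained. Very distant sequences add noise rather than signal to
#' conservation-based scores, hence the filter; the default cutoff 0.35 sits
#' at the classic twilight-zone boundary of sequence homology.
#'
#' @param msa An `rsalor_msa`.
#' @param twilight Identity-to-target cutoff in `[0, 1)`; records strictly
#'   below it are dropped. `0` disables identity filtering.
#' @return A curated `rsalor_msa` (weights are reset).
#' @export
curate_msa <- function(msa, twilight = 0.35) {
  stopifnot(inherits(msa, "rsalor_msa"))
  if (twilight < 0 || twilight >= 1) abort("twilight cutoff must be in [0, 1)")
  records <- msa$records
  keep <- !duplicated(unname(records))
  keep[1] <- TRUE
  records <- records[keep]
  if (twilight > 0 && length(records) > 1L) {
    mask <- msa$column_index
    id_to_target <- vapply(
      records[-1], pairwise_identity, numeric(1),
      a = records[[1]], mask = mask
    )
    records <- c(records[1], records[-1][id_to_target >= twilight])
  }
  if (length(records) == 1L && length(msa$records) > 1L) {
    warn("curation removed every homolog; only the target remains")
  }
  params <- msa$params
  params$twilight <- twilight
  new_msa(records, params = params)
}
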