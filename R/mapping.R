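#' Map structure residues onto target sequence positions
#'
#' Aligns the structure-derived sequence to the MSA target with a global
#' Needleman-Wunsch alignment (BLOSUM62, affine gaps: open 10, extend 0.5)
#' and turns aligned non-gap pairs into a position-to-residue map. The map
#' tolerates structures with missing residues (those target positions stay
#' unmapped) and homologous templates (mismatched aligned pairs are mapped
#' but counted in `n_mismatched`, since RSA is robust to small sequence
#' changes). The mapping is injective and order-preserving by construction.
#'
#' @param target_sequence Target amino-acid string (no gaps).
#' @param chain An `rsalor_chain`, or directly a structure-derived sequence.
#' @param min_identity_warn Warn when the identity over aligned pairs falls
#'   below this fraction (default 0.7).
#' @param min_identity Hard floor: below this the structure is rejected as
#'   not matching the target (default 0.3).
#' @return A tibble of class `rsalor_map` with one row per target position:
#'   `position`, `target_aa`, `residue_key` (`NA` if unmapped), `struct_aa`,
#'   `mismatch`. Attributes: `aligned_identity`, `n_mapped`, `n_mismatched`.
#' @export
align_and_map <- function(target_sequence, chain,
                          min_identity_warn = 0.7, min_identity = 0.3) {
  struct_seq <- if (inherits(chain, "rsalor_chain")) chain$sequence else chain
  residue_keys <- if (inherits(chain, "rsalor_chain")) {
    chain$residues$residue_key
  } else {
    as.character(seq_len(nchar(struct_seq)))
  }
  if (nchar(target_sequence) == 0L || nchar(struct_seq) == 0L) {
    abort("both target and structure sequences must be non-empty")
  }
  aln <- Biostrings::pairwiseAlignment(
    target_sequence, struct_seq,
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  L <- nchar(target_sequence)
  map_key <- rep(NA_character_, L)
  map_aa <- rep(NA_character_, L)
  ti <- 0L
  si <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ti <- ti + 1L
    if (sub[k] != "-") si <- si + 1L
    if (pat[k] != "-" && sub[k] != "-") {
      map_key[ti] <- residue_keys[si]
      map_aa[ti] <- sub[k]
    }
  }
  target_aa <- strsplit(target_sequence, "", fixed = TRUE)[[1]]
  mismatch <- !is.na(map_key) & map_aa != target_aa
  n_mapped <- sum(!is.na(map_key))
  n_mismatched <- sum(mismatch)
  aligned_identity <- if (n_mapped > 0) {
    (n_mapped - n_mismatched) / n_mapped
  } else {
    0
  }
  if (aligned_identity < min_identity) {
    abort(sprintf(
      "structure does not match target: aligned identity %.2f below floor %.2f",
      aligned_identity, min_identity
    ))
  }
  if (aligned_identity < min_identity_warn) {
    warn(sprintf(
      "structure is a distant homolog of the target (aligned identity %.2f)",
      aligned_identity
    ))
  }
  out <- tibble(
    position = seq_len(L),
    target_aa = target_aa,
    residue_key = map_key,
    struct_aa = map_aa,
    mismatch = mismatch
  )
  attr(out, "aligned_identity") <- aligned_identity
  attr(out, "n_mapped") <- n_mapped
  attr(out, "n_mismatched") <- n_mismatched
  class(out) <- c("rsalor_map", class(out))
  out
}

# BLOSUM62 over the 20 standard residues, loaded once from Biostrings.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_ORDER, AA_ORDER]
    }
    cache
  }
})

#' Relative solvent accessibility at a target position
#'
#' Looks up the clipped RSA of the structure residue mapped to target
#' position `i`; returns `NA` when the position is unmapped (missing from
#' the structure). Positions mapped to a mismatched residue of a homologous
#' template still return that residue's RSA.
#'
#' @param map An `rsalor_map` from [align_and_map()].
#' @param profile An `rsalor_rsa` from [rsa_profile()].
#' @param i Target position(s), 1-based.
#' @return Numeric vector of clipped RSA percentages, `NA` where missing.
#' @export
rsa_for_position <- function(map, profile, i) {
  if (any(i < 1L | i > nrow(map))) {
    abort(sprintf("position out of range 1..%d", nrow(map)))
  }
  keys <- map$residue_key[i]
  profile$rsa_clipped[match(keys, profile$residue_key)]
}

# RSA for every target position as a plain vector (NA where unmapped).
rsa_vector <- function(map, profile) {
  profile$rsa_clipped[match(map$residue_key, profile$residue_key)]
}
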