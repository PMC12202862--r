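#' Regularized weighted amino-acid frequencies per target position
#'
#' For each target position `i` (aligned column `c`), the weighted count of
#' amino acid `a` is `n_i(a) = sum_s w_s * 1[s_c == a]` and the coverage is
#' `C_i = sum_a n_i(a)`. Frequencies are regularized with an additive
#' pseudocount `lambda` per amino acid:
#' `f_i(a) = (n_i(a) + lambda) / (C_i + 20 * lambda)`,
#' which bounds every frequency away from 0 and 1 so the log-odd ratio never
#' diverges, and dominates only when the effective number of sequences is
#' small. Gaps (and non-standard symbols, already normalized to gaps) are
#' excluded from the amino-acid denominator; the weighted gap fraction is
#' reported separately. A position whose column is all gaps has uniform
#' frequencies `1/20` and is flagged in `zero_coverage`.
#'
#' @param msa An `rsalor_msa` with weights (see [msa_weights()]); if weights
#'   are absent, unit weights are used.
#' @param pseudocount Regularization strength `lambda > 0` (default 5).
#' @return A tibble of class `rsalor_freqs` with one row per target position:
#'   `position`, `column` (aligned column), `wt` (target amino acid),
#'   `gap_freq`, `coverage`, `zero_coverage`, and one column per amino acid
#'   in [aa_alphabet()] order. Attributes: `pseudocount`, `n_effective`,
#'   `target_sequence`.
#' @export
msa_frequencies <- function(msa, pseudocount = 5) {
  stopifnot(inherits(msa, "rsalor_msa"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("pseudocount must be a positive number")
  }
  w <- msa$weights
  if (is.null(w)) w <- rep(1, length(msa$records))
  codes <- encode_records(msa$records, msa$column_index)
  L <- ncol(codes)
  counts <- matrix(0, nrow = L, ncol = 20L,
                   dimnames = list(NULL, AA_ORDER))
  for (a in 1:20) counts[, a] <- colSums(w * (codes == a))
  coverage <- rowSums(counts)
  gap_freq <- colSums(w * (codes == 0L)) / sum(w)
  freqs <- (counts + pseudocount) / (coverage + 20 * pseudocount)
  target_aa <- strsplit(msa$target_sequence, "", fixed = TRUE)[[1]]
  zero <- coverage == 0
  if (any(zero)) {
    warn(sprintf("%d position(s) have zero amino-acid coverage (all-gap columns)",
                 sum(zero)))
  }
  out <- tibble(
    position = seq_len(L),
    column = msa$column_index,
    wt = target_aa,
    gap_freq = gap_freq,
    coverage = coverage,
    zero_coverage = zero
  )
  out <- dplyr::bind_cols(out, as_tibble(freqs))
  attr(out, "pseudocount") <- pseudocount
  attr(out, "n_effective") <- sum(w)
  attr(out, "target_sequence") <- msa$target_sequence
  class(out) <- c("rsalor_freqs", class(out))
  out
}

# Extract the L x 20 frequency matrix from an rsalor_freqs tibble.
freq_matrix <- function(freqs) {
  m <- as.matrix(freqs[, AA_ORDER])
  rownames(m) <- freqs$position
  m
}
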