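#' Log-odd ratio of wild-type and mutant frequencies
#'
#' The evolutionary score of a substitution `wt -> mt` at target position `i`
#' is the difference of frequency logits,
#' `LOR(i, wt, mt) = log( f_i(wt) / (1 - f_i(wt)) ) - log( f_i(mt) / (1 - f_i(mt)) )`,
#' with natural logarithms. It is positive when the wild type is more
#' represented than the mutant in the alignment column (the usual signature
#' of a destabilizing or fitness-decreasing mutation) and exactly
#' antisymmetric: `LOR(i, a, b) = -LOR(i, b, a)`.
#'
#' @param freqs An `rsalor_freqs` table from [msa_frequencies()].
#' @param position Target position(s), 1-based.
#' @param wt,mt One-letter wild-type and mutant amino acids (vectorized,
#'   recycled against `position`).
#' @return Numeric vector of LOR values.
#' @export
lor_score <- function(freqs, position, wt, mt) {
  stopifnot(inherits(freqs, "rsalor_freqs"))
  n <- max(length(position), length(wt), length(mt))
  position <- rep_len(position, n)
  wt <- rep_len(wt, n)
  mt <- rep_len(mt, n)
  if (any(wt == mt)) abort("wild-type and mutant amino acids must differ")
  if (any(position < 1L | position > nrow(freqs))) {
    abort(sprintf("position out of range 1..%d", nrow(freqs)))
  }
  if (any(!wt %in% AA_ORDER) || any(!mt %in% AA_ORDER)) {
    abort("amino acids must be standard one-letter codes")
  }
  fm <- freq_matrix(freqs)
  fwt <- fm[cbind(position, match(wt, AA_ORDER))]
  fmt <- fm[cbind(position, match(mt, AA_ORDER))]
  if (any(fwt <= 0 | fwt >= 1 | fmt <= 0 | fmt >= 1)) {
    abort("frequencies must lie strictly inside (0, 1); regularize the table")
  }
  logit(fwt) - logit(fmt)
}

logit <- function(p) log(p / (1 - p))

#' Scale a LOR score by the complement of relative solvent accessibility
#'
#' `RSALOR = (1 - RSA/100) * LOR`: mutations of buried residues (RSA near 0)
#' keep their full evolutionary score, while mutations of fully exposed
#' residues (RSA 100) are scored neutral. The RSA factor is in `[0, 1]`, so
#' the sign of RSALOR equals the sign of LOR and its magnitude never exceeds
#' the LOR magnitude.
#'
#' @param lor Numeric LOR value(s).
#' @param rsa Clipped relative solvent accessibility in percent, in
#'   `[0, 100]`; `NA` propagates (score missing without a mapped residue).
#' @return Numeric vector of RSALOR values.
#' @export
rsalor_score <- function(lor, rsa) {
  if (any(rsa < 0 | rsa > 100, na.rm = TRUE)) {
    abort("rsa must be a clipped percentage in [0, 100]")
  }
  (1 - rsa / 100) * lor
}

#' Score the full single-site mutational landscape
#'
#' Produces one record per possible single-site substitution of the target
#' sequence: 19 mutant amino acids at each of the L positions, in
#' deterministic order (position, then [aa_alphabet()] order). Positions
#' without a mapped structure residue (or when no structure is supplied) get
#' `NA` RSA and RSALOR but keep their LOR.
#'
#' @param msa A curated, weighted `rsalor_msa`.
#' @param freqs An `rsalor_freqs` table; computed from `msa` if omitted.
#' @param map Optional `rsalor_map` from [align_and_map()].
#' @param profile Optional `rsalor_rsa` from [rsa_profile()].
#' @param pseudocount Used only when `freqs` is omitted.
#' @return A tibble of class `rsalor_landscape` with columns `mutation`,
#'   `position`, `aa_wt`, `aa_mt`, `gap_freq`, `wt_freq`, `mt_freq`, `rsa`,
#'   `lor`, `rsalor` (exactly `19 * nchar(target)` rows).
#' @export
score_landscape <- function(msa, freqs = NULL, map = NULL, profile = NULL,
                            pseudocount = 5) {
  stopifnot(inherits(msa, "rsalor_msa"))
  if (is.null(freqs)) freqs <- msa_frequencies(msa, pseudocount)
  target_aa <- strsplit(msa$target_sequence, "", fixed = TRUE)[[1]]
  L <- length(target_aa)
  rsa <- if (!is.null(map) && !is.null(profile)) {
    rsa_vector(map, profile)
  } else {
    rep(NA_real_, L)
  }
  fm <- freq_matrix(freqs)
  grid <- tidyr::expand_grid(position = seq_len(L), aa_mt = AA_ORDER)
  grid$aa_wt <- target_aa[grid$position]
  grid <- grid[grid$aa_mt != grid$aa_wt, , drop = FALSE]
  fwt <- fm[cbind(grid$position, match(grid$aa_wt, AA_ORDER))]
  fmt <- fm[cbind(grid$position, match(grid$aa_mt, AA_ORDER))]
  out <- tibble(
    mutation = paste0(grid$aa_wt, grid$position, grid$aa_mt),
    position = grid$position,
    aa_wt = grid$aa_wt,
    aa_mt = grid$aa_mt,
    gap_freq = freqs$gap_freq[grid$position],
    wt_freq = fwt,
    mt_freq = fmt,
    rsa = rsa[grid$position],
    lor = logit(fwt) - logit(fmt)
  )
  out$rsalor <- rsalor_score(out$lor, out$rsa)
  attr(out, "target_sequence") <- msa$target_sequence
  class(out) <- c("rsalor_landscape", class(out))
  out
}

#' Parse mutation strings
#'
#' Accepts the common deep-mutational-scanning grammar `"<wt><pos><mt>"`
#' (e.g. `"A42G"`), with multi-site mutations joined by `":"`
#' (`"A42G:D77K"`). Sites are canonicalized to increasing position order.
#'
#' @param x Character vector of mutation strings.
#' @param target Optional target sequence; when given, each site's wild-type
#'   letter is validated against it.
#' @return A tibble with columns `mutation` (input string), `site` (index
#'   within the mutation), `position`, `aa_wt`, `aa_mt`.
#' @export
parse_mutations <- function(x, target = NULL) {
  one <- function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) {
      abort(sprintf("malformed mutation string: '%s'", s))
    }
    pos <- as.integer(vapply(m, `[`, "", 3L))
    wt <- vapply(m, `[`, "", 2L)
    mt <- vapply(m, `[`, "", 4L)
    ord <- order(pos)
    pos <- pos[ord]; wt <- wt[ord]; mt <- mt[ord]
    if (anyDuplicated(pos)) {
      abort(sprintf("duplicate positions in multi-site mutation '%s'", s))
    }
    if (any(wt == mt)) {
      abort(sprintf("wild-type equals mutant in '%s'", s))
    }
    if (any(!wt %in% AA_ORDER) || any(!mt %in% AA_ORDER)) {
      abort(sprintf("non-standard amino acid in '%s'", s))
    }
    tibble(mutation = s, site = seq_along(pos),
           position = pos, aa_wt = wt, aa_mt = mt)
  }
  out <- dplyr::bind_rows(lapply(x, one))
  if (!is.null(target)) {
    target_aa <- strsplit(target, "", fixed = TRUE)[[1]]
    if (any(out$position > length(target_aa))) {
      abort("mutation position beyond target length")
    }
    mismatch <- out$aa_wt != target_aa[out$position]
    if (any(mismatch)) {
      abort(sprintf(
        "wild-type mismatch with target at position(s) %s",
        paste(out$position[mismatch], collapse = ", ")
      ))
    }
  }
  out
}

#' Score multi-site mutations by additivity
#'
#' Under the no-epistasis approximation, the effect of a multiple mutation is
#' the sum of the effects of its single-site components. LOR sums are always
#' available; the RSALOR sum is missing whenever any site lacks a mapped
#' structure residue, rather than silently mixing scales.
#'
#' @param landscape An `rsalor_landscape` from [score_landscape()].
#' @param mutations Character vector of (possibly multi-site) mutation
#'   strings, e.g. `c("A2G", "A2G:D5K")`.
#' @return A tibble with one row per input mutation: `mutation`, `n_sites`,
#'   `lor`, `rsalor` (`NA` when any site's RSA is missing).
#' @export
score_multi <- function(landscape, mutations) {
  stopifnot(inherits(landscape, "rsalor_landscape"))
  target <- attr(landscape, "target_sequence")
  sites <- parse_mutations(mutations, target = target)
  sites$single <- paste0(sites$aa_wt, sites$position, sites$aa_mt)
  idx <- match(sites$single, landscape$mutation)
  if (anyNA(idx)) {
    abort(sprintf("mutation '%s' not present in the landscape",
                  sites$single[which(is.na(idx))[1]]))
  }
  sites$lor <- landscape$lor[idx]
  sites$rsalor <- landscape$rsalor[idx]
  sites %>%
    group_by(.data$mutation) %>%
    summarise(
      n_sites = dplyr::n(),
      lor = sum(.data$lor),
      rsalor = sum(.data$rsalor),
      .groups = "drop"
    ) %>%
    dplyr::slice(match(unique(mutations), .data$mutation))
}

#' Rescale external predictor scores by solvent accessibility
#'
#' Applies the RSA complement to any per-mutation score from another
#' predictor: `rescaled = (1 - RSA/100) * (score - center) + center`, where
#' `center` is the external predictor's neutral point (default 0). Mutations
#' at positions without a mapped structure residue pass through unchanged and
#' are flagged.
#'
#' @param scores A data frame with columns `mutation` (single-site strings)
#'   and `score`.
#' @param profile An `rsalor_rsa` from [rsa_profile()].
#' @param map An `rsalor_map` from [align_and_map()].
#' @param center Neutral point of the external score scale.
#' @return A tibble: input columns plus `rsa`, `rescaled`, `rsa_missing`.
#' @export
rsa_rescale_external <- function(scores, profile, map, center = 0) {
  stopifnot(is.data.frame(scores),
            all(c("mutation", "score") %in% names(scores)))
  parsed <- parse_mutations(scores$mutation)
  if (any(parsed$site > 1L)) {
    abort("external rescaling expects single-site mutations")
  }
  out <- as_tibble(scores)
  out$rsa <- rsa_for_position(map, profile, parsed$position)
  out$rsa_missing <- is.na(out$rsa)
  factor <- ifelse(out$rsa_missing, 1, 1 - out$rsa / 100)
  out$rescaled <- factor * (out$score - center) + center
  out
}
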