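#' Fit the RSALOR model to an alignment and a structure
#'
#' End-to-end pipeline: read and curate the MSA (deduplication + twilight
#' filter), compute inverse-cluster-size sequence weights and regularized
#' frequencies, optionally read a PDB chain, compute per-residue relative
#' solvent accessibility (Shrake-Rupley), map structure residues onto target
#' positions, and score the complete single-site mutation landscape. Without
#' a structure the model degrades gracefully to LOR-only scoring.
#'
#' @param msa_path Path to an aligned FASTA file (first record = target).
#' @param pdb_path Optional path to a PDB file; `NULL` for LOR-only mode.
#' @param chain_id Chain identifier in the PDB file.
#' @param twilight Identity-to-target cutoff for MSA curation
#'   (see [curate_msa()]).
#' @param cluster_threshold Identity threshold of the weighting neighborhood
#'   (see [msa_weights()]).
#' @param pseudocount Frequency regularization strength
#'   (see [msa_frequencies()]).
#' @param probe_radius,n_sphere_points,occluders SASA settings
#'   (see [shrake_rupley()]).
#' @param min_identity_warn,min_identity Structure-mapping identity controls
#'   (see [align_and_map()]).
#' @param threads Worker count for the weighting step; results are identical
#'   for any value.
#' @return An object of class `rsalor` bundling `msa`, `freqs`, `chain`,
#'   `profile`, `map`, `scores` (the landscape tibble) and `params`. Use
#'   [tidy()] for the per-mutation table, [glance()] for a one-row summary,
#'   and [autoplot()] for a landscape heatmap.
#' @examples
#' msa <- tempfile(fileext = ".fasta")
#' pdb <- tempfile(fileext = ".pdb")
#' simulate_msa(msa, length = 12, n_random = 40, seed = 7)
#' simulate_pdb(pdb, sequence = read_msa(msa)$target_sequence, mode = "helix")
#' fit <- rsalor(msa, pdb, chain_id = "A")
#' glance(fit)
#' head(tidy(fit))
#' @export
rsalor <- function(msa_path, pdb_path = NULL, chain_id = "A",
                   twilight = 0.35, cluster_threshold = 0.80,
                   pseudocount = 5, probe_radius = 1.4,
                   n_sphere_points = 100L,
                   occluders = c("chain", "all-chains"),
                   min_identity_warn = 0.7, min_identity = 0.3,
                   threads = 1L) {
  occluders <- match.arg(occluders)
  raw <- read_msa(msa_path)
  n_raw <- length(raw$records)
  msa <- curate_msa(raw, twilight = twilight)
  msa <- msa_weights(msa, cluster_threshold = cluster_threshold,
                     threads = threads)
  freqs <- msa_frequencies(msa, pseudocount = pseudocount)
  chain <- NULL
  profile <- NULL
  map <- NULL
  if (!is.null(pdb_path)) {
    chain <- read_pdb_chain(pdb_path, chain_id)
    profile <- rsa_profile(chain, probe_radius = probe_radius,
                           n_sphere_points = n_sphere_points,
                           occluders = occluders)
    map <- align_and_map(msa$target_sequence, chain,
                         min_identity_warn = min_identity_warn,
                         min_identity = min_identity)
  }
  scores <- score_landscape(msa, freqs, map, profile)
  structure(
    list(
      msa = msa,
      freqs = freqs,
      chain = chain,
      profile = profile,
      map = map,
      scores = scores,
      params = list(
        msa_path = msa_path, pdb_path = pdb_path, chain_id = chain_id,
        twilight = twilight, cluster_threshold = cluster_threshold,
        pseudocount = pseudocount, probe_radius = probe_radius,
        n_sphere_points = as.integer(n_sphere_points),
        occluders = occluders, min_identity_warn = min_identity_warn,
        min_identity = min_identity, threads = as.integer(threads),
        n_records_raw = n_raw
      )
    ),
    class = "rsalor"
  )
}

#' @export
print.rsalor <- function(x, ...) {
  g <- glance(x)
  cat("<rsalor fit>\n")
  cat(sprintf("  target length: %d  (%d mutations scored)\n",
              g$target_length, nrow(x$scores)))
  cat(sprintf("  MSA: %d records (%d before curation), n_effective %.2f\n",
              g$n_records, x$params$n_records_raw, g$n_effective))
  if (!is.null(x$map)) {
    cat(sprintf("  structure: chain %s, %d/%d positions mapped (%d mismatched), identity %.2f\n",
                x$params$chain_id, g$n_mapped, g$target_length,
                g$n_mismatched, g$aligned_identity))
  } else {
    cat("  structure: none (LOR-only mode)\n")
  }
  invisible(x)
}

#' Tidy the fitted mutation landscape
#'
#' @param x An `rsalor` fit.
#' @param ... Unused.
#' @return The per-mutation landscape tibble (see [score_landscape()]).
#' @export
tidy.rsalor <- function(x, ...) x$scores

#' One-row summary of an RSALOR fit
#'
#' @param x An `rsalor` fit.
#' @param ... Unused.
#' @return A one-row tibble: target length, record counts before/after
#'   curation, `n_effective`, mapping coverage and identity, and mean clipped
#'   RSA over mapped positions.
#' @export
glance.rsalor <- function(x, ...) {
  has_map <- !is.null(x$map)
  tibble(
    target_length = nchar(x$msa$target_sequence),
    n_records_raw = x$params$n_records_raw,
    n_records = length(x$msa$records),
    n_effective = x$msa$n_effective,
    n_mapped = if (has_map) attr(x$map, "n_mapped") else 0L,
    n_mismatched = if (has_map) attr(x$map, "n_mismatched") else 0L,
    aligned_identity = if (has_map) attr(x$map, "aligned_identity") else NA_real_,
    mean_rsa = if (has_map) mean(x$scores$rsa, na.rm = TRUE) else NA_real_
  )
}

#' Heatmap of a mutation landscape
#'
#' Positions on the x axis, mutant amino acids on the y axis, tile fill is
#' the RSALOR score (falling back to LOR when no structure was provided).
#' Positive scores (blue) indicate predicted deleterious substitutions.
#'
#' @param object An `rsalor` fit or an `rsalor_landscape` tibble.
#' @param score `"rsalor"` or `"lor"`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.rsalor <- function(object, score = NULL, ...) {
  autoplot.rsalor_landscape(object$scores, score = score, ...)
}

#' @rdname autoplot.rsalor
#' @export
autoplot.rsalor_landscape <- function(object, score = NULL, ...) {
  if (is.null(score)) {
    score <- if (all(is.na(object$rsalor))) "lor" else "rsalor"
  }
  score <- match.arg(score, c("rsalor", "lor"))
  df <- object
  df$aa_mt <- factor(df$aa_mt, levels = rev(AA_ORDER))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$aa_mt,
                                   fill = .data[[score]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::labs(x = "target position", y = "mutant amino acid",
                  fill = toupper(score)) +
    ggplot2::theme_minimal()
}

#' Run a full scoring job and write the landscape CSV
#'
#' Thin wrapper around [rsalor()] + [write_landscape_csv()] used by the
#' command-line interface: fits the model, writes the CSV with a `#` comment
#' block echoing the configuration, and emits a summary via `message()`.
#'
#' @inheritParams rsalor
#' @param output_path Path of the CSV file to write.
#' @return The `rsalor` fit, invisibly.
#' @export
run_rsalor <- function(msa_path, output_path, pdb_path = NULL,
                       chain_id = "A", twilight = 0.35,
                       cluster_threshold = 0.80, pseudocount = 5,
                       probe_radius = 1.4, n_sphere_points = 100L,
                       occluders = c("chain", "all-chains"), threads = 1L) {
  occluders <- match.arg(occluders)
  fit <- rsalor(msa_path, pdb_path, chain_id = chain_id,
                twilight = twilight, cluster_threshold = cluster_threshold,
                pseudocount = pseudocount, probe_radius = probe_radius,
                n_sphere_points = n_sphere_points, occluders = occluders,
                threads = threads)
  p <- fit$params
  comments <- c(
    "rsalor mutation landscape",
    paste0("msa=", p$msa_path),
    paste0("pdb=", if (is.null(p$pdb_path)) "none (LOR-only)" else p$pdb_path),
    paste0("chain=", p$chain_id),
    sprintf("twilight=%g cluster_threshold=%g pseudocount=%g",
            p$twilight, p$cluster_threshold, p$pseudocount),
    sprintf("probe_radius=%g n_sphere_points=%d occluders=%s",
            p$probe_radius, p$n_sphere_points, p$occluders),
    sprintf("n_records_raw=%d n_records=%d n_effective=%.6g",
            p$n_records_raw, length(fit$msa$records), fit$msa$n_effective)
  )
  write_landscape_csv(fit$scores, output_path, comments = comments)
  g <- glance(fit)
  inform(sprintf(
    "scored %d mutations over %d positions; MSA %d -> %d records (n_eff %.2f); %s",
    nrow(fit$scores), g$target_length, g$n_records_raw, g$n_records,
    g$n_effective,
    if (is.null(fit$map)) "no structure" else
      sprintf("%d/%d positions mapped", g$n_mapped, g$target_length)
  ))
  invisible(fit)
}
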