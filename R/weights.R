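#' Inverse-cluster-size sequence weights
#'
#' Alignments are typically dominated by clusters of closely related
#' sequences; following the convention of coevolutionary (DCA-style) models,
#' each record is down-weighted by the size of its identity neighborhood:
#' `w_s = 1 / |{s' : identity(s, s') >= threshold}|`, the neighborhood always
#' including `s` itself. The sum of weights is the effective number of
#' sequences `n_effective`.
#'
#' Identity is computed over target-covered columns (see
#' [pairwise_identity()]). Two methods are provided: `"fast"` (vectorized row
#' comparisons, optionally partitioned across `threads` with an exact
#' by-record reduction, so the result is independent of `threads`) and
#' `"reference"` (a literal double loop over record pairs). Both count column
#' matches as integers and divide by the same denominator, so they agree
#' bit-for-bit; the reference method exists as an oracle for testing.
#'
#' @param msa An `rsalor_msa`, normally curated first.
#' @param cluster_threshold Identity threshold in `(0, 1]` defining the
#'   cluster neighborhood; default 0.80.
#' @param method `"fast"` or `"reference"`.
#' @param threads Number of worker processes for the `"fast"` method
#'   (forked via `parallel`; the reduction is order-independent).
#' @return The `rsalor_msa` with `weights` and `n_effective` filled in.
#' @export
msa_weights <- function(msa, cluster_threshold = 0.80,
                        method = c("fast", "reference"), threads = 1L) {
  stopifnot(inherits(msa, "rsalor_msa"))
  if (cluster_threshold <= 0 || cluster_threshold > 1) {
    abort("cluster_threshold must be in (0, 1]")
  }
  method <- match.arg(method)
  codes <- encode_records(msa$records, msa$column_index)
  counts <- switch(method,
    fast = neighbor_counts_fast(codes, cluster_threshold, threads),
    reference = neighbor_counts_reference(codes, cluster_threshold)
  )
  weights <- 1 / counts
  names(weights) <- names(msa$records)
  params <- msa$params
  params$cluster_threshold <- cluster_threshold
  out <- new_msa(msa$records, weights = weights, params = params)
  out
}

# Vectorized neighbor counting. For each record i, the number of columns where
# record j matches i with a non-gap symbol is an integer; the identity is that
# integer over the (constant) number of target-covered columns. Partitioning
# the rows and concatenating per-row counts is exact, so the result does not
# depend on `threads`.
neighbor_counts_fast <- function(codes, threshold, threads = 1L) {
  n <- nrow(codes)
  L <- ncol(codes)
  tc <- t(codes)
  count_row <- function(i) {
    nz <- codes[i, ] > 0L
    if (!any(nz)) return(1L)
    matches <- colSums(tc[nz, , drop = FALSE] == codes[i, nz])
    1L + sum(matches[-i] / L >= threshold)
  }
  idx <- seq_len(n)
  if (threads > 1L && n > 1L &&
      .Platform$OS.type == "unix" && requireNamespace("parallel", quietly = TRUE)) {
    chunks <- split(idx, cut(idx, breaks = min(threads, n), labels = FALSE))
    res <- parallel::mclapply(chunks, function(ch) vapply(ch, count_row, integer(1)),
                              mc.cores = threads)
    unlist(res, use.names = FALSE)
  } else {
    vapply(idx, count_row, integer(1))
  }
}

# Literal O(N^2 * L) double loop: the independent oracle.
neighbor_counts_reference <- function(codes, threshold) {
  n <- nrow(codes)
  L <- ncol(codes)
  counts <- rep(1L, n)
  if (n < 2L) return(counts)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m <- 0L
      for (c in seq_len(L)) {
        if (codes[i, c] > 0L && codes[i, c] == codes[j, c]) m <- m + 1L
      }
      if (m / L >= threshold) {
        counts[i] <- counts[i] + 1L
        counts[j] <- counts[j] + 1L
      }
    }
  }
  counts
}
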