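# Seed-deterministic generators of synthetic alignments and structures.
# They provide ground-truth fixtures (known cluster weights, known burial)
# so the whole pipeline is testable without any external data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Describe a cluster of near-identical sequences for [simulate_msa()]
#'
#' A cluster is a founder sequence plus `size - 1` jittered copies. With
#' `identity = 1` the founder is the target itself, so the cluster
#' contributes `size - 1` new records that are near-copies of the target;
#' otherwise the founder is a mutated copy of the target at the requested
#' identity. Each jittered copy differs from the founder at `jitter`
#' deterministic, non-overlapping positions, so cluster members are distinct
#' records with pairwise identity `>= 1 - 2 * jitter / length`.
#'
#' @param size Number of cluster members (including the founder).
#' @param identity Founder identity to the target in `[0, 1]`.
#' @param jitter Number of positions each copy differs from the founder.
#' @return A list consumed by [simulate_msa()].
#' @export
msa_cluster <- function(size, identity = 1, jitter = 1) {
  stopifnot(size >= 1, identity >= 0, identity <= 1, jitter >= 0)
  list(size = size, identity = identity, jitter = jitter)
}

#' Generate a synthetic aligned FASTA file
#'
#' The first record is the noiseless target: the per-column argmax of the
#' column distributions. Random homologs are sampled independently per
#' column from the same distributions (optionally with gaps); cluster
#' records (see [msa_cluster()]) are duplicated-then-mutated copies that
#' create a known weighting structure. Output is byte-identical for a fixed
#' seed.
#'
#' @param path Output FASTA path.
#' @param length Number of alignment columns.
#' @param column_probs Either `NULL` (each column gets one dominant amino
#'   acid with probability 0.6, the rest uniform), the string `"uniform"`,
#'   or a 20 x `length` matrix of per-column amino-acid probabilities with
#'   rows in [aa_alphabet()] order (columns each summing to 1).
#' @param n_random Number of per-column-sampled homologs.
#' @param clusters List of [msa_cluster()] specs.
#' @param gap_rate Per-cell gap probability applied to random homologs.
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return `path`, invisibly.
#' @export
simulate_msa <- function(path, length = 30, column_probs = NULL,
                         n_random = 0, clusters = NULL, gap_rate = 0,
                         seed = 1) {
  L <- as.integer(length)
  stopifnot(L >= 1, n_random >= 0, gap_rate >= 0, gap_rate < 1)
  with_seed(seed, {
    probs <- build_column_probs(column_probs, L)
    target <- AA_ORDER[apply(probs, 2, which.max)]
    records <- list(target = target)
    ci <- 0L
    for (cl in clusters) {
      ci <- ci + 1L
      if (cl$identity >= 1) {
        founder <- target
        copies <- cl$size - 1L
        founder_kept <- FALSE
      } else {
        n_mut <- max(1L, round((1 - cl$identity) * L))
        founder <- mutate_positions(target, sample(L, n_mut))
        copies <- cl$size - 1L
        founder_kept <- TRUE
      }
      if (founder_kept) records[[paste0("cluster", ci, "_0")]] <- founder
      if (copies > 0L && cl$jitter > 0L) {
        for (k in seq_len(copies)) {
          pos <- ((k - 1L) * cl$jitter + seq_len(cl$jitter) - 1L) %% L + 1L
          records[[paste0("cluster", ci, "_", k)]] <-
            mutate_positions(founder, unique(pos))
        }
      } else if (copies > 0L) {
        for (k in seq_len(copies)) {
          records[[paste0("cluster", ci, "_", k)]] <- founder
        }
      }
    }
    if (n_random > 0L) {
      for (k in seq_len(n_random)) {
        seq_k <- vapply(seq_len(L), function(c) {
          sample(AA_ORDER, 1L, prob = probs[, c])
        }, character(1))
        if (gap_rate > 0) {
          gaps <- stats::runif(L) < gap_rate
          seq_k[gaps] <- GAP
        }
        records[[paste0("rand", k)]] <- seq_k
      }
    }
    lines <- character(0)
    for (nm in names(records)) {
      lines <- c(lines, paste0(">", nm), paste(records[[nm]], collapse = ""))
    }
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con)
  })
  invisible(path)
}

build_column_probs <- function(column_probs, L) {
  if (is.null(column_probs)) {
    probs <- matrix(0.4 / 19, nrow = 20L, ncol = L,
                    dimnames = list(AA_ORDER, NULL))
    dominant <- sample.int(20L, L, replace = TRUE)
    probs[cbind(dominant, seq_len(L))] <- 0.6
    probs
  } else if (identical(column_probs, "uniform")) {
    matrix(1 / 20, nrow = 20L, ncol = L, dimnames = list(AA_ORDER, NULL))
  } else {
    stopifnot(is.matrix(column_probs), nrow(column_probs) == 20L,
              ncol(column_probs) == L)
    sums <- colSums(column_probs)
    if (any(abs(sums - 1) > 1e-8)) abort("column_probs columns must sum to 1")
    rownames(column_probs) <- AA_ORDER
    column_probs
  }
}

mutate_positions <- function(seq_chars, positions) {
  out <- seq_chars
  for (p in positions) {
    out[p] <- sample(setdiff(AA_ORDER, out[p]), 1L)
  }
  out
}

# Heavy-atom offsets relative to the CA position (idealized geometry).
RESIDUE_ATOM_OFFSETS <- list(
  N  = c(-1.458, 0.000, 0.000),
  CA = c(0.000, 0.000, 0.000),
  C  = c(0.551, 1.420, 0.000),
  O  = c(-0.207, 2.390, 0.000),
  CB = c(0.522, -0.750, -1.220)
)

#' Generate a synthetic PDB file
#'
#' Three geometry modes with known ground truth:
#' * `"isolated"`: residues placed `spacing` Angstrom apart along x, far
#'   beyond probe contact, so every residue's RSA clips to 100;
#' * `"buried-core"`: the first residue sits at the origin inside a dense
#'   golden-spiral shell of blocker residues (radius `shell_radius`) that
#'   occludes its entire lattice, driving its RSA below 5; remaining
#'   residues are placed isolated;
#' * `"helix"`: an idealized alpha-helical CA trace (100 degrees twist,
#'   1.5 Angstrom rise), a compact but legal backbone for mapping tests.
#'
#' Residues are written as N, CA, C, O (+ CB except glycine) with legal
#' fixed-width ATOM records that round-trip through [read_pdb_chain()].
#'
#' @param path Output PDB path.
#' @param sequence One-letter amino-acid string.
#' @param mode Geometry mode.
#' @param chain_id Chain identifier to write.
#' @param spacing Residue spacing for `"isolated"` placements (Angstrom).
#' @param shell_radius Blocker-shell radius for `"buried-core"` (Angstrom).
#' @param n_shell Number of blocker atoms on the shell.
#' @param seed Unused randomness guard (generation is deterministic); kept
#'   so fixture specs carry an explicit seed.
#' @return `path`, invisibly.
#' @export
simulate_pdb <- function(path, sequence,
                         mode = c("isolated", "buried-core", "helix"),
                         chain_id = "A", spacing = 40, shell_radius = 4.5,
                         n_shell = 240, seed = 1) {
  mode <- match.arg(mode)
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(aa %in% AA_ORDER)) abort("sequence must use standard amino acids")
  n <- length(aa)
  ca <- switch(mode,
    "isolated" = cbind((seq_len(n) - 1) * spacing, 0, 0),
    "buried-core" = cbind(c(0, spacing * seq_len(n - 1) + 2 * shell_radius),
                          0, 0)[seq_len(n), , drop = FALSE],
    "helix" = {
      t <- (seq_len(n) - 1) * 100 * pi / 180
      cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(n) - 1))
    }
  )
  rows <- list()
  serial <- 0L
  add_atom <- function(name, element, resid3, resno, xyz) {
    serial <<- serial + 1L
    rows[[serial]] <<- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, format_atom_name(name), resid3, chain_id, resno,
      xyz[1], xyz[2], xyz[3], 1.00, 0.00, element
    )
  }
  three <- setNames(names(AA_THREE_TO_ONE), unname(AA_THREE_TO_ONE))
  for (i in seq_len(n)) {
    for (name in names(RESIDUE_ATOM_OFFSETS)) {
      if (name == "CB" && aa[i] == "G") next
      add_atom(name, substr(name, 1, 1), three[[aa[i]]], i,
               ca[i, ] + RESIDUE_ATOM_OFFSETS[[name]])
    }
  }
  if (mode == "buried-core") {
    shell <- golden_spiral(n_shell) * shell_radius
    blocker_names <- c("N", "CA", "C", "O")
    for (k in seq_len(n_shell)) {
      resno <- n + 1L + (k - 1L) %/% 4L
      name <- blocker_names[(k - 1L) %% 4L + 1L]
      add_atom(name, substr(name, 1, 1), "GLY", resno, shell[k, ])
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(unlist(rows), "END"), con)
  invisible(path)
}

# PDB atom-name column convention: names shorter than 4 characters start in
# column 14 (one leading space), longer names fill columns 13-16.
format_atom_name <- function(name) {
  if (nchar(name) < 4L) sprintf(" %-3s", name) else name
}
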