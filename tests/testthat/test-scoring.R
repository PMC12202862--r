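test_that("the log-odd ratio reproduces hand-evaluated logit differences", {
  fr <- make_freqs(list(c(A = 0.75, V = 0.25)))
  expect_equal(lor_score(fr, 1, "A", "V"), 2 * log(3), tolerance = 1e-12)
  expect_equal(lor_score(fr, 1, "A", "V"), 2.197225, tolerance = 1e-6)
  # equal frequencies score zero
  fr2 <- make_freqs(list(c(A = 0.3, V = 0.3)))
  expect_equal(lor_score(fr2, 1, "A", "V"), 0, tolerance = 1e-15)
  # positive when wt is more represented than mt
  expect_gt(lor_score(fr, 1, "A", "V"), 0)
  expect_lt(lor_score(fr, 1, "V", "A"), 0)
})

test_that("invalid LOR inputs are rejected", {
  fr <- make_freqs(list(c(A = 0.75, V = 0.25)))
  expect_error(lor_score(fr, 1, "A", "A"), "must differ")
  expect_error(lor_score(fr, 2, "A", "V"), "out of range")
  expect_error(lor_score(fr, 1, "A", "X"), "standard")
  degenerate <- make_freqs(list(c(A = 1, V = 0)))
  expect_error(lor_score(degenerate, 1, "A", "V"), "regularize")
})

test_that("the RSA complement scales scores as specified", {
  expect_equal(rsalor_score(2.0, 100), 0)
  expect_equal(rsalor_score(2.0, 0), 2.0)
  expect_equal(rsalor_score(2.0, 25), 1.5, tolerance = 1e-12)
  expect_equal(rsalor_score(-3.0, 50), -1.5)
  expect_true(is.na(rsalor_score(2.0, NA_real_)))
  expect_error(rsalor_score(1, 120), "\\[0, 100\\]")
})

test_that("LOR is exactly antisymmetric and monotone in the mutant frequency", {
  withr::with_seed(101, {
    recs <- random_alignment_records(25, 30, gap_rate = 0.1)
  })
  msa <- msa_weights(read_msa_from(recs), 0.8)
  fr <- msa_frequencies(msa, 5)
  aa <- aa_alphabet()
  withr::with_seed(55, {
    for (k in 1:200) {
      i <- sample(nrow(fr), 1)
      pair <- sample(aa, 2)
      expect_equal(lor_score(fr, i, pair[1], pair[2]) +
                     lor_score(fr, i, pair[2], pair[1]),
                   0, tolerance = 1e-12)
    }
  })
  # monotonicity at fixed f(wt): lor strictly decreases as f(mt) increases
  fmt <- seq(0.05, 0.9, by = 0.05)
  vals <- vapply(fmt, function(f) {
    lor_score(make_freqs(list(c(A = 0.05, V = f))), 1, "A", "V")
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

landscape_fixture <- function(pdb = TRUE, L = 10, seed = 77) {
  msa <- tempfile(fileext = ".fasta")
  simulate_msa(msa, length = L, n_random = 30,
               clusters = list(msa_cluster(3)), seed = seed)
  if (pdb) {
    target <- read_msa(msa)$target_sequence
    pdb_path <- tempfile(fileext = ".pdb")
    simulate_pdb(pdb_path, target, mode = "helix")
    rsalor(msa, pdb_path, chain_id = "A")
  } else {
    rsalor(msa)
  }
}

test_that("the landscape enumerates exactly 19 mutations per position", {
  fit <- landscape_fixture(L = 10)
  scores <- tidy(fit)
  expect_equal(nrow(scores), 19 * 10)
  expect_equal(scores$aa_wt,
               strsplit(fit$msa$target_sequence, "")[[1]][scores$position])
  # deterministic ordering: position, then fixed amino-acid order
  expect_equal(scores$position, sort(scores$position))
  ord <- order(scores$position, match(scores$aa_mt, aa_alphabet()))
  expect_equal(ord, seq_len(nrow(scores)))
  # record count independent of MSA depth
  fit_deep <- {
    msa <- tempfile(fileext = ".fasta")
    simulate_msa(msa, length = 10, n_random = 200, seed = 78)
    rsalor(msa)
  }
  expect_equal(nrow(tidy(fit_deep)), 19 * 10)
})

test_that("RSALOR keeps the LOR sign and never exceeds its magnitude", {
  fit <- landscape_fixture(L = 12)
  sc <- tidy(fit)
  ok <- !is.na(sc$rsalor)
  expect_true(any(ok))
  expect_true(all(abs(sc$rsalor[ok]) <= abs(sc$lor[ok]) + 1e-12))
  strict <- ok & sc$rsa < 100 & abs(sc$lor) > 0
  expect_true(all(sign(sc$rsalor[strict]) == sign(sc$lor[strict])))
  # equality of magnitudes iff rsa == 0
  eq <- ok & abs(abs(sc$rsalor) - abs(sc$lor)) < 1e-12 & abs(sc$lor) > 1e-9
  expect_true(all(sc$rsa[eq] == 0))
})

test_that("mutation strings parse, canonicalize and validate", {
  p <- parse_mutations("A42G")
  expect_equal(p$position, 42L)
  expect_equal(p$aa_wt, "A")
  expect_equal(p$aa_mt, "G")
  multi <- parse_mutations("D77K:A42G")
  expect_equal(multi$position, c(42L, 77L))  # canonical increasing order
  expect_error(parse_mutations("A42G:G42K"), "duplicate")
  expect_error(parse_mutations("A42A"), "wild-type equals mutant")
  expect_error(parse_mutations("42G"), "malformed")
  expect_error(parse_mutations("C2G", target = "GAAA"), "mismatch")
  expect_error(parse_mutations("A42G", target = "GAAA"), "beyond target")
  expect_silent(parse_mutations("G1A", target = "GAAA"))
})

test_that("multi-site scores are the sum of their single-site components", {
  fit <- landscape_fixture(L = 10)
  sc <- tidy(fit)
  target <- strsplit(fit$msa$target_sequence, "")[[1]]
  m1 <- paste0(target[2], 2, "G")
  if (target[2] == "G") m1 <- paste0(target[2], 2, "A")
  m2 <- paste0(target[5], 5, "K")
  if (target[5] == "K") m2 <- paste0(target[5], 5, "A")
  both <- paste(m1, m2, sep = ":")
  res <- score_multi(sc, c(m1, m2, both))
  expect_equal(res$lor[3], res$lor[1] + res$lor[2], tolerance = 1e-12)
  expect_equal(res$rsalor[3], res$rsalor[1] + res$rsalor[2],
               tolerance = 1e-12)
  # single-site mutation equals its own landscape score
  expect_equal(res$lor[1], sc$lor[sc$mutation == m1])
  # site order in the input string does not matter
  flipped <- score_multi(sc, paste(m2, m1, sep = ":"))
  expect_equal(flipped$lor, res$lor[3])
  expect_equal(flipped$rsalor, res$rsalor[3])
})

test_that("multi-site RSALOR is missing when any site lacks structure", {
  msa <- tempfile(fileext = ".fasta")
  simulate_msa(msa, length = 10, n_random = 25, seed = 42)
  target <- read_msa(msa)$target_sequence
  pdb <- tempfile(fileext = ".pdb")
  simulate_pdb(pdb, substr(target, 4, 10), mode = "helix")
  fit <- rsalor(msa, pdb, chain_id = "A")
  sc <- tidy(fit)
  tgt <- strsplit(target, "")[[1]]
  mt_at <- function(i) paste0(tgt[i], i, if (tgt[i] == "G") "A" else "G")
  res <- score_multi(sc, paste(mt_at(1), mt_at(6), sep = ":"))
  expect_true(is.na(res$rsalor))   # site 1 has no mapped residue
  expect_false(is.na(res$lor))     # evolutionary part still defined
})

test_that("external scores are rescaled by the RSA complement", {
  msa <- tempfile(fileext = ".fasta")
  simulate_msa(msa, length = 8, n_random = 25, seed = 5)
  target <- read_msa(msa)$target_sequence
  pdb <- tempfile(fileext = ".pdb")
  simulate_pdb(pdb, substr(target, 3, 8), mode = "helix")
  fit <- rsalor(msa, pdb, chain_id = "A")
  tgt <- strsplit(target, "")[[1]]
  muts <- vapply(c(1, 4, 6), function(i) {
    paste0(tgt[i], i, if (tgt[i] == "G") "A" else "G")
  }, character(1))
  ext <- tibble::tibble(mutation = muts, score = c(-4, -4, 2))
  out <- rsa_rescale_external(ext, fit$profile, fit$map, center = 0)
  # unmapped position passes through unchanged, flagged
  expect_true(out$rsa_missing[1])
  expect_equal(out$rescaled[1], -4)
  expect_equal(out$rescaled[2], (1 - out$rsa[2] / 100) * -4)
  # hand value: rsa 50, score -4, center 0 -> -2
  prof50 <- fit$profile
  prof50$rsa_clipped[prof50$residue_key ==
                       fit$map$residue_key[4]] <- 50
  out50 <- rsa_rescale_external(ext[2, ], prof50, fit$map, center = 0)
  expect_equal(out50$rescaled, -2)
  # a fully exposed site collapses to the center
  prof100 <- fit$profile
  prof100$rsa_clipped[] <- 100
  out100 <- rsa_rescale_external(ext[3, ], prof100, fit$map, center = 1.5)
  expect_equal(out100$rescaled, 1.5)
})

test_that("conserved columns dominate uniform columns in LOR magnitude", {
  aa <- aa_alphabet()
  probs <- matrix(1 / 20, nrow = 20, ncol = 2, dimnames = list(aa, NULL))
  probs[, 1] <- c(0.95, rep(0.05 / 19, 19))  # column 1: 95% alanine
  msa <- tempfile(fileext = ".fasta")
  simulate_msa(msa, length = 2, column_probs = probs, n_random = 400,
               seed = 23)
  fit <- rsalor(msa)
  sc <- tidy(fit)
  cons <- sc$lor[sc$position == 1]
  unif <- sc$lor[sc$position == 2]
  expect_true(all(cons > 0))
  expect_gt(min(cons), max(abs(unif)))
})
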