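test_that("an isolated atom recovers the closed-form sphere area", {
  chain <- make_chain(cbind(0, 0, 0), "C")
  res <- shrake_rupley(chain, probe_radius = 1.4, n_sphere_points = 100)
  # all lattice points exposed: exactly 4*pi*(1.70+1.40)^2
  expect_equal(res$sasa, 4 * pi * 3.10^2, tolerance = 1e-12)
  expect_equal(res$sasa, 120.7628, tolerance = 1e-4)
})

test_that("disjoint spheres are exactly additive", {
  # separation beyond 2*(r_vdw + probe): no mutual occlusion
  chain <- make_chain(rbind(c(0, 0, 0), c(10, 0, 0)), c("C", "C"))
  res <- shrake_rupley(chain, n_sphere_points = 100)
  expect_equal(res$sasa, rep(4 * pi * 3.10^2, 2), tolerance = 1e-12)
})

test_that("overlapping identical atoms lose equal area, matching a dense lattice", {
  # strong overlap at d = r_vdw
  chain <- make_chain(rbind(c(0, 0, 0), c(1.70, 0, 0)), c("C", "C"))
  res <- shrake_rupley(chain, n_sphere_points = 100)
  iso <- 4 * pi * 3.10^2
  expect_lt(res$sasa[1], iso)
  expect_equal(res$sasa[1], res$sasa[2], tolerance = 1e-9)
  # convergence oracle: high-density lattice as independent reference
  ref <- shrake_rupley(chain, n_sphere_points = 10000)
  expect_equal(res$sasa[1], ref$sasa[1], tolerance = 0.02)
  # exact spherical-cap closed form for two overlapping equal spheres:
  # exposed fraction = (1 + d/(2R)) / 2 with R = r_vdw + probe
  cap <- iso * (1 + 1.70 / (2 * 3.10)) / 2
  expect_equal(ref$sasa[1], cap, tolerance = 1e-3)
})

test_that("per-atom SASA never exceeds the isolated-sphere bound", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(3:8, 1)
      xyz <- matrix(runif(3 * n, 0, 6), ncol = 3)
      elems <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
      chain <- make_chain(xyz, elems)
      res <- shrake_rupley(chain, n_sphere_points = 100)
      bound <- 4 * pi * (chain$atoms$radius + 1.4)^2
      expect_true(all(res$sasa <= bound + 1e-9))
    }
  })
})

test_that("removing a neighbor never decreases another atom's SASA", {
  withr::with_seed(47, {
    for (rep in 1:100) {
      d <- runif(1, 0.5, 7)
      xyz <- rbind(c(0, 0, 0), d * rnorm3())
      chain2 <- make_chain(xyz, c("C", "C"))
      chain1 <- make_chain(xyz[1, , drop = FALSE], "C")
      s2 <- shrake_rupley(chain2, n_sphere_points = 100)$sasa[1]
      s1 <- shrake_rupley(chain1, n_sphere_points = 100)$sasa[1]
      expect_gte(s1, s2)
    }
  })
})

test_that("SASA is rigid-motion invariant within the fixed-lattice tolerance", {
  path <- tempfile(fileext = ".pdb")
  simulate_pdb(path, "ACDEFGHIKL", mode = "helix")
  chain <- read_pdb_chain(path, "A")
  base <- shrake_rupley(chain, n_sphere_points = 100)
  withr::with_seed(13, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- c(5, -3, 11)
  })
  rot <- chain
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")]) %*% t(q)
  rot$atoms$x <- xyz[, 1] + shift[1]
  rot$atoms$y <- xyz[, 2] + shift[2]
  rot$atoms$z <- xyz[, 3] + shift[3]
  moved <- shrake_rupley(rot, n_sphere_points = 100)
  # with a fixed lattice the exposed-point count of an atom can shift by a
  # few lattice quanta under rotation; the chain total stays within 1%
  expect_lt(abs(sum(moved$sasa) - sum(base$sasa)) / sum(base$sasa), 0.01)
  quantum <- 4 * pi * (max(chain$atoms$radius) + 1.4)^2 / 100
  expect_lt(max(abs(moved$sasa - base$sasa)), 3 * quantum)
  # pure translation is exactly invariant (lattice moves with the center)
  tra <- chain
  tra$atoms$x <- chain$atoms$x + 100
  expect_equal(shrake_rupley(tra, n_sphere_points = 100)$sasa, base$sasa,
               tolerance = 1e-9)
})

test_that("the lattice is converged at the default density", {
  path <- tempfile(fileext = ".pdb")
  simulate_pdb(path, "ACDEFGHIKL", mode = "helix")
  chain <- read_pdb_chain(path, "A")
  total_100 <- sum(shrake_rupley(chain, n_sphere_points = 100)$sasa)
  total_960 <- sum(shrake_rupley(chain, n_sphere_points = 960)$sasa)
  expect_lt(abs(total_100 - total_960) / total_960, 0.02)
})

test_that("RSA fixtures behave as constructed", {
  iso <- tempfile(fileext = ".pdb")
  simulate_pdb(iso, "AGS", mode = "isolated")
  prof <- rsa_profile(read_pdb_chain(iso, "A"))
  expect_true(all(prof$rsa >= 100))    # beyond tripeptide reference
  expect_equal(prof$rsa_clipped, rep(100, 3))

  bur <- tempfile(fileext = ".pdb")
  simulate_pdb(bur, "A", mode = "buried-core")
  prof_b <- rsa_profile(read_pdb_chain(bur, "A"))
  expect_lt(prof_b$rsa_clipped[prof_b$residue_key == "1"], 5)
  expect_true(all(prof_b$rsa_clipped >= 0 & prof_b$rsa_clipped <= 100))
  expect_equal(prof_b$rsa,
               100 * prof_b$sasa / c(129.0, rep(104.0, nrow(prof_b) - 1)))
})
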