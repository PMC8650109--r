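test_that("betaMNTD matches hand-computed values on the toy tree", {
  dm <- patristic_distances(read_phylo(toy_newick))
  expect_equal(beta_mntd(c(A = 1), c(C = 1), dm), 4)
  expect_equal(beta_mntd(c(A = .5, B = .5), c(B = 1), dm), 0.5)
  # identical communities: every taxon's nearest relative is itself
  expect_equal(beta_mntd(c(A = .3, C = .7), c(A = .3, C = .7), dm), 0)
  # symmetry
  x <- c(A = 2, B = 1); y <- c(C = 1, D = 3)
  expect_equal(beta_mntd(x, y, dm), beta_mntd(y, x, dm))
  expect_error(beta_mntd(c(A = 0), c(B = 1), dm), "empty")
  expect_error(beta_mntd(c(Z = 1), c(B = 1), dm), "missing")
})

test_that("pairwise betaMNTD agrees with brute force and with picante", {
  set.seed(17)
  for (i in 1:12) {
    inst <- random_instance(sample(4:16, 1), sample(2:6, 1))
    dm <- patristic_distances(inst$tree)
    mine <- bmntd(inst$counts, dm)
    for (a in 1:(nrow(inst$counts) - 1)) for (b in (a + 1):nrow(inst$counts)) {
      expect_equal(mine[a, b],
                   brute_bmntd(inst$counts[a, ], inst$counts[b, ], dm),
                   tolerance = 1e-12)
    }
  }
  skip_if_not_installed("picante")
  set.seed(18)
  inst <- random_instance(12, 5)
  dm <- patristic_distances(inst$tree)
  ref <- as.matrix(picante::comdistnt(inst$counts, dm,
                                      abundance.weighted = TRUE))
  mine <- bmntd(inst$counts, dm)
  expect_equal(mine[rownames(ref), colnames(ref)][lower.tri(ref)],
               ref[lower.tri(ref)], tolerance = 1e-10)
})

test_that("the taxon-shuffling null behaves as shuffling should", {
  # star-like distances: every pair of distinct taxa equidistant, so any
  # permutation leaves betaMNTD unchanged and the null is degenerate
  S <- 6
  dm <- matrix(2, S, S); diag(dm) <- 0
  dimnames(dm) <- list(paste0("t", 1:S), paste0("t", 1:S))
  cm <- rbind(s1 = c(1, 1, 0, 0, 1, 0), s2 = c(0, 1, 1, 1, 0, 0),
              s3 = c(1, 0, 0, 1, 0, 1))
  colnames(cm) <- rownames(dm)
  obs <- bmntd(cm, dm)
  set.seed(2)
  nl <- bmntd_null(cm, dm, n_reps = 50, keep = TRUE)
  expect_equal(nl$mean, obs, tolerance = 1e-12)
  expect_true(all(nl$sd < 1e-12))

  # null mean equals the exhaustive average over all label permutations
  tr <- read_phylo(toy_newick)
  dm4 <- patristic_distances(tr)
  cm4 <- rbind(s1 = c(A = 1, B = 1, C = 0, D = 0),
               s2 = c(A = 0, B = 1, C = 1, D = 0),
               s3 = c(A = 1, B = 0, C = 0, D = 1))
  exact <- 0
  perms <- all_perms(4)
  for (p in perms) exact <- exact + bmntd(cm4, dm4, perm = p)
  exact <- exact / length(perms)
  set.seed(5)
  nl4 <- bmntd_null(cm4, dm4, n_reps = 3000)
  expect_equal(nl4$mean[upper.tri(exact)], exact[upper.tri(exact)],
               tolerance = 0.06)
  expect_error(bmntd_null(cm4, dm4, n_reps = 1), "at least 2")
})

test_that("betaNTI standardizes against the null as defined", {
  expect_equal(beta_nti(5, c(1, 2, 3)), 3)           # (5 - 2) / 1
  expect_equal(beta_nti(2, c(1, 2, 3)), 0)
  null <- c(1, 2, 3)
  # obs at mean + 2 SD lands exactly on the significance boundary
  expect_equal(beta_nti(mean(null) + 2 * sd(null), null), 2)
  expect_error(beta_nti(1, c(2, 2, 2)), "SD is zero")
  expect_error(beta_nti(1, c(2)), "at least 2")
})

test_that("betaNTI is invariant to uniform branch-length scaling", {
  set.seed(23)
  inst <- random_instance(20, 5)
  tr2 <- inst$tree
  tr2$edge.length <- tr2$edge.length * 7.3
  dm1 <- patristic_distances(inst$tree)
  dm2 <- patristic_distances(tr2)
  obs1 <- bmntd(inst$counts, dm1); obs2 <- bmntd(inst$counts, dm2)
  set.seed(101); n1 <- bmntd_null(inst$counts, dm1, n_reps = 99)
  set.seed(101); n2 <- bmntd_null(inst$counts, dm2, n_reps = 99)
  b1 <- (obs1 - n1$mean) / n1$sd
  b2 <- (obs2 - n2$mean) / n2$sd
  ut <- upper.tri(b1)
  expect_lt(max(abs(b1[ut] - b2[ut])), 1e-9)
})

test_that("RC-bray respects its bounds and flags more-similar pairs", {
  set.seed(41)
  cm <- matrix(rpois(8 * 30, 6), 8, 30,
               dimnames = list(paste0("s", 1:8), paste0("t", 1:30)))
  storage.mode(cm) <- "integer"
  rc <- rc_bray_pairs(cm, rbind(c(1, 2), c(3, 4), c(5, 6)), n_reps = 99, seed = 1)
  expect_true(all(rc >= -1 & rc <= 1))

  # identical pair is at least as similar as any pair involving either member
  cm2 <- cm
  cm2[2, ] <- cm2[1, ]
  rc_id <- rc_bray_pairs(cm2, rbind(c(1, 2)), n_reps = 199, seed = 2)
  rc_other <- rc_bray_pairs(cm2, rbind(c(1, 3), c(2, 5)), n_reps = 199, seed = 2)
  expect_true(all(rc_id <= rc_other))
  expect_equal(rc_id, -1)  # obs BC = 0, below every non-degenerate null
})

test_that("per-pair RC streams are order-independent and reproducible", {
  set.seed(43)
  cm <- matrix(rpois(6 * 20, 5), 6, 20,
               dimnames = list(paste0("s", 1:6), paste0("t", 1:20)))
  storage.mode(cm) <- "integer"
  a <- rc_bray_pairs(cm, rbind(c(1, 2), c(3, 4)), n_reps = 49, seed = 7)
  b <- rc_bray_pairs(cm, rbind(c(3, 4), c(1, 2)), n_reps = 49, seed = 7)
  expect_equal(a, rev(b))
  expect_equal(a, rc_bray_pairs(cm, rbind(c(1, 2), c(3, 4)), n_reps = 49, seed = 7))
})

test_that("null calibration: no phylogenetic structure gives ~5% significance", {
  cfg <- sim_config(regime = "drift", n_taxa = 60, slopes = 1, locations = 3,
                    depths = 2, times = 2, reads = 500, seed = 77)
  sim <- simulate_dataset(cfg, seed = 77)
  fit <- suppressWarnings(
    assembly_analysis(sim$counts, sim$tree, sim$metadata,
                      n_reps = 499, rc_policy = "none", seed = 77))
  frac <- mean(abs(fit$pairs$bnti) > 2, na.rm = TRUE)
  # binomial 99% envelope around 0.05 at 66 pairs (pairs share null draws,
  # so this is a sanity envelope, not an exact test)
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 66) + 0.02)
})
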