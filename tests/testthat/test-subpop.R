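bnti_fixture <- function(vals, ids) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[lower.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- NA
  m
}

test_that("per-sample mean betaNTI matches hand averaging", {
  # pairwise values ab=1, ac=2, bc=3
  m <- bnti_fixture(c(1, 2, 3), c("a", "b", "c"))
  mb <- within_group_mean_bnti(m)
  expect_equal(mb, c(a = 1.5, b = 2, c = 2.5))

  # constant matrix: every mean equals the constant
  mc <- bnti_fixture(rep(4, 6), letters[1:4])
  expect_true(all(within_group_mean_bnti(mc) == 4))
})

test_that("depth control restricts partners to the same depth", {
  ids <- paste0("s", 1:5)
  set.seed(3)
  m <- bnti_fixture(rnorm(10), ids)
  md <- data.frame(sample = ids, depth = c("D1", "D1", "D2", "D2", "D3"))
  expect_warning(within_group_mean_bnti(m, md, "depth"), "no eligible")
  mb <- suppressWarnings(within_group_mean_bnti(m, md, "depth"))
  # s5 is alone at D3 and must be excluded
  expect_setequal(names(mb), ids[1:4])
  expect_equal(mb[["s1"]], m["s1", "s2"])
  expect_equal(mb[["s3"]], m["s3", "s4"])

  # with a single depth level, control equals no control
  md1 <- data.frame(sample = ids, depth = "D1")
  expect_equal(within_group_mean_bnti(m, md1, "depth"),
               within_group_mean_bnti(m))
})

test_that("cross-gene correlations recover exact and textbook cases", {
  set.seed(19)
  g1 <- setNames(rnorm(10), paste0("s", 1:10))
  res <- cross_gene_correlation(list(a = g1, b = g1))
  expect_equal(res$r["a", "b"], 1)
  res2 <- cross_gene_correlation(list(a = g1, b = -g1))
  expect_equal(res2$r["a", "b"], -1)

  g2 <- setNames(rnorm(10), paste0("s", 1:10))
  res3 <- cross_gene_correlation(list(a = g1, b = g2))
  ct <- cor.test(g1, g2)
  expect_equal(res3$r["a", "b"], unname(ct$estimate))
  expect_equal(res3$p["a", "b"], ct$p.value)
  expect_equal(res3$n["a", "b"], 10)

  # correlation on the common-sample intersection only
  g3 <- setNames(rnorm(6), paste0("s", 3:8))
  res4 <- cross_gene_correlation(list(a = g1, b = g3))
  common <- paste0("s", 3:8)
  expect_equal(res4$r["a", "b"],
               unname(cor.test(g1[common], g3[common])$estimate))

  # too few common samples: not computable
  g4 <- setNames(rnorm(2), paste0("s", 1:2))
  res5 <- cross_gene_correlation(list(a = g1, b = g4))
  expect_true(is.na(res5$r["a", "b"]))
  expect_equal(res5$n["a", "b"], 2)
})

test_that("all six gene pairs are reported for four genes", {
  set.seed(23)
  means <- lapply(1:4, function(i) setNames(rnorm(8), paste0("s", 1:8)))
  names(means) <- c("narG", "nifH", "rbcL", "rps3")
  res <- cross_gene_correlation(means)
  ut <- upper.tri(res$r)
  expect_equal(sum(ut), 6)
  expect_true(all(is.finite(res$r[ut])))
  expect_true(all(res$p[ut] >= 0 & res$p[ut] <= 1))
})

test_that("environment correlations handle exact and degenerate variables", {
  set.seed(29)
  mb <- setNames(rnorm(8), paste0("s", 1:8))
  md <- data.frame(sample = paste0("s", 1:8),
                   copy = mb, const = 1, noise = rnorm(8))
  res <- env_correlation(list(narG = mb), md, c("copy", "const", "noise"))
  expect_equal(res$r[res$variable == "copy"], 1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$variable == "const"]))
  ct <- cor.test(mb, md$noise)
  expect_equal(res$r[res$variable == "noise"], unname(ct$estimate))
  expect_equal(res$p[res$variable == "noise"], ct$p.value)
  expect_error(env_correlation(list(narG = mb), md, "absent"), "absent")
})

test_that("subpop_assembly wires guild fits into correlations", {
  cfg <- sim_config(regime = "variable_selection", n_taxa = 80, slopes = 1,
                    locations = 4, depths = 2, times = 1, reads = 600,
                    migration = 0.1, seed = 3)
  gs <- simulate_guild_dataset(cfg, n_guilds = 2, shared_driver = TRUE, seed = 3)
  genes <- lapply(gs$guilds, function(g)
    extract_guild_table(gs$counts, gs$tree, g))
  sp <- suppressWarnings(
    subpop_assembly(genes, gs$metadata, control = "depth",
                    variables = c("pH", "TC"), n_reps = 59, seed = 3))
  expect_s3_class(sp, "subpop_assembly")
  expect_setequal(names(sp$means), c("g1", "g2"))
  expect_true(all(abs(sp$cross_gene$r) <= 1, na.rm = TRUE))
  expect_equal(nrow(sp$env), 4)  # 2 genes x 2 variables
  expect_output(print(sp), "gene x gene")
})
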