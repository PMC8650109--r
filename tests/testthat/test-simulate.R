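test_that("simulated trees have the requested tips and unit-mean branches", {
  set.seed(1)
  for (n in c(2, 10, 100)) {
    tr <- simulate_tree(n)
    expect_equal(length(tr$tip.label), n)
    expect_equal(mean(tr$edge.length), 1, tolerance = 1e-12)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("Brownian traits have the advertised moments", {
  # rate 0: no evolution
  tr <- read_phylo(toy_newick)
  expect_true(all(simulate_traits(tr, 0) == simulate_traits(tr, 0)[1]))

  # two-tip tree: trait difference ~ Normal(0, rate * patristic distance)
  tr2 <- read_phylo("(A:1.5,B:0.5);")
  set.seed(2)
  diffs <- replicate(3000, { x <- simulate_traits(tr2, 2); x["A"] - x["B"] })
  expect_lt(abs(mean(diffs)), 3 * sqrt(4 / 3000))
  expect_lt(abs(var(diffs) - 2 * 2), 4 * 4 * sqrt(2 / 3000))

  # siblings correlate more than distant tips (shared-path covariance)
  tr4 <- read_phylo(toy_newick)
  set.seed(3)
  traits <- replicate(2000, simulate_traits(tr4, 1))
  cor_ab <- cor(traits["A", ], traits["B", ])
  cor_ac <- cor(traits["A", ], traits["C", ])
  expect_gt(cor_ab, cor_ac + 0.1)
})

test_that("the niche matrix is conserved: niche-near taxa are clade-mates", {
  set.seed(4)
  tr <- simulate_tree(100)
  niche <- simulate_niche(tr, 1, 8)
  expect_equal(dim(niche), c(100, 8))
  dm <- patristic_distances(tr)
  nd <- as.matrix(dist(niche))
  # for most taxa, the niche-nearest neighbor is phylogenetically closer
  # than a random taxon
  hits <- vapply(1:100, function(i) {
    nn <- which.min(replace(nd[i, ], i, Inf))
    dm[i, nn] < median(dm[i, -i])
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("simulated datasets are deterministic and exactly at depth", {
  cfg <- sim_config(regime = "variable_selection", n_taxa = 40, slopes = 2,
                    locations = 2, depths = 2, times = 2, reads = 300, seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_true(all(rowSums(a$counts) == 300))
  expect_equal(nrow(a$counts), 2 * 2 * 2 * 2)
  expect_setequal(colnames(a$counts), a$tree$tip.label)
})

test_that("the design grid and metadata match the configured factors", {
  cfg <- sim_config(n_taxa = 20, slopes = 3, locations = 6, depths = 5,
                    times = 2, reads = 100, seed = 1)
  sim <- simulate_dataset(cfg)
  md <- sim$metadata
  expect_equal(nrow(md), 180)
  expect_setequal(unique(md$slope), c("East", "Central", "West"))
  expect_setequal(unique(md$depth), paste0("D", 1:5))
  expect_setequal(unique(md$time), c("pre", "post"))
  expect_true(all(c("pH", "EC", "TC", "OC", "IC", "TN", "SWC_mean_Annual",
                    "SWC_fractimedry_Annual", "Temperature_Instantaneous",
                    "DNA_conc") %in% names(md)))
  expect_false(anyDuplicated(md$sample) > 0)
})

test_that("guild extraction restricts, prunes, and preserves counts", {
  cfg <- sim_config(regime = "drift", n_taxa = 30, slopes = 1, locations = 2,
                    depths = 2, times = 1, reads = 200, seed = 5)
  sim <- simulate_dataset(cfg)
  all_taxa <- colnames(sim$counts)
  # full guild is the identity
  full <- extract_guild_table(sim$counts, sim$tree, all_taxa)
  expect_identical(full$counts, sim$counts)
  # clade guild: pruned tree carries exactly the clade
  clade <- ape::extract.clade(sim$tree, 32)$tip.label
  skip_if(length(clade) < 2)
  g <- suppressWarnings(extract_guild_table(sim$counts, sim$tree, clade))
  expect_setequal(g$tree$tip.label, clade)
  expect_identical(colnames(g$counts), clade)
  expect_true(all(g$counts == sim$counts[rownames(g$counts), clade]))
  expect_error(extract_guild_table(sim$counts, sim$tree, c("nope", clade)),
               "absent")
})

test_that("selection collapses toward the favored niche as breadth shrinks", {
  base <- sim_config(regime = "homogeneous_selection", n_taxa = 80, slopes = 1,
                     locations = 3, depths = 2, times = 1, reads = 500,
                     sigma_sel = 0.05, seed = 13)
  wide <- sim_config(regime = "homogeneous_selection", n_taxa = 80, slopes = 1,
                     locations = 3, depths = 2, times = 1, reads = 500,
                     sigma_sel = 0.9, seed = 13)
  narrow_sim <- simulate_dataset(base)
  wide_sim <- simulate_dataset(wide)
  # strong selection concentrates occupied taxa; near-neutral breadth spreads
  expect_lt(sum(colSums(narrow_sim$counts) > 0),
            sum(colSums(wide_sim$counts) > 0))
})
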