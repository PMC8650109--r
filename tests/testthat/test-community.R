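test_that("minimum-depth filter keeps the boundary and reports removals", {
  cm <- rbind(a = c(x = 4999L, y = 0L),
              b = c(x = 4000L, y = 1000L),
              c = c(x = 7000L, y = 1000L))
  out <- filter_min_depth(cm, 5000)
  expect_setequal(rownames(out), c("b", "c"))
  expect_identical(attr(out, "removed_samples"), "a")

  # min_reads = 0 is the identity on samples
  expect_equal(rownames(filter_min_depth(cm, 0)), rownames(cm))
  # idempotent
  out2 <- filter_min_depth(out, 5000)
  expect_equal(unclass(out2), unclass(out)[, colnames(out2)],
               ignore_attr = TRUE)
  expect_error(filter_min_depth(cm, 1e7), "all samples")
})

test_that("rarefaction hits the target depth exactly and reproducibly", {
  set.seed(3)
  cm <- matrix(rpois(5 * 20, 40), 5, 20,
               dimnames = list(paste0("s", 1:5), paste0("t", 1:20)))
  storage.mode(cm) <- "integer"
  r <- rarefy_counts(cm, 300)
  expect_true(all(rowSums(r) == 300))
  expect_true(all(r <= cm))
  set.seed(11); r1 <- rarefy_counts(cm, 300)
  set.seed(11); r2 <- rarefy_counts(cm, 300)
  expect_identical(r1, r2)

  # sample already at depth is unchanged; single-taxon sample is certain
  one <- matrix(c(10L, 0L), 1, 2, dimnames = list("s", c("A", "B")))
  expect_equal(as.vector(rarefy_counts(one, 5)), c(5, 0))
  expect_error(rarefy_counts(cm, 1e6), "below rarefaction depth")
})

test_that("rarefaction draws are hypergeometric", {
  cm <- matrix(c(50L, 50L), 1, 2, dimnames = list("s", c("A", "B")))
  set.seed(21)
  draws <- replicate(4000, rarefy_counts(cm, 10)[1, "A"])
  # hypergeometric mean 5, variance 10 * .5 * .5 * (90/99)
  v <- 10 * 0.25 * 90 / 99
  expect_lt(abs(mean(draws) - 5), 3 * sqrt(v / 4000))
  expect_lt(abs(var(draws) - v), 4 * v / sqrt(4000))
})

test_that("relative abundance normalizes rows to one", {
  cm <- rbind(a = c(A = 2, B = 2), b = c(A = 1, B = 0))
  ra <- relative_abundance(cm)
  expect_equal(ra["a", ], c(A = .5, B = .5))
  expect_equal(ra["b", "A"], 1)
  set.seed(4)
  big <- matrix(rexp(300), 15, 20,
                dimnames = list(paste0("s", 1:15), paste0("t", 1:20)))
  expect_true(all(abs(rowSums(relative_abundance(big)) - 1) < 1e-12))
})

test_that("Bray-Curtis matches the formula and is order-invariant", {
  cm <- rbind(x = c(6, 0, 2), y = c(2, 4, 0))
  colnames(cm) <- c("a", "b", "c")
  bc <- bray_curtis(cm)
  expect_equal(bc["x", "y"], 10 / 14, tolerance = 1e-12)

  cm2 <- rbind(s1 = c(t1 = 3, t2 = 1, t3 = 0), s2 = c(t1 = 3, t2 = 1, t3 = 0),
               s3 = c(t1 = 0, t2 = 0, t3 = 5))
  bc2 <- bray_curtis(cm2)
  expect_equal(bc2["s1", "s2"], 0)   # identical samples
  expect_equal(bc2["s1", "s3"], 1)   # disjoint samples
  set.seed(9)
  cm3 <- matrix(rpois(60, 4), 6, 10,
                dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  perm <- sample(10)
  expect_equal(bray_curtis(cm3), bray_curtis(cm3[, perm]), tolerance = 1e-12)
})

test_that("abundance tables round-trip through TSV in both orientations", {
  set.seed(12)
  cm <- matrix(rpois(12, 5), 3, 4,
               dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  for (o in c("taxa_rows", "samples_rows")) {
    p <- withr::local_tempfile(fileext = ".tsv")
    write_abundance_table(cm, p, orientation = o)
    expect_equal(read_abundance_table(p, orientation = o), cm)
  }
})

test_that("input validation flags tree/table/metadata disagreements", {
  tr <- read_phylo(toy_newick)
  cm <- matrix(1L, 2, 2, dimnames = list(c("s1", "s2"), c("A", "Z")))
  expect_error(validate_inputs(cm, tr), "absent from tree")
  md <- data.frame(sample = "s1")
  cm2 <- matrix(1L, 2, 2, dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_error(validate_inputs(cm2, tr, md), "without metadata")
  rep <- validate_inputs(cm2, tr, data.frame(sample = c("s1", "s2", "s3")),
                         raise = FALSE)
  expect_length(rep$errors, 0)
  expect_match(rep$warnings, "unused", all = FALSE)
})
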