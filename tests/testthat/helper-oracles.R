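# Independent oracles used across the suite: deliberately brute-force and
# kept free of the package's own computational paths.

toy_newick <- "((A:1,B:1):1,(C:1,D:1):1);"

# all-pairs patristic distances by Floyd-Warshall over the tree's node graph
brute_patristic <- function(tree) {
  n_node <- max(tree$edge)
  d <- matrix(Inf, n_node, n_node)
  diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    d[a, b] <- d[b, a] <- tree$edge.length[e]
  }
  for (k in seq_len(n_node))
    for (i in seq_len(n_node))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  ntip <- length(tree$tip.label)
  out <- d[seq_len(ntip), seq_len(ntip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# betaMNTD straight from its definition, double loop, no shared code
brute_bmntd <- function(abund_a, abund_b, dm) {
  fa <- abund_a[abund_a > 0]; fa <- fa / sum(fa)
  fb <- abund_b[abund_b > 0]; fb <- fb / sum(fb)
  s1 <- 0
  for (i in names(fa)) s1 <- s1 + fa[[i]] * min(dm[i, names(fb)])
  s2 <- 0
  for (j in names(fb)) s2 <- s2 + fb[[j]] * min(dm[j, names(fa)])
  0.5 * (s1 + s2)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1))
    for (k in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
  out
}

# random tree + community fixture
random_instance <- function(n_taxa, n_samples, max_count = 9) {
  tree <- ape::rtree(n_taxa)
  cm <- matrix(sample(0:max_count, n_samples * n_taxa, replace = TRUE),
               n_samples, n_taxa,
               dimnames = list(paste0("s", seq_len(n_samples)),
                               tree$tip.label))
  # no empty samples
  for (s in seq_len(n_samples))
    if (sum(cm[s, ]) == 0) cm[s, sample(n_taxa, 1)] <- 1L
  list(tree = tree, counts = cm)
}

expected_modal <- c(
  homogeneous_selection = "homogeneous_selection",
  variable_selection = "variable_selection",
  dispersal_limitation = "dispersal_limitation",
  homogenizing_dispersal = "homogenizing_dispersal",
  drift = "undominated"
)

# the reduced validation design used by the recovery experiments
recovery_config <- function(regime, seed)
  sim_config(regime = regime, n_taxa = 150, slopes = 1, locations = 3,
             depths = 2, times = 2, reads = 1000, seed = seed)
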