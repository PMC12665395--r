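# Shared fixtures, all built in code.

# deterministic random tree with branch lengths in [lo, hi]
fixture_tree <- function(n, seed = 1, lo = 0.05, hi = 0.3) {
  with_seed(seed, ape::rtree(n, br = function(k) runif(k, lo, hi)))
}

# small homogeneous DNA superalignment simulated on a known tree
fixture_homogeneous <- function(n_taxa = 10, L = 5000, seed = 3,
                                tree_seed = 2) {
  sp <- fixture_tree(n_taxa, seed = tree_seed, lo = 0.1, hi = 0.4)
  aln <- ils_like_dataset(list(list(tree = sp, weight = 1)),
                          n_genes = 10L, gene_length = L %/% 10L,
                          seed = seed)
  list(tree = sp, aln = aln)
}

# tiny 4-taxon alignment built by hand
fixture_tiny <- function() {
  superalignment(c(A = "ACGTACGTAC", B = "ACGTACGTAT",
                   C = "TCGAACGTAC", D = "TCGAACGAAC"))
}

expect_phylo_equal <- function(t1, t2) {
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
}
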