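test_that("sequence evolution respects branch lengths and the JC model", {
  tr <- fixture_tree(6, seed = 1)
  tr0 <- tr; tr0$edge.length[] <- 0
  aln0 <- with_seed(2, evolve_gene(tr0, 200))
  m <- as.matrix(aln0)
  expect_true(all(m == rep(m[1, ], each = nrow(m))))

  # two taxa, total path 0.3041: expected p-distance 0.25 (inverse JC)
  two <- parse_newick("(a:0.15205,b:0.15205);")
  aln <- with_seed(3, evolve_gene(two, 1e5))
  mm <- as.matrix(aln)
  p_hat <- mean(mm[1, ] != mm[2, ])
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_lt(abs(p_hat - 0.25), 3 * se)

  # per-site independence: lag-1 autocorrelation of mismatch indicators ~ 0
  mis <- as.integer(mm[1, ] != mm[2, ])
  r1 <- stats::cor(mis[-1], mis[-length(mis)])
  expect_lt(abs(r1), 3 / sqrt(length(mis)))

  topo <- tr; topo$edge.length <- NULL
  expect_error(evolve_gene(topo, 10), "branch lengths")
})

test_that("mixture datasets concatenate to the exact total length with a
           faithful partition map and truth record", {
  sp <- fixture_tree(5, seed = 4)
  aln <- ils_like_dataset(list(list(tree = sp, weight = 1)),
                          n_genes = 100, gene_length = 1600, seed = 5)
  expect_equal(aln$L, 160000L)
  expect_equal(nrow(aln$partition_map), 100L)
  expect_equal(aln$partition_map$end[100], 160000L)
  truth <- attr(aln, "truth")
  expect_true(all(truth$class == 1L))  # single-class homogeneous control

  expect_error(ils_like_dataset(list(list(tree = sp, weight = 0.6),
                                     list(tree = sp, weight = 0.6))),
               "sum to 1")
  other <- ape::rtree(5, tip.label = paste0("x", 1:5))
  expect_error(ils_like_dataset(list(list(tree = sp, weight = 0.5),
                                     list(tree = other, weight = 0.5))),
               "mismatched")
})

test_that("a 50/50 NNI mixture leaves the conflicting clade in about half
           of the gene trees", {
  base <- fixture_tree(8, seed = 6, lo = 0.15, hi = 0.5)
  alt <- nni_variant(base)
  taxa <- sort(base$tip.label)
  conflict <- setdiff(bipartitions(ape::unroot(base), taxa),
                      bipartitions(alt, taxa))
  aln <- ils_like_dataset(list(list(tree = base, weight = 0.5),
                               list(tree = alt, weight = 0.5)),
                          n_genes = 100, gene_length = 400, seed = 7)
  pm <- aln$partition_map
  aln_m <- as.matrix(aln)
  has_conflict <- vapply(seq_len(nrow(pm)), function(g) {
    cols <- pm$start[g]:pm$end[g]
    gene <- superalignment(aln_m[, cols])
    tr <- suppressWarnings(
      infer_tree(gene, NULL, engine_config("builtin_nj", "jc")))
    conflict %in% bipartitions(tr, taxa)
  }, logical(1))
  expect_gte(mean(has_conflict), 0.40)
  expect_lte(mean(has_conflict), 0.60)
})

test_that("branch scaling drives gene-tree estimation error while the
           concatenated signal stays consistent", {
  sp <- fixture_tree(10, seed = 8, lo = 0.1, hi = 0.4)
  taxa <- sort(sp$tip.label)
  rf_at <- function(scale, n_genes = 15) {
    genes <- gtee_dataset(sp, scale = scale, n_genes = n_genes,
                          gene_length = 400, seed = 9)
    mean(vapply(genes, function(g) {
      tr <- suppressWarnings(
        infer_tree(g, NULL, engine_config("builtin_nj", "jc")))
      phangorn::RF.dist(tr, ape::unroot(sp))
    }, numeric(1)))
  }
  expect_gt(rf_at(0.05), rf_at(1))

  # scaling multiplies total tree length exactly
  sc <- sp; sc$edge.length <- sc$edge.length * 0.05
  expect_equal(sum(sc$edge.length), 0.05 * sum(sp$edge.length))

  # concatenation of many low-scale genes still recovers the species tree
  cat_aln <- ils_like_dataset(list(list(tree = sp, weight = 1)),
                              n_genes = 100, gene_length = 400,
                              scale = 0.05, seed = 10)
  big <- infer_tree(cat_aln, NULL, engine_config("builtin_nj", "jc"))
  expect_equal(phangorn::RF.dist(big, ape::unroot(sp)), 0)
})

test_that("missing-data injection hits the requested fractions", {
  sim <- fixture_homogeneous(n_taxa = 5, L = 10000, seed = 11,
                             tree_seed = 12)
  tx <- sim$aln$labels[1]
  fr <- stats::setNames(0.959, tx)
  out <- inject_missing(sim$aln, fr, seed = 13)
  mf <- coverage_profile(out)$mf[match(tx, out$labels)]
  expect_equal(mf, 0.959, tolerance = 1e-3)
  untouched <- setdiff(out$labels, tx)[1]
  expect_identical(out$seqs[[untouched]], sim$aln$seqs[[untouched]])

  same <- inject_missing(sim$aln, stats::setNames(0, tx), seed = 14)
  expect_identical(as.matrix(same), as.matrix(sim$aln))

  expect_error(inject_missing(sim$aln, stats::setNames(1, tx)), "no data")
  expect_error(inject_missing(sim$aln, stats::setNames(0.5, "ghost")),
               "named by taxa")

  # informative sites per subsample follow the hypergeometric mean l(1-mf)
  l <- 400L
  inf_counts <- with_seed(15, vapply(1:40, function(r) {
    idx <- draw_subsample(out$L, l)$indices
    sum(out$seqs[[tx]][idx] %in% charToRaw("ACGTU"))
  }, numeric(1)))
  expect_equal(mean(inf_counts), l * (1 - 0.959), tolerance = 0.15)
})

test_that("skewed gene lengths hit the target skewness regime", {
  lens <- skewed_gene_lengths(1245, 970, 3.2, seed = 16)
  expect_true(all(lens >= 1))
  expect_equal(mean(lens), 970, tolerance = 0.15 * 970)
  sk <- mean((lens - mean(lens))^3) / sd(lens)^3
  expect_gte(sk, 2.5); expect_lte(sk, 4.0)

  expect_equal(skewed_gene_lengths(10, 500, 0), rep(500L, 10))
  expect_error(skewed_gene_lengths(10, 500, -1), "symmetric")
})

test_that("equal-length subsamples are far more homogeneous than genes
           (substitution-count uniformity)", {
  # genes with skewed lengths vary wildly in how many substitutions they
  # carry; fixed-size random site subsamples do not
  sp <- fixture_tree(6, seed = 17, lo = 0.1, hi = 0.3)
  lens <- skewed_gene_lengths(60, 200, 3.0, seed = 18)
  aln <- ils_like_dataset(list(list(tree = sp, weight = 1)),
                          n_genes = 60, gene_length = lens, seed = 19)
  m <- as.matrix(aln)
  # crude per-site substitution signal: does the site vary at all
  varying <- apply(m, 2, function(col) length(unique(col)) > 1)
  pm <- aln$partition_map
  per_gene <- vapply(seq_len(nrow(pm)), function(g)
    sum(varying[pm$start[g]:pm$end[g]]), numeric(1))
  l <- 200L
  per_sub <- with_seed(20, vapply(1:60, function(r)
    sum(varying[draw_subsample(aln$L, l)$indices]), numeric(1)))
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(per_sub), 0.5 * cv(per_gene))
})
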