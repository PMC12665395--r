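test_that("bipartitions enumerate non-trivial splits canonically", {
  taxa4 <- c("A", "B", "C", "D")
  tr <- parse_newick("((A,B),(C,D));")
  b <- bipartitions(tr, taxa4)
  expect_length(b, 1L)
  expect_setequal(key_to_taxa(b, taxa4), c("C", "D"))  # side without A

  star <- parse_newick("(A,B,C,D,E);")
  expect_length(bipartitions(star, c("A", "B", "C", "D", "E")), 0L)

  cat6 <- parse_newick("(A,(B,(C,(D,(E,F)))));")
  expect_length(bipartitions(ape::unroot(cat6), LETTERS[1:6]), 3L)

  expect_error(bipartitions(tr, c("A", "B", "C", "E")), "differing.*[DE]")
})

test_that("bcl values are replicate-tree frequencies on the 100/R grid", {
  taxa <- c("A", "B", "C", "D")
  t_ab <- parse_newick("((A,B),(C,D));")
  t_ac <- parse_newick("((A,C),(B,D));")
  trees <- c(rep(list(t_ab), 9), rep(list(t_ac), 11))
  m <- bcl_for_subsample(trees, taxa)
  expect_equal(unname(m[split_key(c("C", "D"), taxa)]), 45)
  expect_equal(unname(m[split_key(c("B", "D"), taxa)]), 55)
  expect_true(all(m %% 5 == 0))  # R = 20 means 5-point resolution

  all_ab <- bcl_for_subsample(rep(list(t_ab), 20), taxa)
  expect_equal(unname(all_ab), 100, ignore_attr = TRUE)
})

test_that("aggregation unions clades, fills absences with 0, checks R", {
  taxa <- c("A", "B", "C", "D")
  t_ab <- parse_newick("((A,B),(C,D));")
  t_ac <- parse_newick("((A,C),(B,D));")
  m1 <- bcl_for_subsample(rep(list(t_ab), 4), taxa)
  m2 <- bcl_for_subsample(rep(list(t_ac), 4), taxa)
  bcl <- aggregate_bcl(list(m1, m1, m2, m2))
  k_ab <- split_key(c("C", "D"), taxa)
  expect_equal(unname(bcl$values[, k_ab]), c(100, 100, 0, 0))
  expect_equal(bcl$S, 4L)

  # clade never seen in any tree is absent from the output
  k_ad <- split_key(c("B", "C"), taxa)
  expect_false(k_ad %in% bcl$clades)

  m3 <- bcl_for_subsample(rep(list(t_ab), 10), taxa)
  expect_error(aggregate_bcl(list(m1, m3)), "differing")
})

test_that("per-tree split budget is conserved for binary replicate trees", {
  # sum over clades of a subsample's bcl = 100 * (n - 3) for binary trees
  sim <- fixture_homogeneous(n_taxa = 7, L = 1400, seed = 51, tree_seed = 52)
  cfg <- engine_config()
  sub <- with_seed(53, draw_subsample(sim$aln$L, 200))
  trees <- with_seed(54, lapply(1:10, function(j)
    infer_tree(sim$aln, upsample_replicate(sub), cfg)))
  m <- bcl_for_subsample(trees, sim$aln$labels)
  expect_equal(sum(m), 100 * (7 - 3))
})

test_that("NBS, FBS estimate and OC identities hold", {
  expect_equal(nbs(c(100, 100, 0, 0)), 50)
  expect_equal(nbs(c(95, 95, 95, 95)), 95)
  expect_equal(fbs_estimate(c(100, 100, 0, 0)), 50)
  expect_equal(fbs_estimate(c(0, 0, 100)), 0)
  expect_equal(fbs_estimate(c(100, 90, 95)), 95)

  # the contested-clade arithmetic: FBS 100 but mean bcl 46 gives OC 54
  x <- c(rep(100, 46), rep(0, 54))
  expect_equal(overconfidence(x, FBS_ref = 100), 54)
  # symmetric distribution around the reference: OC = 0
  expect_equal(overconfidence(c(40, 60, 50, 30, 70), FBS_ref = 50), 0)
  expect_equal(overconfidence(c(80, 80, 80)), 0)  # FBS_ref = mean = median

  # degenerate distribution: mean = median = v, OC = 0
  v <- rep(85, 6)
  expect_equal(nbs(v), 85)
  expect_equal(fbs_estimate(v), 85)
  expect_equal(overconfidence(v), 0)
})

test_that("rmsd_step is the root mean square of NBS changes", {
  expect_equal(rmsd_step(c(0.5, 0.7), c(0.5, 0.7)), 0)
  expect_equal(rmsd_step(c(0, 0), c(0.03, 0.04)), sqrt(0.00125))
  expect_equal(round(rmsd_step(c(0, 0), c(0.03, 0.04)), 5), 0.03536)
  expect_equal(rmsd_step(0.10, 0.15), 0.05)  # boundary: not < 0.05
  expect_error(rmsd_step(numeric(0), numeric(0)), "C = 0")
  expect_error(rmsd_step(c(1, 2), 1), "same clade set")
})

test_that("adaptive run stops after two stable iterations and is
           deterministic", {
  sim <- fixture_homogeneous(n_taxa = 8, L = 4000, seed = 61, tree_seed = 62)
  # deep fixture branches make occasional replicate pairs saturate under
  # JC; the cap warning is expected behaviour here
  res <- suppressWarnings(
    adaptive_nbs_run(sim$aln, engine_config("builtin_nj", "jc"),
                     s0 = 5, R = 20, seed = 63, modality = FALSE))
  expect_true(res$converged)
  # strong homogeneous signal: NBS identical across added iterations,
  # so the run stops at exactly s0 + 2 subsamples
  expect_equal(res$bcl$S, 7L)
  expect_true(all(res$history$rmsd < 0.05))

  res2 <- suppressWarnings(
    adaptive_nbs_run(sim$aln, engine_config("builtin_nj", "jc"),
                     s0 = 5, R = 20, seed = 63, modality = FALSE))
  expect_identical(res$records, res2$records)
  expect_identical(write_newick(res$consensus), write_newick(res2$consensus))

  # s_max exhaustion flags non-convergence
  capped <- suppressWarnings(
    adaptive_nbs_run(sim$aln, engine_config("builtin_nj", "jc"),
                     s0 = 2, R = 3, s_max = 3, seed = 64,
                     rmsd_tol = 1e-9, modality = FALSE))
  expect_false(capped$converged)
})

test_that("NBS equals the clade frequency over pooled replicate trees
           when R is constant (oracle equivalence)", {
  sim <- fixture_homogeneous(n_taxa = 6, L = 1200, seed = 71, tree_seed = 72)
  cfg <- engine_config()
  S <- 4L; R <- 6L
  maps <- list(); pooled <- list()
  for (i in seq_len(S)) {
    sub <- with_seed(derive_seed(73, i), draw_subsample(sim$aln$L, 150))
    trees <- lapply(seq_len(R), function(j)
      with_seed(derive_seed(73, i, j),
                infer_tree(sim$aln, upsample_replicate(sub), cfg)))
    maps[[i]] <- bcl_for_subsample(trees, sim$aln$labels)
    pooled <- c(pooled, trees)
  }
  bcl <- aggregate_bcl(maps)
  pooled_freq <- vapply(bcl$clades, function(k)
    100 * mean(vapply(pooled, function(tr)
      k %in% bipartitions(tr, sim$aln$labels), logical(1))),
    numeric(1))
  expect_equal(nbs(bcl), pooled_freq, tolerance = 1e-12)
  # every bcl value sits on the 100/R grid
  g <- bcl$values / (100 / R)
  expect_true(all(abs(g - round(g)) < 1e-9))
})

test_that("adaptive run skips subsamples that blank out a taxon", {
  sim <- fixture_homogeneous(n_taxa = 6, L = 600, seed = 81, tree_seed = 82)
  # make one taxon almost entirely missing so small subsamples often
  # contain no informative site for it
  sparse <- inject_missing(sim$aln,
                           c(t1 = 0.9)[intersect("t1", sim$aln$labels)],
                           seed = 83)
  expect_warning(
    res <- adaptive_nbs_run(sparse, engine_config(), l = 5L, s0 = 2, R = 2,
                            s_max = 3, seed = 84, modality = FALSE),
    "skipped")
  expect_true(length(res$manifest$skipped_subsamples) >= 1)
})

test_that("greedy consensus keeps the majority clade among conflicts and
           resolves fully consistent runs", {
  taxa <- c("A", "B", "C", "D", "E")
  rec <- data.frame(
    clade = c(split_key(c("B", "C"), taxa), split_key(c("C", "D"), taxa)),
    NBS = c(80, 30))
  cons <- consensus_with_nbs(rec, taxa)
  b <- bipartitions(cons, taxa)
  expect_true(split_key(c("B", "C"), taxa) %in% b)
  expect_false(split_key(c("C", "D"), taxa) %in% b)
  labs <- cons$node.label[!is.na(cons$node.label) & nzchar(cons$node.label)]
  expect_equal(labs, "80")

  # all clades at 100: fully resolved binary consensus
  sim <- fixture_homogeneous(n_taxa = 8, L = 4000, seed = 91, tree_seed = 92)
  res <- adaptive_nbs_run(sim$aln, engine_config(), s0 = 3, R = 5,
                          seed = 93, modality = FALSE)
  strong <- res$records[res$records$NBS == 100, ]
  expect_gte(nrow(strong), 5L)  # n - 3 = 5 true clades
  expect_true(ape::is.binary(ape::unroot(res$consensus)))
  expect_phylo_equal(res$consensus, sim$tree)
})

test_that("consensus >50 clade set is always pairwise compatible", {
  # property suite over random heterogeneous runs
  for (s in 1:25) {
    base <- fixture_tree(7, seed = 100 + s)
    alt <- nni_variant(base)
    aln <- ils_like_dataset(list(list(tree = base, weight = 0.5),
                                 list(tree = alt, weight = 0.5)),
                            n_genes = 8, gene_length = 60,
                            seed = 200 + s)
    res <- adaptive_nbs_run(aln, engine_config(), s0 = 3, R = 4, s_max = 6,
                            seed = 300 + s, modality = FALSE)
    maj <- res$records[res$records$NBS > 50, "clade"]
    if (length(maj) >= 2) {
      prs <- utils::combn(maj, 2)
      for (p in seq_len(ncol(prs)))
        expect_true(keys_compatible(prs[1, p], prs[2, p]))
    }
    # and the consensus must contain every >50 clade
    expect_true(all(maj %in% bipartitions(res$consensus, res$taxa)))
  }
})

test_that("map_supports annotates references and rejects taxon mismatches", {
  sim <- fixture_homogeneous(n_taxa = 8, L = 4000, seed = 111,
                             tree_seed = 112)
  res <- adaptive_nbs_run(sim$aln, engine_config(), s0 = 3, R = 5,
                          seed = 113, modality = FALSE)
  ann <- map_supports(res$consensus, res)
  keep <- function(x) sort(x[!is.na(x) & nzchar(x)])
  expect_identical(keep(ann$node.label), keep(res$consensus$node.label))

  # reference holding a clade never observed gets 0 there
  taxa <- res$taxa
  never <- ape::rtree(8, tip.label = taxa)
  ann2 <- map_supports(never, res)
  tab <- attr(ann2, "table")
  expect_true(all(tab$NBS >= 0))
  seen <- res$records$clade
  unseen_rows <- !(tab$clade %in% seen)
  if (any(unseen_rows)) expect_true(all(tab$NBS[unseen_rows] == 0))

  extra <- ape::rtree(9, tip.label = c(taxa, "intruder"))
  expect_error(map_supports(extra, res), "intruder")
})

test_that("validation mode reports per-clade deltas for a doubled
           subsample size", {
  sim <- fixture_homogeneous(n_taxa = 6, L = 2000, seed = 121,
                             tree_seed = 122)
  res <- adaptive_nbs_run(sim$aln, engine_config(), l = 100L, s0 = 3, R = 5,
                          seed = 123, modality = FALSE)
  val <- nbs_validation(sim$aln, res, s_max = 6)
  expect_true(all(c("NBS", "NBS_doubled", "delta") %in% names(val)))
  expect_equal(attr(val, "rerun")$manifest$l, 200L)
  # strong signal: doubling the subsample leaves true clades at 100
  expect_true(all(abs(val$delta[val$NBS == 100]) <= 5))
})
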