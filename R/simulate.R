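#' Simulate a gene alignment along a tree (Jukes-Cantor)
#'
#' Sites evolve independently down the tree under the Jukes-Cantor model:
#' the root sequence is uniform over `A C G T` and along a branch of length
#' `t` (expected substitutions per site) each site changes with probability
#' `(3/4)(1 - exp(-4t/3))`, uniformly to one of the other three bases.
#'
#' @param tree a `phylo` with branch lengths.
#' @param length number of sites (`>= 1`).
#' @return A DNA [superalignment()] on the tree's tips.
#' @export
evolve_gene <- function(tree, length) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; simulation needs them")
  stopifnot(length >= 1)
  length <- as.integer(length)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- base::length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- tree$edge[1L, 1L]
  seqs[[root]] <- sample.int(4L, length, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    p <- 0.75 * (1 - exp(-4 * t / 3))
    s <- seqs[[par]]
    hit <- runif(length) < p
    if (any(hit)) {
      # uniform among the three other bases
      s[hit] <- 1L + (s[hit] - 1L + sample.int(3L, sum(hit),
                                               replace = TRUE)) %% 4L
    }
    seqs[[child]] <- s
  }
  bases <- c("A", "C", "G", "T")
  out <- vapply(seq_len(ntip),
                function(i) paste0(bases[seqs[[i]]], collapse = ""),
                character(1))
  names(out) <- tree$tip.label
  superalignment(out, alphabet = "dna")
}

#' One nearest-neighbour-interchange variant of a tree
#'
#' Picks an internal edge (both endpoints internal) and swaps one subtree
#' across it, producing a topology that conflicts with the original in
#' exactly one bipartition.  Used to build gene-tree mixtures with a known
#' contested clade.
#'
#' @param tree a binary `phylo` with branch lengths.
#' @param edge which eligible internal edge to swap (index into the list of
#'   internal edges, default 1).
#' @return The rearranged `phylo`.
#' @export
nni_variant <- function(tree, edge = 1L) {
  # work unrooted: edges at a degree-2 root are not genuine internal edges
  tree <- stats::reorder(ape::unroot(tree), "cladewise")
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 1L] > ntip & tree$edge[, 2L] > ntip)
  if (length(internal) < edge) stop("tree has only ", length(internal),
                                    " internal edges")
  e <- internal[edge]
  u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
  ch_v <- which(tree$edge[, 1L] == v & seq_len(nrow(tree$edge)) != e)
  ch_u <- which(tree$edge[, 1L] == u & tree$edge[, 2L] != v)
  if (length(ch_v) < 1L || length(ch_u) < 1L) stop("edge is not swappable")
  r1 <- ch_u[1L]   # sibling subtree, moves under v
  r2 <- ch_v[1L]   # first child of v, moves under u
  tree$edge[r1, 1L] <- v
  tree$edge[r2, 1L] <- u
  parse_newick(write_newick(tree))
}

#' Concatenated dataset from a gene-tree topology mixture
#'
#' Emulates gene-tree heterogeneity (for example ILS-like discordance) as a
#' finite mixture: each gene's topology is drawn from weighted classes, the
#' gene evolves under Jukes-Cantor, and the genes are concatenated into one
#' superalignment with a partition map.  A single-class mixture is the
#' homogeneous control.  The per-gene class assignments (the simulation
#' truth) are attached for evaluation.
#'
#' @param mixture list of classes, each `list(tree = phylo, weight = w)`;
#'   weights must sum to 1 and all trees share one taxon set.
#' @param n_genes number of genes.
#' @param gene_length sites per gene: a single number, a vector of length
#'   `n_genes` (for example from [skewed_gene_lengths()]), or a function
#'   `function(n)` returning one.
#' @param scale multiplier applied to every branch length (low values mean
#'   few substitutions per gene, the gene-tree estimation error regime).
#' @param missing optional named per-taxon missing fractions, applied with
#'   [inject_missing()].
#' @param seed master seed.
#' @return A [superalignment()] with `partition_map`; attribute `truth` is a
#'   data frame (`gene`, `class`, `start`, `end`), attribute `weights` the
#'   mixture weights.
#' @export
ils_like_dataset <- function(mixture, n_genes = 100L, gene_length = 1600L,
                             scale = 1, missing = NULL, seed = 1L) {
  stopifnot(length(mixture) >= 1L, n_genes >= 1L, scale > 0)
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  taxa <- sort(mixture[[1L]]$tree$tip.label)
  for (m in mixture)
    if (!identical(sort(m$tree$tip.label), taxa))
      stop("mixture topologies have mismatched taxon sets")
  lens <- if (is.function(gene_length)) {
    with_seed(derive_seed(seed, 1L), as.integer(gene_length(n_genes)))
  } else if (length(gene_length) == 1L) {
    rep.int(as.integer(gene_length), n_genes)
  } else {
    stopifnot(length(gene_length) == n_genes)
    as.integer(gene_length)
  }
  stopifnot(all(lens >= 1L))
  classes <- with_seed(derive_seed(seed, 2L),
                       sample.int(length(mixture), n_genes, replace = TRUE,
                                  prob = w))
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    tr <- mixture[[classes[g]]]$tree
    if (scale != 1) tr$edge.length <- tr$edge.length * scale
    genes[[g]] <- with_seed(derive_seed(seed, 3L, g),
                            evolve_gene(tr, lens[g]))
  }
  # concatenate in the taxon order of the first class's tree tips (sorted)
  cat_seqs <- vapply(taxa, function(tx)
    paste0(vapply(genes, function(gn) rawToChar(gn$seqs[[tx]]),
                  character(1)),
           collapse = ""),
    character(1))
  ends <- cumsum(lens)
  pm <- data.frame(name = sprintf("gene%04d", seq_len(n_genes)),
                   start = c(1L, utils::head(ends, -1L) + 1L),
                   end = ends)
  aln <- superalignment(cat_seqs, alphabet = "dna", partition_map = pm)
  if (!is.null(missing))
    aln <- inject_missing(aln, missing, seed = derive_seed(seed, 4L))
  attr(aln, "truth") <- data.frame(gene = pm$name, class = classes,
                                   start = pm$start, end = pm$end)
  attr(aln, "weights") <- w
  aln
}

#' Gene alignments under uniform branch-length scaling (GTEE regimes)
#'
#' Every gene shares the species topology, but all branch lengths are
#' multiplied by `scale`; small scales (0.1, 0.07, 0.05) leave each gene
#' with so few substitutions that individual gene trees are estimated with
#' high error, while the concatenated signal stays consistent.
#'
#' @param species_tree `phylo` with branch lengths.
#' @param scale branch-length multiplier.
#' @param n_genes number of genes.
#' @param gene_length sites per gene.
#' @param seed master seed.
#' @return List of `n_genes` gene [superalignment()]s.
#' @export
gtee_dataset <- function(species_tree, scale = 0.05, n_genes = 1000L,
                         gene_length = 1600L, seed = 1L) {
  stopifnot(scale > 0)
  tr <- species_tree
  tr$edge.length <- tr$edge.length * scale
  lapply(seq_len(n_genes), function(g)
    with_seed(derive_seed(seed, 5L, g), evolve_gene(tr, gene_length)))
}

#' Replace residues with missing data
#'
#' Replaces a per-taxon fraction of sites with `?`, uniformly at random,
#' to emulate data-poor taxa.
#'
#' @param aln a [superalignment()].
#' @param fractions named numeric vector of missing fractions in `[0, 1)`;
#'   taxa not named are untouched.
#' @param seed seed.
#' @return The modified [superalignment()].
#' @export
inject_missing <- function(aln, fractions, seed = 1L) {
  stopifnot(inherits(aln, "superalignment"))
  if (is.null(names(fractions)) || !all(names(fractions) %in% aln$labels))
    stop("fractions must be named by taxa present in the alignment")
  if (any(fractions >= 1))
    stop("missing fraction of 1 would leave a taxon with no data")
  if (any(fractions < 0)) stop("fractions must be in [0, 1)")
  chr <- vapply(aln$seqs, rawToChar, character(1))
  q <- charToRaw("?")
  with_seed(seed, {
    for (tx in names(fractions)) {
      k <- round(fractions[[tx]] * aln$L)
      if (k == 0) next
      r <- aln$seqs[[tx]]
      r[sample.int(aln$L, k)] <- q
      chr[[tx]] <- rawToChar(r)
    }
  })
  superalignment(chr, alphabet = aln$alphabet,
                 partition_map = aln$partition_map)
}

#' Skewed gene lengths (lognormal)
#'
#' Empirical phylogenomic gene-length distributions are strongly
#' right-skewed.  Lengths are drawn lognormal with `sigma` solved
#' numerically so the distribution skewness matches `target_skewness`
#' (lognormal skewness is `(w + 2) * sqrt(w - 1)` with `w = exp(sigma^2)`)
#' and `mu` set so the mean equals `mean_length`.
#'
#' @param n_genes number of lengths.
#' @param mean_length target mean (`>= 50`).
#' @param target_skewness nonnegative; 0 returns constant lengths, negative
#'   targets are unattainable for a lognormal (use a symmetric sampler).
#' @param seed seed.
#' @return Integer vector of `n_genes` lengths (all `>= 1`).
#' @export
skewed_gene_lengths <- function(n_genes, mean_length, target_skewness,
                                seed = 1L) {
  stopifnot(n_genes >= 1, mean_length >= 50)
  if (target_skewness < 0)
    stop("negative skewness is unattainable for a lognormal sampler; ",
         "use a symmetric length distribution instead")
  if (target_skewness == 0)
    return(rep.int(as.integer(round(mean_length)), n_genes))
  skew_of <- function(s) { w <- exp(s^2); (w + 2) * sqrt(w - 1) }
  sigma <- stats::uniroot(function(s) skew_of(s) - target_skewness,
                          c(1e-6, 4))$root
  mu <- log(mean_length) - sigma^2 / 2
  with_seed(seed, {
    pmax(1L, as.integer(round(stats::rlnorm(n_genes, mu, sigma))))
  })
}
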