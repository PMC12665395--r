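#' Bipartitions (splits) of an unrooted tree
#'
#' Clade identity across replicate trees is the bipartition: the two-way
#' split of the taxon set induced by removing one internal branch.  Splits
#' are encoded canonically as a binary membership string over a fixed global
#' taxon ordering, using the side that does not contain the first taxon;
#' trivial splits (a side with fewer than 2 taxa) are excluded.
#'
#' @param tree a `phylo` tree whose tips are exactly `taxa`.
#' @param taxa character vector fixing the global taxon ordering.
#' @return Character vector of canonical split keys (possibly empty for a
#'   star tree).
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' bipartitions(tr, c("A", "B", "C", "D"))
#' @export
bipartitions <- function(tree, taxa) {
  unique(unname(node_split_keys(tree, taxa)))
}

# named vector: canonical split key per internal node (non-root, non-trivial)
node_split_keys <- function(tree, taxa) {
  if (!setequal(tree$tip.label, taxa))
    stop("tree tips do not match the global taxon set; differing: ",
         paste(c(setdiff(tree$tip.label, taxa), setdiff(taxa, tree$tip.label)),
               collapse = ", "))
  n <- length(taxa)
  pp <- ape::prop.part(tree)
  nodes <- (n + 1L):(n + tree$Nnode)
  keys <- character(0)
  for (k in seq_along(pp)) {
    tips <- tree$tip.label[pp[[k]]]
    m <- length(tips)
    if (m < 2L || m > n - 2L) next
    keys[as.character(nodes[k])] <- split_key(tips, taxa)
  }
  keys
}

fmt_support <- function(v) format(v, digits = 6, trim = TRUE, scientific = FALSE)

split_key <- function(tips, taxa) {
  member <- taxa %in% tips
  if (member[1L]) member <- !member
  paste0(as.integer(member), collapse = "")
}

key_to_taxa <- function(key, taxa) {
  taxa[strsplit(key, "")[[1L]] == "1"]
}

# splits compatible iff (as sets excluding the reference taxon) nested/disjoint
keys_compatible <- function(k1, k2) {
  m1 <- strsplit(k1, "")[[1L]] == "1"
  m2 <- strsplit(k2, "")[[1L]] == "1"
  both <- m1 & m2
  !any(both) || all(m1[m2]) || all(m2[m1])
}

#' Per-subsample bcl values from replicate trees
#'
#' The bootstrap confidence limit (bcl) of a clade within one subsample is
#' the percentage of that subsample's upsampled replicate trees containing
#' the clade.  With `R` replicates the values lie on a `100/R` grid; the
#' default `R = 20` gives 5-point resolution.
#'
#' @param trees list of `phylo` replicate trees (failed replicates as `NULL`
#'   are dropped and counted).
#' @param taxa global taxon ordering.
#' @return Named numeric vector (percent) over the clades present in at
#'   least one tree; attributes `R` (trees used) and `n_failed`.
#' @export
bcl_for_subsample <- function(trees, taxa) {
  failed <- sum(vapply(trees, is.null, logical(1)))
  trees <- Filter(Negate(is.null), trees)
  if (length(trees) < 1L) stop("no successful replicate trees")
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (k in bipartitions(tr, taxa)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  out <- vapply(keys, function(k) 100 * counts[[k]] / length(trees),
                numeric(1))
  attr(out, "R") <- length(trees)
  attr(out, "n_failed") <- failed
  out
}

#' Aggregate per-subsample bcl maps into bcl distributions
#'
#' The union of clades over subsamples is taken; a clade missing from a
#' subsample's replicate trees receives bcl = 0 there (absence under
#' resampling is evidence of absence).  Every distribution therefore has
#' length `S`.
#'
#' @param maps list of [bcl_for_subsample()] results with a common `R`.
#' @return A `bcl_set`: list with `clades` (keys), `values` (S-by-K percent
#'   matrix, columns named by clade key), `S`, `R`.
#' @export
aggregate_bcl <- function(maps) {
  stopifnot(length(maps) >= 1L)
  Rs <- vapply(maps, function(m) as.integer(attr(m, "R")), integer(1))
  if (length(unique(Rs)) != 1L)
    stop("subsamples have differing replicate counts R: ",
         paste(unique(Rs), collapse = ", "))
  keys <- sort(unique(unlist(lapply(maps, names))))
  vals <- matrix(0, nrow = length(maps), ncol = length(keys),
                 dimnames = list(NULL, keys))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    vals[i, names(m)] <- as.numeric(m)
  }
  structure(list(clades = keys, values = vals,
                 S = length(maps), R = Rs[1L]),
            class = "bcl_set")
}

#' Net Bootstrap Support, FBS estimate and overconfidence
#'
#' For a clade with subsample bcl values `bcl_1..bcl_S`:
#' `NBS = mean(bcl)` (the net frequency of support across the data, valid
#' whether or not the distribution is unimodal), the Felsenstein bootstrap
#' support is estimated by `fbs = median(bcl)`, and the overconfidence is
#' `OC = FBS - NBS`, the average signed excess of the superalignment
#' bootstrap over subsample-level support.  `OC` is 0 when the bcl
#' distribution is balanced and symmetric around FBS, and large when a
#' clade's support is driven by a fraction of the data.
#'
#' @param x numeric vector of bcl values (percent), or a `bcl_set` (then a
#'   value per clade is returned).
#' @param ... unused.
#' @return Numeric (percent); for `overconfidence` possibly negative.
#' @export
nbs <- function(x, ...) UseMethod("nbs")

#' @rdname nbs
#' @export
nbs.default <- function(x, ...) mean(x)

#' @rdname nbs
#' @export
nbs.bcl_set <- function(x, ...) colMeans(x$values)

#' @rdname nbs
#' @export
fbs_estimate <- function(x, ...) UseMethod("fbs_estimate")

#' @rdname nbs
#' @export
fbs_estimate.default <- function(x, ...) median(x)

#' @rdname nbs
#' @export
fbs_estimate.bcl_set <- function(x, ...) apply(x$values, 2L, median)

#' @rdname nbs
#' @param FBS_ref reference FBS (percent).  Defaults to the median of the
#'   bcl distribution, which approximates the superalignment FBS; supply an
#'   externally computed FBS to measure overconfidence against it.
#' @export
overconfidence <- function(x, FBS_ref = NULL, ...) UseMethod("overconfidence")

#' @rdname nbs
#' @export
overconfidence.default <- function(x, FBS_ref = NULL, ...) {
  if (is.null(FBS_ref)) FBS_ref <- median(x)
  stopifnot(FBS_ref >= 0, FBS_ref <= 100)
  FBS_ref - mean(x)
}

#' @rdname nbs
#' @export
overconfidence.bcl_set <- function(x, FBS_ref = NULL, ...) {
  if (is.null(FBS_ref)) FBS_ref <- fbs_estimate(x)
  FBS_ref - nbs(x)
}

#' RMSD between successive NBS vectors
#'
#' The adaptive stopping rule compares per-clade NBS between successive
#' iterations over the union clade set (clades not yet observed fill in as
#' 0) and stops when the root mean squared deviation falls below a
#' threshold.  Vectors are expected on the proportion scale in `[0, 1]` so
#' the conventional threshold 0.05 means five support points.
#'
#' @param nbs_prev,nbs_curr equal-length numeric vectors on `[0, 1]`.
#' @return `sqrt(mean((nbs_curr - nbs_prev)^2))`.
#' @examples
#' rmsd_step(c(0, 0), c(0.03, 0.04))  # 0.03536
#' @export
rmsd_step <- function(nbs_prev, nbs_curr) {
  if (length(nbs_prev) != length(nbs_curr))
    stop("NBS vectors must cover the same clade set")
  if (length(nbs_prev) == 0L) stop("no clades to compare (C = 0)")
  sqrt(mean((nbs_curr - nbs_prev)^2))
}

#' Adaptive NBS analysis of a superalignment
#'
#' Runs the full little-bootstrap pipeline: draw site subsamples of size `l`,
#' build `R` upsampled full-length replicates per subsample, infer a
#' replicate tree for each, collect per-subsample bcl values, and summarise
#' per clade as NBS (mean), FBS estimate (median) and OC (FBS - NBS).
#' Starting from `s0` subsamples, one subsample is added per iteration and
#' the RMSD of per-clade NBS (proportion scale, union clade set) between
#' successive iterations is tracked; the run stops once the RMSD is below
#' `rmsd_tol` on two consecutive iterations, or at `s_max` subsamples
#' (flagged non-converged).  A subsample in which some taxon has no
#' informative residue is skipped with a warning and redrawn.
#'
#' All randomness is derived from `seed` hierarchically per (subsample,
#' replicate), so results are reproducible and order-independent.
#'
#' @param aln a [superalignment()].
#' @param cfg an [engine_config()].
#' @param g subsampling exponent (used when `l` is `NULL`).
#' @param l subsample size; default [subsample_size()]`(L, g)`.
#' @param s0 initial number of subsamples (default 5).
#' @param R upsampled replicates per subsample (default 20, giving 5-point
#'   bcl resolution).
#' @param rmsd_tol stopping threshold on the proportion-scale RMSD
#'   (default 0.05).
#' @param s_max maximum number of subsamples (default 100).
#' @param seed master seed.
#' @param modality run [classify_modality()] per clade (default TRUE).
#' @param alpha significance level for modality calls.
#' @param n_mc Monte Carlo replicates for the dip test.
#' @param FBS_ref optional externally computed FBS (percent) used for OC
#'   instead of the per-clade median; either a single value or a vector
#'   named by clade key.
#' @return An `nbs_result`: list with `records` (per-clade data frame),
#'   `bcl` (the `bcl_set`), `consensus` (NBS-annotated `phylo`), `history`
#'   (RMSD trace), `converged`, `manifest`.
#' @export
adaptive_nbs_run <- function(aln, cfg = engine_config(), g = 0.7, l = NULL,
                             s0 = 5L, R = 20L, rmsd_tol = 0.05, s_max = 100L,
                             seed = 1L, modality = TRUE, alpha = 0.05,
                             n_mc = 2000L, FBS_ref = NULL) {
  stopifnot(inherits(aln, "superalignment"), s0 >= 1L, R >= 1L, s_max >= s0)
  if (is.null(l)) l <- subsample_size(aln$L, g)
  taxa <- aln$labels
  inf <- informative_bytes(aln$alphabet)
  skipped <- integer(0)

  one_subsample <- function(i) {
    for (attempt in 0:19) {
      sub <- with_seed(derive_seed(seed, i, 0, attempt),
                       draw_subsample(aln$L, l))
      empty <- vapply(aln$seqs,
                      function(r) !any(r[sub$indices] %in% inf), logical(1))
      if (!any(empty)) return(sub)
      warning("subsample ", i, " skipped: taxon '",
              taxa[which(empty)[1L]],
              "' has zero informative sites in it", call. = FALSE)
      skipped <<- c(skipped, i)
    }
    stop("could not draw a usable subsample after 20 attempts; ",
         "consider enforce_sparsity_policy(mode = 'drop')")
  }

  subsample_bcl <- function(i) {
    sub <- one_subsample(i)
    trees <- vector("list", R)
    for (j in seq_len(R)) {
      rw <- with_seed(derive_seed(seed, i, j), upsample_replicate(sub))
      trees[[j]] <- infer_tree(aln, rw, cfg, seed = derive_seed(seed, i, j))
    }
    n_failed <- sum(vapply(trees, is.null, logical(1)))
    if (n_failed > R / 2)
      stop("subsample ", i, ": ", n_failed, " of ", R,
           " replicate inferences failed")
    bcl_for_subsample(trees, taxa)
  }

  maps <- lapply(seq_len(s0), subsample_bcl)
  union_nbs <- function(maps, keys) {
    v <- numeric(length(keys)); names(v) <- keys
    acc <- matrix(0, length(maps), length(keys), dimnames = list(NULL, keys))
    for (i in seq_along(maps)) acc[i, names(maps[[i]])] <- maps[[i]]
    colMeans(acc)
  }

  history <- data.frame(S = integer(0), rmsd = numeric(0))
  converged <- FALSE
  below <- 0L
  S <- s0
  while (S < s_max) {
    keys_prev_ctx <- sort(unique(unlist(lapply(maps, names))))
    S <- S + 1L
    maps[[S]] <- subsample_bcl(S)
    keys <- sort(unique(unlist(lapply(maps, names))))
    nbs_prev <- union_nbs(maps[seq_len(S - 1L)], keys)
    nbs_curr <- union_nbs(maps, keys)
    r <- rmsd_step(nbs_prev / 100, nbs_curr / 100)
    history <- rbind(history, data.frame(S = S, rmsd = r))
    below <- if (r < rmsd_tol) below + 1L else 0L
    if (below >= 2L) { converged <- TRUE; break }
  }

  bcl <- aggregate_bcl(maps)
  NBS <- nbs(bcl); FBS <- fbs_estimate(bcl)
  ref <- if (is.null(FBS_ref)) FBS else {
    if (length(FBS_ref) == 1L) stats::setNames(rep(FBS_ref, length(NBS)),
                                               names(NBS))
    else FBS_ref[names(NBS)]
  }
  OC <- ref - NBS
  records <- data.frame(
    clade = bcl$clades,
    taxa = vapply(bcl$clades,
                  function(k) paste(sort(key_to_taxa(k, taxa)),
                                    collapse = ";"),
                  character(1)),
    NBS = unname(NBS), FBS_est = unname(FBS), OC = unname(OC),
    S = bcl$S, R = bcl$R,
    stringsAsFactors = FALSE, row.names = NULL)

  if (modality && bcl$S >= 4L) {
    null_tab <- with_seed(derive_seed(seed, 999983L),
                          dip_null_table(bcl$S, n_mc))
    mod <- lapply(seq_along(bcl$clades), function(k)
      classify_modality(bcl$values[, k], R = bcl$R, alpha = alpha,
                        n_mc = n_mc, null = null_tab,
                        seed = derive_seed(seed, 999979L, k)))
    records$dip_p <- vapply(mod, function(m) m$dip_p, numeric(1))
    records$n_modes <- vapply(mod, function(m) m$n_modes, numeric(1))
    records$modality <- vapply(mod, function(m) m$verdict, character(1))
  } else {
    records$dip_p <- NA_real_
    records$n_modes <- NA_real_
    records$modality <- "untested"
  }
  records$converged <- converged
  records <- records[order(-records$NBS, records$clade), ]
  row.names(records) <- NULL

  consensus <- consensus_with_nbs(records, taxa)
  manifest <- list(seed = seed, L = aln$L, l = l, g = g, s0 = s0, R = R,
                   rmsd_tol = rmsd_tol, s_max = s_max,
                   rmsd_scale = "proportion",
                   engine = cfg$engine, distance = cfg$distance,
                   model_hint = cfg$model_hint,
                   rmsd_trace = history$rmsd,
                   skipped_subsamples = unique(skipped),
                   converged = converged)
  structure(list(records = records, bcl = bcl, consensus = consensus,
                 history = history, converged = converged,
                 taxa = taxa, manifest = manifest),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("NBS analysis:", length(x$taxa), "taxa,", x$bcl$S, "subsamples x",
      x$bcl$R, "replicates;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat(nrow(x$records), "clades observed; consensus clades:",
      sum(!is.na(x$consensus$node.label)) , "\n")
  invisible(x)
}

#' Greedy majority-rule consensus annotated with NBS
#'
#' Clades with NBS above 50 are mutually compatible whenever `R` is constant
#' (NBS then equals the clade's frequency among the pooled replicate trees)
#' and are all included; remaining clades are added greedily in order of
#' decreasing NBS when compatible with everything already accepted.  NBS
#' values are written as internal node labels.
#'
#' @param records the `records` data frame of an [adaptive_nbs_run()] result
#'   (or the result itself).
#' @param taxa global taxon ordering (taken from the result if omitted).
#' @return A rooted-representation `phylo` with NBS node labels.
#' @export
consensus_with_nbs <- function(records, taxa = NULL) {
  if (inherits(records, "nbs_result")) {
    taxa <- records$taxa
    records <- records$records
  }
  if (is.null(taxa)) stop("taxa ordering required")
  ord <- order(-records$NBS, records$clade)
  keys <- records$clade[ord]; supp <- records$NBS[ord]
  accepted <- character(0); acc_supp <- numeric(0)
  for (i in seq_along(keys)) {
    if (supp[i] > 50 ||
        all(vapply(accepted, keys_compatible, logical(1), k2 = keys[i]))) {
      accepted <- c(accepted, keys[i])
      acc_supp <- c(acc_supp, supp[i])
    }
  }
  build_tree_from_clades(accepted, acc_supp, taxa)
}

# build a rooted-representation tree from a pairwise-compatible clade set
build_tree_from_clades <- function(keys, supports, taxa) {
  clades <- lapply(keys, key_to_taxa, taxa = taxa)
  sizes <- lengths(clades)
  o <- order(-sizes)
  clades <- clades[o]; supports <- supports[o]
  label_of <- function(i) fmt_support(supports[i])
  # recursive newick over the laminar family
  nwk <- function(tipset, cl_idx) {
    # maximal accepted clades strictly inside tipset
    maximal <- integer(0)
    for (i in cl_idx) {
      inside <- all(clades[[i]] %in% tipset) && length(clades[[i]]) < length(tipset)
      if (!inside) next
      dominated <- any(vapply(maximal, function(j)
        all(clades[[i]] %in% clades[[j]]), logical(1)))
      if (!dominated) maximal <- c(maximal, i)
    }
    parts <- character(0)
    used <- character(0)
    for (i in maximal) {
      sub_idx <- cl_idx[vapply(cl_idx, function(j)
        j != i && all(clades[[j]] %in% clades[[i]]), logical(1))]
      parts <- c(parts, paste0(nwk(clades[[i]], sub_idx), label_of(i)))
      used <- c(used, clades[[i]])
    }
    parts <- c(parts, setdiff(tipset, used))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(nwk(taxa, seq_along(clades)), ";")
  parse_newick(txt)
}

#' Map NBS supports onto a reference phylogeny
#'
#' Each internal branch of the reference is annotated with the NBS of its
#' bipartition (0 for clades never observed in any replicate tree); the
#' per-clade table for the reference's clades (NBS, FBS estimate, OC) is
#' attached as attribute `table`.
#'
#' @param reference a `phylo` on the same taxon set.
#' @param result an `nbs_result` (or its `records` data frame plus `taxa`).
#' @param taxa global taxon ordering (taken from the result if omitted).
#' @return The reference tree with NBS node labels and a `table` attribute.
#' @export
map_supports <- function(reference, result, taxa = NULL) {
  if (inherits(result, "nbs_result")) {
    taxa <- result$taxa
    records <- result$records
  } else records <- result
  if (is.null(taxa)) stop("taxa ordering required")
  if (!setequal(reference$tip.label, taxa))
    stop("reference tree taxa differ from alignment taxa: ",
         paste(c(setdiff(reference$tip.label, taxa),
                 setdiff(taxa, reference$tip.label)), collapse = ", "))
  supp <- stats::setNames(records$NBS, records$clade)
  keys <- node_split_keys(reference, taxa)
  labs <- rep("", reference$Nnode)
  ntip <- length(reference$tip.label)
  for (nd in names(keys)) {
    v <- supp[keys[[nd]]]
    labs[as.integer(nd) - ntip] <-
      fmt_support(if (is.na(v)) 0 else v)
  }
  reference$node.label <- labs
  tab <- records[match(keys, records$clade), ]
  tab$clade <- keys
  tab$taxa <- vapply(keys, function(k)
    paste(sort(key_to_taxa(k, taxa)), collapse = ";"), character(1))
  tab$NBS[is.na(tab$NBS)] <- 0
  row.names(tab) <- NULL
  attr(reference, "table") <- tab
  reference
}

annotate_supports <- function(tree, support_by_key) {
  taxa <- tree$tip.label
  keys <- node_split_keys(tree, taxa)
  ntip <- length(taxa)
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", tree$Nnode)
  for (nd in names(keys)) {
    v <- support_by_key[keys[[nd]]]
    if (!is.na(v)) labs[as.integer(nd) - ntip] <-
      fmt_support(v)
  }
  tree$node.label <- labs
  tree
}

#' Validation re-run with doubled subsample size
#'
#' Stability check for a completed analysis: the run is repeated with twice
#' the subsample size (all other settings equal) and per-clade NBS values
#' are compared.  Clades whose support depends strongly on the subsample
#' size warrant caution.
#'
#' @param aln the [superalignment()] analysed.
#' @param result the original `nbs_result`.
#' @param ... overrides passed on to [adaptive_nbs_run()].
#' @return Data frame with `clade`, `taxa`, `NBS`, `NBS_doubled`, `delta`;
#'   the re-run result is attached as attribute `rerun`.
#' @export
nbs_validation <- function(aln, result, ...) {
  stopifnot(inherits(result, "nbs_result"))
  m <- result$manifest
  l2 <- min(2L * m$l, aln$L - 1L)
  args <- list(aln = aln, l = l2, g = m$g, s0 = m$s0, R = m$R,
               rmsd_tol = m$rmsd_tol, s_max = m$s_max,
               seed = derive_seed(m$seed, 424243L), modality = FALSE)
  dots <- list(...)
  args[names(dots)] <- dots
  rerun <- do.call(adaptive_nbs_run, args)
  keys <- union(result$records$clade, rerun$records$clade)
  n1 <- stats::setNames(result$records$NBS, result$records$clade)[keys]
  n2 <- stats::setNames(rerun$records$NBS, rerun$records$clade)[keys]
  n1[is.na(n1)] <- 0; n2[is.na(n2)] <- 0
  out <- data.frame(
    clade = keys,
    taxa = vapply(keys, function(k)
      paste(sort(key_to_taxa(k, result$taxa)), collapse = ";"), character(1)),
    NBS = unname(n1), NBS_doubled = unname(n2),
    delta = unname(n2 - n1), row.names = NULL)
  attr(out, "rerun") <- rerun
  out[order(-abs(out$delta)), ]
}
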