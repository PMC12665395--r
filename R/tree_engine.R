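#' Configure the replicate-tree inference engine
#'
#' The statistics downstream (bcl, NBS, FBS, OC) are engine-agnostic: any
#' program that turns a replicate alignment into an unrooted tree can be
#' used.  The built-in engine computes site-weighted p or Jukes-Cantor
#' distances and runs neighbor joining, which is fast enough to bootstrap
#' thousands of replicates on a desktop.  External maximum-likelihood
#' programs are wrapped through a command template.
#'
#' @param engine `"builtin_nj"` or `"external"`.
#' @param distance `"p"` (proportion of mismatches) or `"jc"`
#'   (Jukes-Cantor corrected), for the built-in engine.
#' @param external_cmd_template command template with placeholders `{aln}`
#'   (replicate FASTA path), `{out}` (output Newick path), `{seed}`; must
#'   exit 0 and write exactly one Newick tree.
#' @param model_hint free-text note recorded in run manifests (for example
#'   the substitution model an external engine was configured with).
#' @param saturation_cap distance assigned (with a warning) to pairs at or
#'   beyond the distance-correction singularity (default 5.0).
#' @return An `engine_config` object.
#' @export
engine_config <- function(engine = c("builtin_nj", "external"),
                          distance = c("p", "jc"),
                          external_cmd_template = NULL,
                          model_hint = NULL,
                          saturation_cap = 5.0) {
  engine <- match.arg(engine)
  distance <- match.arg(distance)
  if (engine == "external" &&
      (is.null(external_cmd_template) || !nzchar(external_cmd_template)))
    stop("external engine requires external_cmd_template")
  structure(list(engine = engine, distance = distance,
                 external_cmd_template = external_cmd_template,
                 model_hint = model_hint,
                 saturation_cap = saturation_cap),
            class = "engine_config")
}

#' Site-weighted pairwise distance matrix
#'
#' For each taxon pair, distances are computed over sites where both taxa
#' carry informative (unambiguous, non-gap) residues — pairwise deletion —
#' with each site contributing its replicate weight:
#' `p = sum(w * mismatch) / sum(w * comparable)`.  The Jukes-Cantor
#' correction is `-(3/4) log(1 - 4p/3)` for DNA and `-(19/20) log(1 - 20p/19)`
#' for protein.  Saturated pairs (`p` at or beyond the correction's domain)
#' are capped at `cap` with a warning rather than erroring, because upsampled
#' replicates of very small subsamples can saturate by chance.
#'
#' @param aln a [superalignment()].
#' @param weights a `replicate_weights` object, or `NULL` for uniform weights
#'   over all sites.
#' @param distance `"p"` or `"jc"`.
#' @param cap distance assigned to saturated pairs.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = labels.
#' @export
weighted_distance_matrix <- function(aln, weights = NULL,
                                     distance = c("p", "jc"), cap = 5.0) {
  distance <- match.arg(distance)
  stopifnot(inherits(aln, "superalignment"))
  n <- length(aln$labels)
  if (n < 4L) stop("need at least 4 taxa, got ", n)
  if (is.null(weights)) {
    sites <- seq_len(aln$L)
    w <- rep.int(1, aln$L)
  } else {
    stopifnot(inherits(weights, "replicate_weights"))
    sites <- weights$indices
    w <- as.numeric(weights$counts)
  }
  cols <- aln_columns(aln, sites)
  inf <- informative_bytes(aln$alphabet)
  valid <- matrix(cols %in% inf, nrow = n)
  if (aln$alphabet == "dna") cols[cols == charToRaw("U")] <- charToRaw("T")
  D <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  saturated <- FALSE
  pmax_ <- if (aln$alphabet == "dna") 3 / 4 else 19 / 20
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      wtot <- sum(w[ok])
      if (wtot == 0)
        stop("taxa '", aln$labels[i], "' and '", aln$labels[j],
             "' share no comparable sites in this replicate")
      p <- sum(w[ok & (cols[i, ] != cols[j, ])]) / wtot
      d <- if (distance == "p") p else {
        if (p >= pmax_) { saturated <- TRUE; cap }
        else jc_correct(p, pmax_)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (saturated)
    warning("one or more saturated pairs capped at distance ", cap,
            call. = FALSE)
  D
}

jc_correct <- function(p, pmax_) {
  # pmax_ = (k-1)/k for a k-state alphabet: -(pmax_) * log(1 - p / pmax_)
  -pmax_ * log(1 - p / pmax_)
}

#' Neighbor joining
#'
#' Standard Q-matrix neighbor joining (via [ape::nj()]); negative branch
#' length estimates, which NJ can produce on noisy matrices, are clamped to
#' zero.  On additive matrices NJ recovers the generating topology and branch
#' lengths exactly.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param labels optional taxon labels (defaults to `rownames(D)`).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop("distance matrix contains non-finite entries")
  if (nrow(D) < 4L) stop("neighbor joining needs >= 4 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Infer one replicate tree
#'
#' Built-in path: [weighted_distance_matrix()] then [neighbor_joining()],
#' consuming the weight vector directly.  External path: the replicate is
#' materialised, written to FASTA, the command template is run, and the
#' resulting Newick parsed.  A failed external run (non-zero exit or
#' unparseable output) returns `NULL` so the caller can track the failure
#' rate.
#'
#' @param aln a [superalignment()].
#' @param weights a `replicate_weights` object or `NULL` (uniform).
#' @param cfg an [engine_config()].
#' @param seed integer substituted for `{seed}` in external templates.
#' @return A `phylo` tree on the alignment's taxa, or `NULL` on external
#'   failure.
#' @export
infer_tree <- function(aln, weights = NULL, cfg = engine_config(),
                       seed = 0L) {
  stopifnot(inherits(cfg, "engine_config"))
  if (cfg$engine == "builtin_nj") {
    D <- weighted_distance_matrix(aln, weights, cfg$distance,
                                  cap = cfg$saturation_cap)
    return(neighbor_joining(D))
  }
  rep_aln <- if (is.null(weights)) aln else materialize(aln, weights)
  fa <- tempfile(fileext = ".fasta"); out <- tempfile(fileext = ".nwk")
  on.exit(unlink(c(fa, out)))
  write_alignment(rep_aln, fa, "fasta")
  cmd <- cfg$external_cmd_template
  cmd <- gsub("{aln}", fa, cmd, fixed = TRUE)
  cmd <- gsub("{out}", out, cmd, fixed = TRUE)
  cmd <- gsub("{seed}", as.character(seed), cmd, fixed = TRUE)
  # group the command so silencing our side never clobbers a redirection
  # inside the template itself
  status <- suppressWarnings(system(sprintf("{ %s ; } > /dev/null 2>&1", cmd)))
  if (status != 0L || !file.exists(out)) return(NULL)
  tr <- tryCatch(parse_newick(paste(readLines(out, warn = FALSE),
                                    collapse = "")),
                 error = function(e) NULL)
  if (!is.null(tr) && !setequal(tr$tip.label, aln$labels)) return(NULL)
  tr
}

#' Parse and write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] adding strict
#' validation: unbalanced parentheses are reported with a character offset,
#' duplicate leaf labels are an error, and trees with fewer than 3 tips are
#' rejected.  Internal node labels (the support dialect) survive a round
#' trip; branch lengths are written with 10 significant digits.
#'
#' @param text Newick string (a file path is also accepted if the file
#'   exists).
#' @return `parse_newick`: a `phylo` object.
#' @export
parse_newick <- function(text) {
  if (length(text) == 1L && !grepl("(", text, fixed = TRUE) &&
      file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at character offset ", i)
    }
  }
  if (depth > 0L)
    stop("unbalanced '(': ", depth, " unclosed at character offset ",
         length(chars))
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("unparseable Newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param support_annotation optional named vector written as internal node
#'   labels (names are bipartition keys as from [bipartitions()]).
#' @return `write_newick`: the Newick string (invisibly if written to file).
#' @export
write_newick <- function(tree, file = NULL, support_annotation = NULL) {
  if (!is.null(support_annotation))
    tree <- annotate_supports(tree, support_annotation)
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
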