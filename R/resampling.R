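#' Default little-bootstrap subsample size
#'
#' The number of sites drawn (without replacement) into each subsample is
#' `floor(L^g)` with `g = 0.7` by default, clamped to `[4, L - 1]`.  For the
#' 1,207,638-site rodent-scale example this gives 18,086 sites, i.e. about
#' 1.5 percent of the superalignment.  The exponent is exposed because the
#' optimal subsample-size protocol is dataset dependent; any `0 < g < 1`
#' retains the little-bootstraps guarantees (subsample size grows sublinearly
#' while upsampled replicates stay full length).
#'
#' A small epsilon guard is applied before flooring so that powers that are
#' exact integers in real arithmetic (for example `1024^0.7 = 128`) are not
#' truncated by floating-point error.
#'
#' @param L superalignment length in sites (`>= 16`).
#' @param g subsampling exponent in `(0, 1)`.
#' @return Integer subsample size `l`.
#' @examples
#' subsample_size(1207638)   # 18086
#' subsample_size(1024)      # 128
#' @export
subsample_size <- function(L, g = 0.7) {
  stopifnot(length(L) == 1L, length(g) == 1L, g > 0, g < 1)
  if (L < 16) stop("L = ", L, " is too short for site subsampling (need >= 16)")
  l <- floor(exp(g * log(L)) + 1e-9)
  as.integer(min(max(l, 4), L - 1))
}

#' Draw a site subsample
#'
#' Selects `l` distinct site indices uniformly at random from `1:L`
#' (without replacement), the first step of a little-bootstrap analysis.
#'
#' @param L superalignment length, or a [superalignment()].
#' @param l subsample size, `0 < l < L`.
#' @return An object of class `site_subsample`: `indices` (sorted), `l`,
#'   `parent_L`.
#' @export
draw_subsample <- function(L, l) {
  if (inherits(L, "superalignment")) L <- L$L
  L <- as.integer(L); l <- as.integer(l)
  if (l <= 0L || l >= L)
    stop("subsample size l = ", l, " must satisfy 0 < l < L = ", L)
  idx <- sort.int(sample.int(L, l, replace = FALSE))
  structure(list(indices = idx, l = l, parent_L = L),
            class = "site_subsample")
}

#' Upsample a subsample into a full-length bootstrap replicate
#'
#' Draws `parent_L` sites with replacement from the subsample, so the
#' replicate has the length of the entire superalignment and is expected to
#' contain `L / l` copies of each subsampled site.  The replicate is returned
#' as a weight vector (site index, multiplicity), never materialised.
#'
#' @param sub a [draw_subsample()] result.
#' @return An object of class `replicate_weights`: `indices` (sorted site
#'   indices with positive count), `counts`, `total` (`== parent_L`),
#'   `parent_L`.
#' @export
upsample_replicate <- function(sub) {
  stopifnot(inherits(sub, "site_subsample"))
  tab <- tabulate(sample.int(sub$l, sub$parent_L, replace = TRUE), sub$l)
  keep <- tab > 0L
  structure(list(indices = sub$indices[keep], counts = tab[keep],
                 total = sub$parent_L, parent_L = sub$parent_L),
            class = "replicate_weights")
}

#' Standard (Felsenstein) bootstrap replicate
#'
#' `L` draws with replacement from all `L` sites; such replicates contain on
#' average a fraction `1 - (1 - 1/L)^L` (about 63 percent for large `L`) of
#' the distinct sites.
#'
#' @param L number of sites.
#' @return A `replicate_weights` object with `total = L`.
#' @export
standard_bootstrap <- function(L) {
  L <- as.integer(L); stopifnot(L >= 1L)
  tab <- tabulate(sample.int(L, L, replace = TRUE), L)
  keep <- tab > 0L
  structure(list(indices = which(keep), counts = tab[keep],
                 total = L, parent_L = L),
            class = "replicate_weights")
}

#' Double bootstrap replicate
#'
#' A standard bootstrap replicate (outer loop) is itself resampled with
#' replacement (inner loop).  The support of the result is a subset of the
#' outer replicate's support; the measured distinct-site fraction is close to
#' `1 - exp(-(1 - 1/e))` (about 47 percent) for large `L`.
#'
#' @param L number of sites.
#' @return A `replicate_weights` object with `total = L`; attribute
#'   `outer_indices` records the outer replicate's support.
#' @export
double_bootstrap <- function(L) {
  L <- as.integer(L); stopifnot(L >= 1L)
  outer <- sample.int(L, L, replace = TRUE)
  inner <- outer[sample.int(L, L, replace = TRUE)]
  tab <- tabulate(inner, L)
  keep <- tab > 0L
  out <- structure(list(indices = which(keep), counts = tab[keep],
                        total = L, parent_L = L),
                   class = "replicate_weights")
  attr(out, "outer_indices") <- sort.int(unique(outer))
  out
}

#' Fraction of distinct sites in a replicate
#'
#' @param rw a `replicate_weights` object.
#' @param L reference length (defaults to the replicate's parent length).
#' @return `|support| / L`.
#' @export
distinct_fraction <- function(rw, L = rw$parent_L) {
  stopifnot(inherits(rw, "replicate_weights"))
  length(rw$indices) / L
}

#' Materialise a weighted replicate as an explicit alignment
#'
#' Expands a weight vector into a full replicate alignment (columns in
#' ascending site order, repeats adjacent), as needed by external engines.
#' The built-in engine consumes weights directly and never materialises.
#'
#' @param aln a [superalignment()].
#' @param rw a `replicate_weights` object over `aln`'s sites.
#' @param max_cells refuse to materialise more than this many residues
#'   (default `2e8`); weight-aware engines avoid the expansion entirely.
#' @return A [superalignment()] with `rw$total` sites.
#' @export
materialize <- function(aln, rw, max_cells = 2e8) {
  stopifnot(inherits(aln, "superalignment"), inherits(rw, "replicate_weights"))
  if (max(rw$indices) > aln$L) stop("replicate indices exceed alignment length")
  cells <- as.numeric(rw$total) * length(aln$labels)
  if (cells > max_cells)
    stop("materialising ", rw$total, " sites x ", length(aln$labels),
         " taxa exceeds max_cells = ", max_cells,
         "; use a weight-aware engine instead")
  cols <- rep.int(rw$indices, rw$counts)
  seqs <- vapply(aln$seqs, function(r) rawToChar(r[cols]), character(1))
  superalignment(seqs, alphabet = aln$alphabet)
}
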