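#' Dip statistic for unimodality
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and any unimodal CDF (nondecreasing, convex up to a mode,
#' concave after it, with an atom allowed at the mode).  It is 0 for
#' perfectly unimodal-compatible samples, at most 0.25 (attained by an equal
#' two-point mass), and at most `1/(2n)` for a strictly uniform grid.  Large
#' values indicate multimodality.
#'
#' The minimisation is carried out exactly over unimodal CDFs whose mode lies
#' at an observed value or at the midpoint of a gap between adjacent observed
#' values (a finite candidate grid; see the methods vignette), by bisection
#' on the band half-width with convex-minorant feasibility checks.
#'
#' @param x numeric sample; `n < 3` returns 0 by convention.
#' @return The dip statistic in `[0, 0.25]`.
#' @examples
#' dip_statistic(c(rep(0, 10), rep(100, 10)))  # 0.25
#' @export
dip_statistic <- function(x) {
  if (!all(is.finite(x))) stop("sample contains non-finite values")
  n <- length(x)
  if (n < 3L) return(0)
  x <- sort(x)
  xv <- unique(x)
  if (length(xv) == 1L) return(0)
  a <- cumsum(tabulate(match(x, xv), length(xv))) / n
  dip_stat_cpp(xv, a)
}

#' Monte Carlo null table for the dip test
#'
#' Dips of `n_mc` uniform(0,1) samples of size `n` — the conventional
#' calibration reference.  Computing the table once per sample size and
#' reusing it across many tests (the same idea as diptest's precomputed
#' quantile tables) makes large calibration studies cheap.
#'
#' @param n sample size.
#' @param n_mc number of Monte Carlo replicates (default 2000).
#' @return Numeric vector of `n_mc` null dip values (attribute `n`).
#' @export
dip_null_table <- function(n, n_mc = 2000L) {
  stopifnot(n >= 3L, n_mc >= 1L)
  out <- dip_null_cpp(as.integer(n), as.integer(n_mc))
  attr(out, "n") <- as.integer(n)
  out
}

#' Monte Carlo dip test of unimodality
#'
#' Null hypothesis: the sample comes from a unimodal distribution.  The
#' p-value is the add-one-corrected proportion of uniform(0,1) null samples
#' of equal size whose dip reaches the observed dip:
#' `p = (b + 1) / (n_mc + 1)`.
#'
#' @param x numeric sample (`n >= 4`).
#' @param n_mc Monte Carlo replicates (default 2000).
#' @param null optional precomputed [dip_null_table()] for `length(x)`;
#'   drawn fresh (using the current RNG state) when `NULL`.
#' @return List with `statistic` (dip), `p.value`, `n_mc`.
#' @export
dip_test <- function(x, n_mc = 2000L, null = NULL) {
  n <- length(x)
  if (n < 4L) stop("dip test needs n >= 4")
  D <- dip_statistic(x)
  if (is.null(null)) null <- dip_null_table(n, n_mc)
  else {
    if (!is.null(attr(null, "n")) && attr(null, "n") != n)
      stop("null table was computed for n = ", attr(null, "n"),
           ", sample has n = ", n)
    n_mc <- length(null)
  }
  b <- sum(null >= D - 1e-12)
  list(statistic = D, p.value = (b + 1) / (n_mc + 1), n_mc = n_mc)
}

count_modes <- function(x, bw, grid_n = NULL) {
  # evaluation grid kept finer than the kernel (>= 4 points per bandwidth),
  # otherwise grid aliasing at small bandwidths splits or merges modes
  span <- diff(range(x)) + 6 * bw
  if (is.null(grid_n))
    grid_n <- min(16384L, max(512L, as.integer(ceiling(10 * span / bw))))
  d <- density(x, bw = bw, n = grid_n,
               from = min(x) - 3 * bw, to = max(x) + 3 * bw)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  # discard floating-point wiggles in density-underflow regions
  sum(y[peaks] > 1e-9 * max(y))
}

critical_bandwidth <- function(x, k, h_min = 0, tol = 1e-4) {
  # smallest bandwidth whose Gaussian KDE has at most k modes; mode count
  # is nonincreasing in bandwidth, so bisection applies.  h_min floors the
  # search: modes closer together than the data's resolution are artifacts.
  floor_h <- max(h_min, diff(range(x)) / 5000, tol / 100)
  hi <- max(sd(x), diff(range(x)) / 4, floor_h)
  while (count_modes(x, hi) > k) hi <- hi * 2
  if (count_modes(x, floor_h) <= k) return(floor_h)
  lo <- floor_h
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (count_modes(x, mid) <= k) hi <- mid else lo <- mid
    if (hi - lo < tol * hi) break
  }
  hi
}

#' Silverman critical-bandwidth mode-count test
#'
#' For `k = 1, 2, ...` the critical bandwidth `h_k` is the smallest Gaussian
#' kernel bandwidth whose density estimate has at most `k` modes.  The
#' hypothesis "at most k modes" is assessed by a smoothed bootstrap: samples
#' are drawn from the `h_k`-smoothed, variance-rescaled data and the
#' p-value is the proportion whose KDE at bandwidth `h_k` shows more than
#' `k` modes.  The reported mode count is the smallest `k` not rejected at
#' `alpha`.
#'
#' @param x numeric sample (`n >= 5`, not all equal).
#' @param k_max largest mode count examined (default 4; `k_max` is returned
#'   if every smaller `k` is rejected).
#' @param n_boot bootstrap replicates per `k` (default 500).
#' @param alpha significance level (default 0.05).
#' @param h_min lower bound on the bandwidths examined.  For data living on
#'   a known grid (bcl values at `100/R` resolution) set it to half the
#'   grid spacing: peaks separated by less than the resolution of the
#'   measurement are artifacts, not modes.
#' @return Smallest non-rejected mode count (attribute `p_values`).
#' @export
silverman_modes <- function(x, k_max = 4L, n_boot = 500L, alpha = 0.05,
                            h_min = 0) {
  n <- length(x)
  if (n < 5L) stop("Silverman test needs n >= 5")
  if (length(unique(x)) == 1L) {
    warning("degenerate sample (all values equal); reporting 1 mode")
    out <- 1L; attr(out, "p_values") <- NA_real_
    return(out)
  }
  xbar <- mean(x); s2 <- var(x)
  floor_h <- max(h_min, diff(range(x)) / 5000, 1e-6)
  pvals <- numeric(0)
  for (k in seq_len(k_max)) {
    if (count_modes(x, floor_h) <= k) {
      # at the finest meaningful bandwidth the data already show <= k
      # modes: no evidence of more at the measurement resolution
      pvals[k] <- 1
      out <- k
      attr(out, "p_values") <- pvals
      return(out)
    }
    h <- critical_bandwidth(x, k, h_min = h_min)
    shrink <- 1 / sqrt(1 + h^2 / s2)
    exceed <- 0L
    for (b in seq_len(n_boot)) {
      y <- xbar + (x[sample.int(n, n, replace = TRUE)] - xbar +
                     h * rnorm(n)) * shrink
      if (count_modes(y, h) > k) exceed <- exceed + 1L
    }
    pvals[k] <- exceed / n_boot
    if (pvals[k] >= alpha) {
      out <- k
      attr(out, "p_values") <- pvals
      return(out)
    }
  }
  out <- as.integer(k_max)
  attr(out, "p_values") <- pvals
  out
}

#' Classify a bcl distribution as unimodal or multimodal
#'
#' A bimodal bcl distribution — for example one mode at 100 and one at 0 —
#' is the signature of a clade whose support is contested across the genome
#' (incomplete lineage sorting, problematic loci, or other heterogeneity).
#' The dip test is applied first; only if it rejects unimodality at `alpha`
#' is the Silverman mode count consulted, and the verdict is `multimodal`
#' when the dip rejects and at least two modes are found.
#'
#' bcl values are rescaled to `[0, 1]` and, because they lie on a `100/R`
#' grid, tied values are jittered by uniform noise of amplitude
#' `(100/R)/20` (far below the grid spacing) under a fixed seed before the
#' dip test, avoiding ECDF degeneracy on heavily tied samples.
#'
#' @param x numeric vector of bcl values (percent) of length `S`.
#' @param R replicates per subsample (sets the grid for jittering).
#' @param alpha significance level (default 0.05).
#' @param n_mc dip Monte Carlo replicates.
#' @param null optional precomputed [dip_null_table()] of size `S`.
#' @param seed seed for the jitter and (if needed) the Monte Carlo draw.
#' @return List with `verdict` (`"unimodal"`, `"multimodal"`, or
#'   `"untested"` when `S < 4`), `dip_D`, `dip_p`, `n_modes`, `alpha`.
#' @export
classify_modality <- function(x, R = 20L, alpha = 0.05, n_mc = 2000L,
                              null = NULL, seed = 1L) {
  S <- length(x)
  if (S < 4L)
    return(list(verdict = "untested", dip_D = NA_real_, dip_p = NA_real_,
                n_modes = NA_integer_, alpha = alpha))
  if (length(unique(x)) == 1L)  # degenerate: unimodal by definition
    return(list(verdict = "unimodal", dip_D = 0, dip_p = 1,
                n_modes = 1L, alpha = alpha))
  z <- x / 100
  step <- (1 / R) / 20
  res <- with_seed(seed, {
    zj <- z + runif(S, -step, step)
    dip_test(zj, n_mc = n_mc, null = null)
  })
  n_modes <- NA_integer_
  verdict <- "unimodal"
  if (res$p.value < alpha) {
    # bandwidth floored at half the bcl grid spacing (on the [0,1] scale):
    # peaks closer than the 100/R support resolution are not real modes
    n_modes <- with_seed(derive_seed(seed, 7L),
                         as.integer(silverman_modes(z, alpha = alpha,
                                                    h_min = (1 / R) / 2)))
    if (n_modes >= 2L) verdict <- "multimodal"
  }
  list(verdict = verdict, dip_D = res$statistic, dip_p = res$p.value,
       n_modes = n_modes, alpha = alpha)
}

#' Wilcoxon tests for support comparisons
#'
#' Utilities used when evaluating support metrics: the signed-rank test for
#' paired differences (for example OC of matched clades under two settings)
#' and the rank-sum test for unpaired groups (for example OC of correct
#' versus incorrect clades).  Both are two-sided and delegate to
#' [stats::wilcox.test()]: exact null enumeration for small samples without
#' ties, normal approximation with continuity and tie correction otherwise.
#'
#' @param diffs numeric vector of paired differences; zeros are dropped
#'   first (at least 5 non-zero values required).
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  nz <- diffs[diffs != 0]
  if (length(nz) == 0L) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  if (length(nz) < 5L) stop("need at least 5 non-zero differences")
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  stats::wilcox.test(nz, exact = exact, correct = TRUE)$p.value
}

#' @rdname wilcoxon_signed_rank
#' @param x,y numeric vectors for the unpaired comparison.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  exact <- length(x) <= 25L && length(y) <= 25L &&
    !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}
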