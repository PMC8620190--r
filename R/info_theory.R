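#' Equal-width discretization
#'
#' Splits the value range of `x` into `|B| = floor(sqrt(n))` equal-width
#' bins and assigns each sample the label
#' `ceil((v - v_min) * |B| / denom)`, where `denom = v_max` when
#' `v_min >= 0` and `denom = v_max - v_min` when `v_min < 0`. The minimum
#' value therefore always maps to label 0, so up to `|B| + 1` labels can be
#' occupied; labels only ever enter the entropy estimators through equality,
#' so they are used as-is. With `range_denominator = TRUE` the denominator is
#' the full range `v_max - v_min` regardless of sign, which makes the bins
#' genuinely equal-width also for non-negative data.
#'
#' @param x numeric vector, length >= 4 (so that at least 2 bins exist) and
#'   not constant.
#' @param range_denominator use `v_max - v_min` as the denominator even when
#'   all values are non-negative.
#' @return An object of class `discretized`: list with integer `bins` (one
#'   label in `0..bin_count` per sample), `bin_count`, `v_min`, `v_max`.
#' @export
equal_width_discretize <- function(x, range_denominator = FALSE) {
  n <- length(x)
  if (n < 4) stop("need at least 4 samples to discretize (got ", n, ")")
  if (anyNA(x)) stop("missing values are not supported in discretization")
  v_min <- min(x)
  v_max <- max(x)
  if (v_min == v_max) stop("constant vector cannot be discretized")
  nb <- as.integer(floor(sqrt(n)))
  denom <- if (v_min < 0 || range_denominator) v_max - v_min else v_max
  bins <- as.integer(ceiling((x - v_min) * nb / denom))
  # the maximum maps to label |B| exactly; guard against floating-point
  # overshoot in the product above
  bins[bins > nb] <- nb
  structure(list(bins = bins, bin_count = as.integer(nb),
                 v_min = v_min, v_max = v_max),
            class = "discretized")
}

#' Plug-in entropy of a contingency table
#'
#' Shannon entropy, in nats, of the empirical distribution `counts / total`.
#' Works for marginal (1-d), joint (2-d) and triple-joint (3-d) count arrays;
#' cells with zero count contribute nothing (`0 log 0 := 0`).
#'
#' @param counts non-negative integer vector/array with a positive total.
#' @return entropy in nats.
#' @export
entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative count in contingency table")
  total <- sum(counts)
  if (total <= 0) stop("contingency table is empty")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

## Joint contingency counts of up to three label vectors (labels 0-based).
joint_counts <- function(...) {
  vs <- list(...)
  n <- length(vs[[1L]])
  nl <- vapply(vs, function(v) max(v) + 1L, integer(1))
  idx <- vs[[1L]]
  mult <- nl[1L]
  if (length(vs) > 1) for (k in 2:length(vs)) {
    idx <- idx + vs[[k]] * mult
    mult <- mult * nl[k]
  }
  tabulate(idx + 1L, nbins = mult)
}

bins_of <- function(x) {
  if (inherits(x, "discretized")) x$bins else as.integer(x)
}

#' Mutual information of two discretized vectors
#'
#' Plug-in estimate `MI = S(v) + S(w) - S(v, w)` in nats, from the empirical
#' joint distribution of the bin labels. Tiny negative values from floating
#' point are clamped to 0 (the plug-in estimate is analytically
#' non-negative).
#'
#' @param vd,wd [equal_width_discretize()] results (or plain 0-based integer
#'   label vectors) of equal length.
#' @return MI in nats, `>= 0`.
#' @export
mutual_information <- function(vd, wd) {
  v <- bins_of(vd); w <- bins_of(wd)
  if (length(v) != length(w))
    stop("mutual_information: vectors differ in length")
  mi <- entropy(joint_counts(v)) + entropy(joint_counts(w)) -
    entropy(joint_counts(v, w))
  clamp0(mi)
}

#' Conditional mutual information given a third vector
#'
#' Plug-in estimate `CMI = S(v, f) + S(w, f) - S(v, w, f) - S(f)` in nats:
#' the expected mutual information of `v` and `w` within each level of `f`.
#' Clamped to `>= 0` against floating-point noise.
#'
#' @param vd,wd,fd [equal_width_discretize()] results (or 0-based integer
#'   label vectors) of equal length.
#' @return CMI in nats, `>= 0`.
#' @export
conditional_mutual_information <- function(vd, wd, fd) {
  v <- bins_of(vd); w <- bins_of(wd); f <- bins_of(fd)
  n <- length(v)
  if (length(w) != n || length(f) != n)
    stop("conditional_mutual_information: vectors differ in length")
  cmi <- entropy(joint_counts(v, f)) + entropy(joint_counts(w, f)) -
    entropy(joint_counts(v, w, f)) - entropy(joint_counts(f))
  clamp0(cmi)
}

clamp0 <- function(x, tol = 1e-12) {
  if (x < 0 && x > -tol) 0 else max(x, 0)
}

#' Interaction information of a triplet
#'
#' Discretizes the three raw series with [equal_width_discretize()] and
#' returns `II = CMI(v; w | f) - MI(v; w)` along with both components. A
#' negative II indicates an indirect dependency somewhere in the triplet
#' (typically the microbial edge when `f` is the shared environmental
#' driver); a positive II indicates that environmental preference and
#' genuine dependence are entangled.
#'
#' @param v,w raw abundance vectors; `f` raw environmental-factor vector.
#'   Equal lengths, each discretizable.
#' @param range_denominator passed to [equal_width_discretize()].
#' @return list with `ii`, `mi`, `cmi` (all in nats).
#' @export
interaction_information <- function(v, w, f, range_denominator = FALSE) {
  vd <- equal_width_discretize(v, range_denominator)
  wd <- equal_width_discretize(w, range_denominator)
  fd <- equal_width_discretize(f, range_denominator)
  mi <- mutual_information(vd, wd)
  cmi <- conditional_mutual_information(vd, wd, fd)
  list(ii = cmi - mi, mi = mi, cmi = cmi)
}

#' Permutation significance of the interaction information
#'
#' Because `MI(v; w)` does not involve the environmental factor, the
#' significance of `II = CMI - MI` equals the significance of the CMI. The
#' factor series is permuted uniformly at random `iterations` times, the CMI
#' recomputed each time, and `c` counts how many permuted CMI values are at
#' least as small as (i.e. `<=`) the original. The p-value is
#' `(c + 1) / (iterations + 1)`.
#'
#' Uses R's RNG: seed with [set.seed()] for reproducibility.
#'
#' @param v,w,f raw series as in [interaction_information()].
#' @param iterations number of permutations (>= 1; default 1000).
#' @param range_denominator passed to [equal_width_discretize()].
#' @return p-value in `[1/(iterations+1), 1]`.
#' @export
ii_significance <- function(v, w, f, iterations = 1000,
                            range_denominator = FALSE) {
  if (iterations < 1) stop("iterations must be >= 1")
  vd <- equal_width_discretize(v, range_denominator)
  wd <- equal_width_discretize(w, range_denominator)
  fd <- equal_width_discretize(f, range_denominator)
  cmi_perm_pvalue(vd$bins, wd$bins, fd$bins, as.integer(iterations))
}

## Thin wrapper so edge_methods can reuse already-discretized labels.
cmi_perm_pvalue <- function(vb, wb, fb, iterations) {
  c_le <- cmi_perm_count_cpp(as.integer(vb), as.integer(wb), as.integer(fb),
                             as.integer(iterations))
  (c_le + 1) / (iterations + 1)
}
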