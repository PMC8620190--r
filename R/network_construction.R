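#' Parameters for association-network construction
#'
#' @param permutations permutations for the score p-value (default 2000;
#'   the attainable p-value floor is `1/(permutations + 1)`).
#' @param p_threshold keep edges with `p <= p_threshold` (default 0.001).
#' @param q_threshold keep edges with Bonferroni `q <= q_threshold`
#'   (default 0.001). Note that with a pure permutation p-value the floor is
#'   `1/(permutations + 1)`, so a Bonferroni-corrected 0.001 over many tests
#'   can be unattainable; set `q_threshold = 1` to disable the corrected
#'   filter (see [run_benchmark()]).
#' @return list of class `assoc_params`.
#' @export
assoc_params <- function(permutations = 2000, p_threshold = 0.001,
                         q_threshold = 0.001) {
  stopifnot(permutations >= 1,
            p_threshold > 0, p_threshold <= 1,
            q_threshold > 0, q_threshold <= 1)
  structure(list(permutations = as.integer(permutations),
                 p_threshold = p_threshold, q_threshold = q_threshold),
            class = "assoc_params")
}

#' Robust standardization by median and MAD
#'
#' `(x - median(x)) / MAD(x)` with the unscaled median absolute deviation
#' (no 1.4826 normal-consistency factor).
#'
#' @param x numeric vector with positive MAD.
#' @return standardized vector.
#' @export
robust_z <- function(x) {
  med <- median(x)
  mad0 <- median(abs(x - med))
  if (mad0 == 0) stop("degenerate series: median absolute deviation is 0")
  (x - med) / mad0
}

#' Zero-delay local similarity of two standardized series
#'
#' Over all contiguous index windows `[i, j]`, maximizes
#' `|sum_t x_t y_t| / n`; the score is that maximum, the sign is the sign of
#' the maximizing sum, and the window gives the association start (0-based)
#' and duration. Ties are broken by earliest start, then longest duration,
#' then positive sign. This is a deliberately simplified contemporary
#' (no time-delay) association scorer.
#'
#' @param x,y numeric vectors of equal length (typically [robust_z()]
#'   output).
#' @return list with `score`, `sign` (`"+"`/`"-"`), `start`, `duration`.
#' @export
local_similarity <- function(x, y) {
  if (length(x) != length(y))
    stop("local_similarity: series differ in length")
  local_similarity_cpp(as.numeric(x), as.numeric(y))
}

#' Permutation p-value for a local-similarity score
#'
#' Permutes `y` uniformly at random `permutations` times, recomputes the
#' local-similarity score, and returns
#' `(#\{score_perm >= score_obs\} + 1) / (permutations + 1)`.
#'
#' Uses R's RNG; seed with [set.seed()].
#'
#' @inheritParams local_similarity
#' @param permutations number of permutations.
#' @return p-value in `[1/(permutations+1), 1]`.
#' @export
assoc_permutation_p <- function(x, y, permutations = 2000) {
  if (length(x) != length(y))
    stop("assoc_permutation_p: series differ in length")
  cnt <- ls_perm_count_cpp(as.numeric(x), as.numeric(y),
                           as.integer(permutations))
  (cnt + 1) / (permutations + 1)
}

#' Bonferroni correction
#'
#' `q_i = min(1, m * p_i)` over the `m` tests, via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "bonferroni")
}

#' Construct an association network from time series
#'
#' Scores every taxon-taxon and taxon-factor pair (factor-factor pairs are
#' never tested) with [local_similarity()] on [robust_z()]-standardized
#' series, assigns permutation p-values and Bonferroni q-values over all
#' tested pairs, and keeps pairs with `p <= p_threshold` and
#' `q <= q_threshold`. The kept edge carries the signed score and the
#' maximizing window as its association start/duration. Series with zero
#' MAD are dropped with a warning.
#'
#' @param abund taxa x samples abundance matrix.
#' @param env factors x samples environment matrix on the same sample axis.
#' @param params an [assoc_params()].
#' @param seed optional integer seed for the permutation tests.
#' @return an [assoc_network()] over the taxa and factors.
#' @export
construct_network <- function(abund, env, params = assoc_params(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(env) && ncol(env) != ncol(abund))
    stop("abundance and environment matrices differ in sample count")
  n <- ncol(abund)
  series <- list()
  kinds <- character()
  for (id in rownames(abund)) {
    z <- tryCatch(robust_z(abund[id, ]), error = function(e) NULL)
    if (is.null(z)) {
      warning("dropping degenerate abundance series '", id, "'")
    } else {
      series[[id]] <- z
      kinds[id] <- "taxon"
    }
  }
  for (id in rownames(env)) {
    z <- tryCatch(robust_z(env[id, ]), error = function(e) NULL)
    if (is.null(z)) {
      warning("dropping degenerate environment series '", id, "'")
    } else {
      series[[id]] <- z
      kinds[id] <- "env"
    }
  }
  ids <- names(series)
  pairs <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  # never test factor-factor pairs
  keep <- !(kinds[ids[pairs[, 1L]]] == "env" &
            kinds[ids[pairs[, 2L]]] == "env")
  pairs <- pairs[keep, , drop = FALSE]
  m <- nrow(pairs)
  rows <- vector("list", m)
  pvals <- numeric(m)
  # a pair stays significant only while its exceedance count c satisfies
  # (c+1)/(perm+1) <= p_threshold; once c passes that cap the exact count no
  # longer matters (the pair is dropped and Bonferroni q depends only on the
  # pair's own p), so counting may stop early
  c_cap <- floor(params$p_threshold * (params$permutations + 1) - 1)
  for (k in seq_len(m)) {
    a <- ids[pairs[k, 1L]]; b <- ids[pairs[k, 2L]]
    ls <- local_similarity(series[[a]], series[[b]])
    cnt <- ls_perm_count_cpp(series[[a]], series[[b]],
                             params$permutations, as.integer(c_cap))
    pvals[k] <- (cnt + 1) / (params$permutations + 1)
    rows[[k]] <- data.frame(node1 = a, node2 = b,
                            score = if (ls$sign == "+") ls$score else -ls$score,
                            p = NA_real_, q = NA_real_,
                            start = ls$start, duration = ls$duration,
                            stringsAsFactors = FALSE)
  }
  nodes <- data.frame(id = ids, kind = unname(kinds[ids]),
                      stringsAsFactors = FALSE)
  if (m == 0) return(assoc_network(nodes, NULL, n_samples = n))
  edges <- do.call(rbind, rows)
  edges$p <- pvals
  edges$q <- bonferroni(pvals)
  sig <- edges$p <= params$p_threshold & edges$q <= params$q_threshold &
    edges$score != 0
  edges <- edges[sig, , drop = FALSE]
  assoc_network(nodes, if (nrow(edges)) edges else NULL, n_samples = n)
}
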