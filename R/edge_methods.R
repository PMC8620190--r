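#' Parameters for environmentally driven edge detection
#'
#' @param methods subset of `"SP"` (sign pattern), `"OL"` (overlap),
#'   `"II"` (interaction information), `"DPI"` (data processing inequality).
#' @param combination `"intersection"` (an edge is removed when some triplet
#'   is flagged by all selected methods), `"union"` (removed when any method
#'   flags any triplet) or `"single"` (exactly one method selected; removed
#'   when it flags at least one triplet).
#' @param ol_threshold overlap percentage above which (strictly) the overlap
#'   method flags; default 60.
#' @param ii_alpha significance level for the interaction-information
#'   permutation test; default 0.05.
#' @param ii_iterations permutations for the significance test; default 1000.
#' @param agree_across_triplets alternative intersection semantics: each
#'   method flags the *edge* when it flags any of its triplets, and the edge
#'   is removed when every selected method flags it (possibly in different
#'   triplets). Default `FALSE`: all methods must agree within the same
#'   triplet.
#' @param ii_ignore_significance flag on a negative interaction information
#'   alone, without requiring the permutation p-value to pass `ii_alpha`.
#' @param range_denominator passed to [equal_width_discretize()].
#' @return list of class `ended_params`.
#' @export
ended_params <- function(methods = c("SP", "OL", "II", "DPI"),
                         combination = c("intersection", "union", "single"),
                         ol_threshold = 60,
                         ii_alpha = 0.05,
                         ii_iterations = 1000,
                         agree_across_triplets = FALSE,
                         ii_ignore_significance = FALSE,
                         range_denominator = FALSE) {
  combination <- match.arg(combination)
  methods <- match.arg(methods, c("SP", "OL", "II", "DPI"),
                       several.ok = TRUE)
  if (!length(methods)) stop("at least one method must be selected")
  if (combination == "single" && length(methods) != 1)
    stop("combination 'single' needs exactly one method")
  if (ol_threshold <= 0 || ol_threshold > 100)
    stop("ol_threshold must lie in (0, 100]")
  if (ii_alpha <= 0 || ii_alpha >= 1) stop("ii_alpha must lie in (0, 1)")
  structure(list(methods = methods, combination = combination,
                 ol_threshold = ol_threshold, ii_alpha = ii_alpha,
                 ii_iterations = as.integer(ii_iterations),
                 agree_across_triplets = isTRUE(agree_across_triplets),
                 ii_ignore_significance = isTRUE(ii_ignore_significance),
                 range_denominator = isTRUE(range_denominator)),
            class = "ended_params")
}

#' Sign-pattern classifier
#'
#' A triplet's microbial edge is classified as environmentally driven when
#' the product of the three association signs is positive, i.e. when the
#' number of negative signs is even. Four of the eight sign combinations are
#' flagged.
#'
#' @param s_vw,s_vf,s_wf association signs, `"+"` or `"-"`.
#' @return `TRUE` when the edge is flagged as environmentally driven.
#' @export
sign_pattern <- function(s_vw, s_vf, s_wf) {
  signs <- c(s_vw, s_vf, s_wf)
  if (!all(signs %in% c("+", "-"))) stop("signs must be '+' or '-'")
  sum(signs == "-") %% 2L == 0L
}

#' Time-window overlap of a triplet
#'
#' Percentage of the microbial association window `[b_vw, e_vw)` covered by
#' the intersection of all three association windows, where `e = b + d`:
#' `O = 100 * (min(e_vw, e_vf, e_wf) - max(b_vw, b_vf, b_wf)) / (e_vw - b_vw)`.
#' Negative when the windows are disjoint; no clipping is applied. The
#' overlap method flags a triplet when `O` strictly exceeds the threshold
#' (default 60).
#'
#' @param edge_vw,edge_vf,edge_wf edges (lists or one-row data.frames) with
#'   elements `start` and `duration`.
#' @return overlap percentage (can exceed 100 or be negative).
#' @export
overlap_percent <- function(edge_vw, edge_vf, edge_wf) {
  b <- c(edge_vw$start, edge_vf$start, edge_wf$start)
  e <- b + c(edge_vw$duration, edge_vf$duration, edge_wf$duration)
  if (e[1L] == b[1L]) stop("microbial association window has zero length")
  100 * (min(e) - max(b)) / (e[1L] - b[1L])
}

#' Data-processing-inequality classifier
#'
#' In a chain v -- f -- w the mutual information between the endpoints cannot
#' exceed the smaller of the two direct-link MIs; the edge with the smallest
#' MI in the triplet is the indirect candidate. Flags when
#' `MI(v; w) <= min(MI(v; f), MI(w; f))` (a tie counts as smallest).
#'
#' @param mi_vw,mi_vf,mi_wf mutual information values in nats, `>= 0`.
#' @return `TRUE` when the microbial edge is flagged.
#' @export
dpi_flag <- function(mi_vw, mi_vf, mi_wf) {
  if (any(c(mi_vw, mi_vf, mi_wf) < 0)) stop("MI values must be >= 0")
  mi_vw <= min(mi_vf, mi_wf)
}

## MI between two cached discretizations, memoized per unordered id pair.
pair_mi <- function(cache, a, b) {
  key <- edge_key(a, b)
  hit <- cache$mi[[key]]
  if (!is.null(hit)) return(hit)
  val <- mutual_information(cache$disc[[a]], cache$disc[[b]])
  cache$mi[[key]] <- val
  val
}

#' Evaluate one environmental triplet
#'
#' Computes, for the requested methods only, the sign-pattern flag from the
#' three edge signs, the overlap percentage from the three edge windows, the
#' interaction information with its permutation p-value from the raw series,
#' and the DPI flag from the three pairwise MIs of the discretized series.
#' Methods not requested are `NA`.
#'
#' @param triplet one row of [find_environmental_triplets()] (or a list with
#'   `v`, `w`, `f`).
#' @param network the [assoc_network()] holding the three edges.
#' @param abund abundance matrix (taxa x samples) containing rows `v`, `w`.
#' @param env environment matrix (factors x samples) containing row `f`.
#' @param params an [ended_params()].
#' @return one-row data.frame of per-method flags and the quantities behind
#'   them (`overlap_O`, `ii_value`, `ii_p`, `mi_vw`, `mi_vf`, `mi_wf`).
#' @export
evaluate_triplet <- function(triplet, network, abund, env, params = ended_params()) {
  cache <- triplet_cache(network, abund, env, params)
  flags <- evaluate_triplet_cached(triplet$v, triplet$w, triplet$f,
                                   network, cache, params)
  cbind(data.frame(v = triplet$v, w = triplet$w, f = triplet$f,
                   stringsAsFactors = FALSE), flags)
}

## Shared per-network state: row lookup + memoized discretizations and MIs.
triplet_cache <- function(network, abund, env, params) {
  cache <- new.env(parent = emptyenv())
  cache$mi <- list()
  cache$disc <- list()
  cache$rows <- list()
  if (!is.null(abund))
    for (id in rownames(abund)) cache$rows[[id]] <- abund[id, ]
  if (!is.null(env))
    for (id in rownames(env)) cache$rows[[id]] <- env[id, ]
  cache$params <- params
  cache
}

disc_of <- function(cache, id) {
  hit <- cache$disc[[id]]
  if (!is.null(hit)) return(hit)
  row <- cache$rows[[id]]
  if (is.null(row)) stop("no abundance/environment row for node '", id, "'")
  d <- equal_width_discretize(row, cache$params$range_denominator)
  cache$disc[[id]] <- d
  d
}

evaluate_triplet_cached <- function(v, w, f, network, cache, params) {
  want <- params$methods
  i_vw <- edge_index(network, v, w)
  i_vf <- edge_index(network, v, f)
  i_wf <- edge_index(network, w, f)
  if (anyNA(c(i_vw, i_vf, i_wf)))
    stop("triplet {", v, ", ", w, ", ", f, "} has a missing edge")
  e <- network$edges
  sp <- ol <- ii <- dpi <- NA
  overlap_O <- ii_value <- ii_p <- mi_vw <- mi_vf <- mi_wf <- NA_real_
  if ("SP" %in% want)
    sp <- sign_pattern(e$sign[i_vw], e$sign[i_vf], e$sign[i_wf])
  if ("OL" %in% want) {
    overlap_O <- overlap_percent(e[i_vw, ], e[i_vf, ], e[i_wf, ])
    ol <- overlap_O > params$ol_threshold
  }
  if (any(c("II", "DPI") %in% want)) {
    vd <- disc_of(cache, v); wd <- disc_of(cache, w); fd <- disc_of(cache, f)
    if ("II" %in% want) {
      mi <- pair_mi(cache, v, w)
      cmi <- conditional_mutual_information(vd, wd, fd)
      ii_value <- cmi - mi
      ii_p <- cmi_perm_pvalue(vd$bins, wd$bins, fd$bins, params$ii_iterations)
      ii <- ii_value < 0 &&
        (params$ii_ignore_significance || ii_p <= params$ii_alpha)
    }
    if ("DPI" %in% want) {
      mi_vw <- pair_mi(cache, v, w)
      mi_vf <- pair_mi(cache, v, f)
      mi_wf <- pair_mi(cache, w, f)
      dpi <- dpi_flag(mi_vw, mi_vf, mi_wf)
    }
  }
  data.frame(sp = sp, ol = ol, ii = ii, dpi = dpi,
             overlap_O = overlap_O, ii_value = ii_value, ii_p = ii_p,
             mi_vw = mi_vw, mi_vf = mi_vf, mi_wf = mi_wf)
}

#' Per-triplet method flags for a whole network
#'
#' Evaluates every environmental triplet with the selected methods.
#' Discretizations and pairwise MIs are computed once per node/pair, and the
#' II permutation test runs once per triplet. Triplets are processed in the
#' deterministic order of [find_environmental_triplets()], so results are
#' reproducible under a fixed RNG seed.
#'
#' @inheritParams evaluate_triplet
#' @return data.frame: `v`, `w`, `f` plus the columns of
#'   [evaluate_triplet()].
#' @export
triplet_flags <- function(network, abund, env, params = ended_params()) {
  trips <- find_environmental_triplets(network)
  cache <- triplet_cache(network, abund, env, params)
  if (!nrow(trips)) {
    return(cbind(trips, data.frame(sp = logical(), ol = logical(),
                                   ii = logical(), dpi = logical(),
                                   overlap_O = numeric(), ii_value = numeric(),
                                   ii_p = numeric(), mi_vw = numeric(),
                                   mi_vf = numeric(), mi_wf = numeric())))
  }
  rows <- vector("list", nrow(trips))
  for (i in seq_len(nrow(trips))) {
    rows[[i]] <- evaluate_triplet_cached(trips$v[i], trips$w[i], trips$f[i],
                                         network, cache, params)
  }
  out <- cbind(trips, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

## Combine per-triplet flags into per-edge verdicts under the chosen
## combination rule. Returns the verdict table (one row per network edge).
combine_verdicts <- function(network, flags, params) {
  edges <- network$edges
  keys <- edge_key(edges$node1, edges$node2)
  n_tr <- sp_f <- ol_f <- ii_f <- dpi_f <- integer(length(keys))
  removed <- logical(length(keys))
  if (nrow(flags)) {
    fkey <- edge_key(flags$v, flags$w)
    idx <- match(fkey, keys)
    meth <- params$methods
    use <- function(col, m) if (m %in% meth) col else rep(NA, nrow(flags))
    sp <- use(flags$sp, "SP"); ol <- use(flags$ol, "OL")
    ii <- use(flags$ii, "II"); dpi <- use(flags$dpi, "DPI")
    sel <- rbind(if ("SP" %in% meth) sp, if ("OL" %in% meth) ol,
                 if ("II" %in% meth) ii, if ("DPI" %in% meth) dpi)
    all_agree <- apply(sel, 2L, all)   # per-triplet: all selected methods
    any_flag <- apply(sel, 2L, any)
    for (j in seq_along(fkey)) {
      i <- idx[j]
      n_tr[i] <- n_tr[i] + 1L
      if (isTRUE(sp[j])) sp_f[i] <- sp_f[i] + 1L
      if (isTRUE(ol[j])) ol_f[i] <- ol_f[i] + 1L
      if (isTRUE(ii[j])) ii_f[i] <- ii_f[i] + 1L
      if (isTRUE(dpi[j])) dpi_f[i] <- dpi_f[i] + 1L
    }
    rm_edge <- switch(params$combination,
      intersection = {
        if (params$agree_across_triplets) {
          # each method flags the edge if it flags >= 1 triplet; removal
          # needs every method to flag the edge (triplets may differ)
          per_method <- lapply(seq_len(nrow(sel)), function(r)
            tapply(sel[r, ], idx, any))
          agree <- Reduce(`&`, per_method)
          as.integer(names(agree))[which(agree)]
        } else {
          unique(idx[all_agree])
        }
      },
      union = unique(idx[any_flag]),
      single = unique(idx[any_flag]))
    removed[rm_edge] <- TRUE
  }
  data.frame(node1 = edges$node1, node2 = edges$node2,
             n_triplets = n_tr, sp_flags = sp_f, ol_flags = ol_f,
             ii_flags = ii_f, dpi_flags = dpi_f, removed = removed,
             stringsAsFactors = FALSE)
}

#' Detect and remove environmentally driven edges
#'
#' Runs the selected detection methods on every environmental triplet of the
#' network and combines the per-triplet flags into per-edge verdicts.
#' Under the default intersection combination, a triplet flags its microbial
#' edge only when *all* selected methods flag it within that same triplet,
#' and an edge is removed when at least one of its triplets flags it; an
#' edge in no triplet is always kept, and taxon-factor edges are never
#' removed.
#'
#' @inheritParams evaluate_triplet
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the II permutation test is reproducible.
#' @return list of class `ended_result`:
#'   \describe{
#'     \item{verdicts}{one row per edge: triplet count, per-method
#'       flagged-triplet counts, `removed`.}
#'     \item{flags}{the per-triplet [triplet_flags()] table.}
#'     \item{removed}{data.frame of removed edges (`node1`, `node2`).}
#'     \item{filtered}{the input network with removed edges dropped.}
#'     \item{params}{the parameters used.}
#'   }
#' @export
apply_ended <- function(network, abund = NULL, env = NULL,
                        params = ended_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  needs_data <- any(c("II", "DPI") %in% params$methods)
  if (needs_data && (is.null(abund) || is.null(env)))
    stop("methods II/DPI need abundance and environment matrices")
  flags <- triplet_flags(network, abund, env, params)
  verdicts <- combine_verdicts(network, flags, params)
  rm_idx <- which(verdicts$removed)
  keep <- setdiff(seq_len(nrow(network$edges)), rm_idx)
  filtered <- network
  filtered$edges <- network$edges[keep, , drop = FALSE]
  rownames(filtered$edges) <- NULL
  structure(list(verdicts = verdicts, flags = flags,
                 removed = verdicts[rm_idx, c("node1", "node2"), drop = FALSE],
                 filtered = filtered, params = params),
            class = "ended_result")
}

#' @export
print.ended_result <- function(x, ...) {
  cat("Environmentally driven edge detection (",
      paste(x$params$methods, collapse = "+"), ", ",
      x$params$combination, ")\n", sep = "")
  cat("Triplets evaluated:", nrow(x$flags), "\n")
  cat("Edges removed:", nrow(x$removed), "of", nrow(x$verdicts), "\n")
  invisible(x)
}
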