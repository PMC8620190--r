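#' Confusion counts for edge removal
#'
#' By convention, the "positive" class is the false association: a network
#' edge between taxa that is absent from the ground-truth interaction set.
#' A true positive is a false association correctly removed; a false
#' positive is a true interaction incorrectly removed; a false negative is a
#' false association kept; a true negative is a true interaction kept. Only
#' microbial (taxon-taxon) edges are counted.
#'
#' @param removed data.frame of removed edges (`node1`, `node2`), a subset
#'   of the network's microbial edges.
#' @param network the [assoc_network()] the removals came from.
#' @param truth data.frame of ground-truth interacting taxon pairs (`v`,
#'   `w`), e.g. `truth_edges` of [simulate_community()].
#' @return list of class `confusion` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(removed, network, truth) {
  kind <- setNames(network$nodes$kind, network$nodes$id)
  e <- network$edges
  micro <- e[kind[e$node1] == "taxon" & kind[e$node2] == "taxon", ,
             drop = FALSE]
  mkeys <- edge_key(micro$node1, micro$node2)
  rkeys <- if (nrow(removed)) edge_key(removed$node1, removed$node2)
           else character()
  if (!all(rkeys %in% mkeys))
    stop("removed edge not among the network's microbial edges")
  tkeys <- if (nrow(truth)) edge_key(truth[[1L]], truth[[2L]]) else character()
  is_true <- mkeys %in% tkeys
  is_removed <- mkeys %in% rkeys
  structure(list(TP = sum(is_removed & !is_true),
                 FP = sum(is_removed & is_true),
                 FN = sum(!is_removed & !is_true),
                 TN = sum(!is_removed & is_true)),
            class = "confusion")
}

#' Classification rates from confusion counts
#'
#' `TPR = TP/P` (sensitivity), `TNR = TN/N` (specificity),
#' `FPR = 1 - TNR`, `PPV = TP/(TP+FP)` (precision), and
#' `ACC = (TP+TN)/(P+N)`, with `P = TP + FN` (all false associations) and
#' `N = TN + FP` (all true interactions). Ratios with a zero denominator —
#' notably PPV when nothing was removed — are reported as `NA`.
#'
#' @param cc a [confusion()] result (or list with `TP`, `FP`, `TN`, `FN`).
#' @return list of class `rate_set` with `TPR`, `TNR`, `FPR`, `PPV`, `ACC`.
#' @export
rates <- function(cc) {
  P <- cc$TP + cc$FN
  N <- cc$TN + cc$FP
  div <- function(a, b) if (b > 0) a / b else NA_real_
  TNR <- div(cc$TN, N)
  structure(list(TPR = div(cc$TP, P),
                 TNR = TNR,
                 FPR = if (is.na(TNR)) NA_real_ else 1 - TNR,
                 PPV = div(cc$TP, cc$TP + cc$FP),
                 ACC = div(cc$TP + cc$TN, P + N)),
            class = "rate_set")
}

#' Multivariate hypergeometric probability of a random removal
#'
#' Probability of removing exactly `k_neg` negative and `k_pos` positive
#' edges when `n = k_neg + k_pos` edges are drawn uniformly without
#' replacement from a network with `N_neg` negative and `N_pos` positive
#' edges: `C(N_neg, k_neg) C(N_pos, k_pos) / C(N, n)`, computed in
#' log-space. Outside the support the probability is 0.
#'
#' @param N_neg,N_pos negative / positive edge counts (`N = N_neg + N_pos`).
#' @param k_neg,k_pos removed negative / positive counts
#'   (`n = k_neg + k_pos`).
#' @return probability in `[0, 1]`.
#' @export
hypergeom_pmf <- function(N_neg, N_pos, k_neg, k_pos) {
  if (k_neg < 0 || k_pos < 0 || k_neg > N_neg || k_pos > N_pos) return(0)
  exp(lchoose(N_neg, k_neg) + lchoose(N_pos, k_pos) -
      lchoose(N_neg + N_pos, k_neg + k_pos))
}

#' Expected removals under random draws
#'
#' Expected number of negative and positive edges among `n` edges removed
#' uniformly at random from `N = N_neg + N_pos`: `n * N_neg / N` and
#' `n * N_pos / N`, reported both rounded (as printed in summaries) and
#' unrounded (the unrounded pair sums to `n` exactly).
#'
#' @param N total edge count.
#' @param N_neg,N_pos negative and positive edge counts.
#' @param n number of removed edges.
#' @return list with `E_neg`, `E_pos` (rounded) and `e_neg`, `e_pos`
#'   (unrounded).
#' @export
expected_removals <- function(N, N_neg, N_pos, n) {
  if (N_neg + N_pos != N) stop("N_neg + N_pos must equal N")
  if (n > N) stop("cannot remove more edges than exist")
  e_neg <- n * N_neg / N
  e_pos <- n * N_pos / N
  list(E_neg = round(e_neg), E_pos = round(e_pos),
       e_neg = e_neg, e_pos = e_pos)
}

#' Upper-tail probability of the negative-removal count
#'
#' Probability that a uniform random removal of `n` edges contains at least
#' `k_neg_obs` negative edges: the exact sum of [hypergeom_pmf()] over
#' `k >= k_neg_obs` in log-space.
#'
#' @inheritParams hypergeom_pmf
#' @param n number of removed edges.
#' @param k_neg_obs observed negative-removal count.
#' @return tail probability in `[0, 1]`.
#' @export
tail_probability <- function(N_neg, N_pos, n, k_neg_obs) {
  k_hi <- min(n, N_neg)
  if (k_neg_obs > k_hi) return(0)
  k_lo <- max(k_neg_obs, 0, n - N_pos)
  ks <- k_lo:k_hi
  lp <- lchoose(N_neg, ks) + lchoose(N_pos, n - ks) -
    lchoose(N_neg + N_pos, n)
  mx <- max(lp)
  exp(mx) * sum(exp(lp - mx))
}

## Removal sets of every single method and the intersection, reusing one
## triplet_flags evaluation.
removal_modes <- function(network, flags, params) {
  modes <- list()
  for (m in params$methods) {
    pm <- params; pm$methods <- m; pm$combination <- "single"
    modes[[m]] <- combine_verdicts(network, flags, pm)
  }
  modes[["intersection"]] <- combine_verdicts(network, flags, params)
  modes
}

#' Benchmark the edge classifiers on simulated communities
#'
#' For each replicate: simulate a community, optionally add Poisson noise,
#' construct an association network, evaluate every environmental triplet
#' once, and derive the removal set of each single method plus the
#' intersection combination; then score each against the simulator's ground
#' truth. Replicates whose network has no microbial edge are recorded with
#' `NA` rates and skipped in the medians.
#'
#' @param sim_cfg a [sim_config()]; its seed is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param assoc_parms an [assoc_params()]. Defaults to
#'   `assoc_params(q_threshold = 1)`: the pure permutation p-value cannot
#'   clear a Bonferroni-corrected 0.001 over ~1300 tests (its floor is
#'   `1/(permutations+1)`), so the corrected filter is disabled here.
#' @param ended_parms an [ended_params()].
#' @param n_datasets number of replicates.
#' @param noise add Poisson noise before network construction.
#' @param noise_scale passed to [add_poisson_noise()].
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @return list of class `ended_benchmark` with
#'   \describe{
#'     \item{per_replicate}{one row per replicate x method: edge counts,
#'       removed count and fraction, confusion counts and rates.}
#'     \item{summary}{per-method medians and standard deviations.}
#'   }
#' @export
run_benchmark <- function(sim_cfg = sim_config(),
                          assoc_parms = assoc_params(q_threshold = 1),
                          ended_parms = ended_params(),
                          n_datasets = 10,
                          noise = FALSE, noise_scale = 1,
                          seed = 1) {
  stopifnot(n_datasets >= 1)
  rows <- list()
  for (i in seq_len(n_datasets)) {
    rep_seed <- as.integer(seed + i)
    res <- tryCatch(
      benchmark_replicate(sim_cfg, assoc_parms, ended_parms,
                          noise, noise_scale, rep_seed),
      error = function(e) {
        warning("replicate ", i, " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      res$replicate <- i
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("all benchmark replicates failed")
  per_rep <- do.call(rbind, rows)
  rownames(per_rep) <- NULL
  metric_cols <- c("removed_fraction", "TPR", "TNR", "FPR", "PPV", "ACC")
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$method), function(d) {
    med <- vapply(metric_cols, function(cn) median(d[[cn]], na.rm = TRUE),
                  numeric(1))
    sdv <- vapply(metric_cols, function(cn) sd(d[[cn]], na.rm = TRUE),
                  numeric(1))
    out <- data.frame(method = d$method[1L], n_replicates = nrow(d))
    for (cn in metric_cols) {
      out[[paste0("median_", cn)]] <- med[[cn]]
      out[[paste0("sd_", cn)]] <- sdv[[cn]]
    }
    out
  }))
  rownames(summ) <- NULL
  structure(list(per_replicate = per_rep, summary = summ),
            class = "ended_benchmark")
}

benchmark_replicate <- function(sim_cfg, assoc_parms, ended_parms,
                                noise, noise_scale, rep_seed) {
  cfg <- sim_cfg
  cfg$seed <- rep_seed
  sim <- simulate_community(cfg)
  ab <- sim$abundances
  if (noise) {
    set.seed(rep_seed)
    ab <- add_poisson_noise(ab, scale = noise_scale)
  }
  net <- construct_network(ab, env_matrix(sim), assoc_parms, seed = rep_seed)
  kind <- setNames(net$nodes$kind, net$nodes$id)
  micro_n <- sum(kind[net$edges$node1] == "taxon" &
                 kind[net$edges$node2] == "taxon")
  set.seed(rep_seed)
  flags <- triplet_flags(net, ab, env_matrix(sim), ended_parms)
  modes <- removal_modes(net, flags, ended_parms)
  out <- lapply(names(modes), function(mname) {
    verd <- modes[[mname]]
    rem <- verd[verd$removed, c("node1", "node2"), drop = FALSE]
    cc <- confusion(rem, net, sim$truth_edges)
    rt <- rates(cc)
    data.frame(method = mname, seed = rep_seed,
               n_edges = micro_n, n_triplet_edges = sum(verd$n_triplets > 0),
               removed = nrow(rem),
               removed_fraction = if (micro_n > 0) nrow(rem) / micro_n
                                  else NA_real_,
               TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               TPR = rt$TPR, TNR = rt$TNR, FPR = rt$FPR,
               PPV = rt$PPV, ACC = rt$ACC,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.ended_benchmark <- function(x, ...) {
  cat("Edge-removal benchmark over",
      max(x$per_replicate$replicate), "replicate(s)\n")
  print(x$summary[, c("method", "median_removed_fraction",
                      "median_TPR", "median_TNR", "median_PPV",
                      "median_ACC")], row.names = FALSE)
  invisible(x)
}
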