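# Independent oracles used to check the production code paths.

# Brute-force triplet enumeration over all node triples.
brute_triplets <- function(network) {
  kind <- setNames(network$nodes$kind, network$nodes$id)
  taxa <- sort(network$nodes$id[network$nodes$kind == "taxon"])
  facs <- sort(network$nodes$id[network$nodes$kind == "env"])
  has_edge <- function(a, b) !is.na(ended:::edge_index(network, a, b))
  out <- list()
  if (length(taxa) >= 2) for (i in seq_len(length(taxa) - 1)) {
    for (j in (i + 1):length(taxa)) for (f in facs) {
      v <- taxa[i]; w <- taxa[j]
      if (has_edge(v, w) && has_edge(v, f) && has_edge(w, f))
        out[[length(out) + 1L]] <- data.frame(v = v, w = w, f = f,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(v = character(), w = character(), f = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$v, res$w, res$f), ]
  rownames(res) <- NULL
  res
}

# Literal O(n^2) window scan for the local-similarity score.
brute_local_similarity <- function(x, y) {
  n <- length(x)
  best <- -1; best_start <- 0; best_dur <- 1; best_sign <- "+"
  for (i in seq_len(n)) for (j in i:n) {
    s <- sum(x[i:j] * y[i:j])
    a <- abs(s)
    cand_sign <- if (s >= 0) "+" else "-"
    better <- a > best ||
      (a == best && (i - 1 < best_start ||
        (i - 1 == best_start && (j - i + 1 > best_dur ||
          (j - i + 1 == best_dur && cand_sign == "+" && best_sign == "-")))))
    if (better) {
      best <- a; best_start <- i - 1; best_dur <- j - i + 1
      best_sign <- cand_sign
    }
  }
  list(score = best / n, sign = best_sign, start = best_start,
       duration = best_dur)
}

# Direct double-sum MI over empirical probabilities (0-based labels).
mi_direct <- function(v, w) {
  n <- length(v)
  tab <- table(v, w) / n
  pv <- rowSums(tab); pw <- colSums(tab)
  s <- 0
  for (i in seq_along(pv)) for (j in seq_along(pw)) {
    p <- tab[i, j]
    if (p > 0) s <- s + p * log(p / (pv[i] * pw[j]))
  }
  unname(s)
}

# Direct triple-sum CMI over empirical probabilities.
cmi_direct <- function(v, w, f) {
  n <- length(v)
  tab <- table(v, w, f) / n
  pf <- apply(tab, 3, sum)
  pvf <- apply(tab, c(1, 3), sum)
  pwf <- apply(tab, c(2, 3), sum)
  s <- 0
  d <- dim(tab)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- tab[i, j, k]
    if (p > 0)
      s <- s + p * log(pf[k] * p / (pvf[i, k] * pwf[j, k]))
  }
  unname(s)
}

# Small random network over a handful of taxa and factors, each possible
# edge present independently; full-window timings.
random_network <- function(n_taxa, n_fac, p_edge = 0.4, n_samples = 20) {
  ids <- c(paste0("t", seq_len(n_taxa)), paste0("f", seq_len(n_fac)))
  kinds <- c(rep("taxon", n_taxa), rep("env", n_fac))
  nodes <- data.frame(id = ids, kind = kinds, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    if (kinds[i] == "env" && kinds[j] == "env") next
    if (runif(1) < p_edge) {
      s <- sample(c(-1, 1), 1) * runif(1, 0.1, 1)
      rows[[length(rows) + 1L]] <-
        data.frame(node1 = ids[i], node2 = ids[j], score = s,
                   p = 0.001, q = 0.001, start = 0L, duration = n_samples,
                   stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else NULL
  assoc_network(nodes, edges, n_samples = n_samples)
}

write_tsv_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
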