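#' @useDynLib ended, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median p.adjust rpois runif sd setNames
#' @importFrom utils read.delim write.table
NULL

## Canonical key for an unordered node pair; used everywhere edges are
## looked up or compared.
edge_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\001")
}

#' Create an association network
#'
#' An association network is an undirected graph whose nodes are taxa or
#' environmental factors and whose edges are signed, timed associations
#' (co-presence when the score is positive, mutual exclusion when negative).
#' Each edge carries the association score, p- and q-values, and the time
#' window of the association as a 0-based half-open sample interval
#' `[start, start + duration)`.
#'
#' @param nodes data.frame with columns `id` (unique, non-empty) and `kind`
#'   (`"taxon"` or `"env"`).
#' @param edges data.frame with columns `node1`, `node2`, `score`, `p`, `q`,
#'   `start`, `duration`. A `sign` column (`"+"`/`"-"`) is derived from the
#'   score; a zero score is rejected.
#' @param n_samples number of samples in the underlying series, or `NA` when
#'   unknown. When known, every edge window must fit inside it.
#' @return An object of class `assoc_network`: a list with elements `nodes`,
#'   `edges` and `n_samples`.
#' @export
assoc_network <- function(nodes, edges, n_samples = NA_integer_) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "kind") %in% names(nodes)))
    stop("node table needs columns 'id' and 'kind'")
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  if (nrow(edges) == 0) {
    edges <- data.frame(node1 = character(), node2 = character(),
                        score = numeric(), sign = character(),
                        p = numeric(), q = numeric(),
                        start = integer(), duration = integer(),
                        stringsAsFactors = FALSE)
  } else {
    need <- c("node1", "node2", "score", "p", "q", "start", "duration")
    miss <- setdiff(need, names(edges))
    if (length(miss))
      stop("edge table is missing required column(s): ",
           paste(miss, collapse = ", "))
    edges$node1 <- as.character(edges$node1)
    edges$node2 <- as.character(edges$node2)
    edges$sign <- ifelse(edges$score > 0, "+", "-")
    edges <- edges[, c("node1", "node2", "score", "sign",
                       "p", "q", "start", "duration")]
  }
  net <- structure(list(nodes = nodes, edges = edges,
                        n_samples = as.integer(n_samples)),
                   class = "assoc_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (any(!nzchar(nodes$id))) stop("empty node id")
  if (anyDuplicated(nodes$id)) stop("duplicate node id(s)")
  if (!all(nodes$kind %in% c("taxon", "env")))
    stop("node kind must be 'taxon' or 'env'")
  if (nrow(edges)) {
    loops <- which(edges$node1 == edges$node2)
    if (length(loops))
      stop("self-loop edge at row ", loops[1L], ": ", edges$node1[loops[1L]])
    unknown <- setdiff(c(edges$node1, edges$node2), nodes$id)
    if (length(unknown))
      stop("edge endpoint(s) not in node table: ",
           paste(unique(unknown), collapse = ", "))
    zero <- which(edges$score == 0)
    if (length(zero)) stop("edge with score 0 at row ", zero[1L])
    keys <- edge_key(edges$node1, edges$node2)
    if (anyDuplicated(keys))
      stop("duplicate edge for pair at row ", which(duplicated(keys))[1L])
    if (any(edges$p < 0 | edges$p > 1) || any(edges$q < 0 | edges$q > 1))
      stop("p and q values must lie in [0, 1]")
    if (any(edges$duration < 1)) stop("edge duration must be >= 1")
    if (any(edges$start < 0)) stop("edge start index must be >= 0")
    if (!is.na(net$n_samples) &&
        any(edges$start + edges$duration > net$n_samples))
      stop("edge window exceeds the sample axis (start + duration > n_samples)")
  }
  invisible(net)
}

#' @export
print.assoc_network <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = c("taxon", "env")))
  cat("Association network:", nrow(x$nodes), "nodes (",
      kinds[["taxon"]], "taxa,", kinds[["env"]], "environmental factors ),",
      nrow(x$edges), "edges\n")
  if (!is.na(x$n_samples)) cat("Sample axis:", x$n_samples, "samples\n")
  invisible(x)
}

#' Read a node table
#'
#' Tab-separated file with header `id  kind`, `kind` being `taxon` or `env`.
#' Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `kind`.
#' @export
read_node_table <- function(path) {
  tab <- read.delim(path, sep = "\t", comment.char = "#",
                    colClasses = "character")
  if (!all(c("id", "kind") %in% names(tab)))
    stop("node table ", path, " is missing required column(s): ",
         paste(setdiff(c("id", "kind"), names(tab)), collapse = ", "))
  tab[, c("id", "kind")]
}

#' Read an association network from an edge table
#'
#' The edge table is a TSV with a header naming at least
#' `node1 node2 score p q start duration` (extra columns, such as the ones
#' written by [write_annotated_edge_table()], are ignored). Node kinds come
#' from a companion node table (see [read_node_table()]); nodes appearing in
#' the edge table but not in the node table are an error.
#'
#' @param path edge table path.
#' @param nodes node table data.frame (`id`, `kind`) or path to one.
#' @param n_samples optional sample count used to validate edge windows.
#' @return An [assoc_network()].
#' @export
read_edge_table <- function(path, nodes, n_samples = NA) {
  if (is.character(nodes)) nodes <- read_node_table(nodes)
  tab <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("node1", "node2", "score", "p", "q", "start", "duration")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("edge table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  assoc_network(nodes, tab, n_samples = n_samples)
}

#' Write an annotated edge table
#'
#' Emits the input edge columns plus, per edge, the number of environmental
#' triplets in which it was evaluated as the microbial edge, the per-method
#' flagged-triplet counts, and the final removal decision. Column order is
#' fixed: `node1 node2 score p q start duration n_triplets sp_flags ol_flags
#' ii_flags dpi_flags removed`. Edges outside any triplet (including all
#' taxon-factor edges) get zero counts and `removed = FALSE`.
#'
#' @param network an [assoc_network()].
#' @param verdicts the `verdicts` data.frame of an [apply_ended()] result;
#'   one row per network edge.
#' @param path output file path.
#' @param header optional character vector of provenance lines written as
#'   `#`-prefixed comments before the table.
#' @return Invisibly, the written data.frame.
#' @export
write_annotated_edge_table <- function(network, verdicts, path, header = NULL) {
  edges <- network$edges
  keys <- edge_key(edges$node1, edges$node2)
  vkeys <- edge_key(verdicts$node1, verdicts$node2)
  idx <- match(keys, vkeys)
  if (anyNA(idx))
    stop("verdict missing for edge ", edges$node1[which(is.na(idx))[1L]],
         " -- ", edges$node2[which(is.na(idx))[1L]])
  out <- cbind(edges[, c("node1", "node2", "score", "p", "q",
                         "start", "duration")],
               verdicts[idx, c("n_triplets", "sp_flags", "ol_flags",
                               "ii_flags", "dpi_flags", "removed")])
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (line in header) writeLines(paste0("# ", line), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Enumerate environmental triplets
#'
#' An environmental triplet is a closed triplet `{v, w, f}` in which `v` and
#' `w` are taxa, `f` is an environmental factor, and all three pairwise edges
#' are present in the network. Every detection method operates on these
#' units. The result is ordered by `(v, w, f)` ids, one row per
#' (unordered taxon pair, factor).
#'
#' @param network an [assoc_network()].
#' @return data.frame with columns `v`, `w` (taxa, `v < w`) and `f` (factor);
#'   zero rows when the network has no triplet.
#' @export
find_environmental_triplets <- function(network) {
  edges <- network$edges
  empty <- data.frame(v = character(), w = character(), f = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(edges)) return(empty)
  kind <- setNames(network$nodes$kind, network$nodes$id)
  k1 <- kind[edges$node1]; k2 <- kind[edges$node2]
  tt <- edges[k1 == "taxon" & k2 == "taxon", , drop = FALSE]
  tf <- edges[xor(k1 == "env", k2 == "env"), , drop = FALSE]
  if (!nrow(tt) || !nrow(tf)) return(empty)
  # factor -> associated taxa
  fac <- ifelse(kind[tf$node1] == "env", tf$node1, tf$node2)
  tax <- ifelse(kind[tf$node1] == "env", tf$node2, tf$node1)
  tfkey <- paste(tax, fac, sep = "\001")
  out <- vector("list", nrow(tt))
  for (i in seq_len(nrow(tt))) {
    v <- min(tt$node1[i], tt$node2[i])
    w <- max(tt$node1[i], tt$node2[i])
    fv <- fac[tax == v]
    fw <- fac[tax == w]
    fs <- sort(intersect(fv, fw))
    if (length(fs))
      out[[i]] <- data.frame(v = v, w = w, f = fs, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$v, out$w, out$f), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Pair lookup: row index of the edge {u,v} in network$edges, NA if absent.
edge_index <- function(network, u, v) {
  match(edge_key(u, v), edge_key(network$edges$node1, network$edges$node2))
}

#' Jaccard co-occurrence index
#'
#' Number of samples in which both taxa are present divided by the number of
#' samples in which at least one is present. Presence means abundance above
#' `threshold` (default 0). Two all-absent vectors give 0.
#'
#' @param x,y abundance vectors over the same sample axis.
#' @param threshold presence threshold; a sample counts as occupied when the
#'   value is strictly greater than this.
#' @return a number in `[0, 1]`.
#' @export
jaccard_index <- function(x, y, threshold = 0) {
  if (length(x) != length(y))
    stop("jaccard_index: vectors differ in length (",
         length(x), " vs ", length(y), ")")
  px <- x > threshold
  py <- y > threshold
  u <- sum(px | py)
  if (u == 0) return(0)
  sum(px & py) / u
}

#' Read an abundance or environment sample matrix
#'
#' TSV with the row id in the first column and samples, in temporal order, in
#' the remaining columns. Abundance matrices must be non-negative;
#' environment matrices are unconstrained.
#'
#' @param path file path.
#' @param role `"abundance"` or `"environment"`.
#' @return numeric matrix (rows x samples) with row and column names and a
#'   `"role"` attribute.
#' @export
read_sample_matrix <- function(path, role = c("abundance", "environment")) {
  role <- match.arg(role)
  tab <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(ids)) stop("duplicate row id in ", path)
  if (role == "abundance" && any(m < 0))
    stop("abundance matrix ", path, " contains negative values")
  attr(m, "role") <- role
  m
}

write_sample_matrix <- function(m, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (line in header) writeLines(paste0("# ", line), con)
  out <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
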