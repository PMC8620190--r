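test_that("sign pattern flags exactly the even-minus combinations", {
  combos <- expand.grid(s_vw = c("+", "-"), s_vf = c("+", "-"),
                        s_wf = c("+", "-"), stringsAsFactors = FALSE)
  flagged <- mapply(sign_pattern, combos$s_vw, combos$s_vf, combos$s_wf)
  expect_equal(sum(flagged), 4L)
  parity <- rowSums(combos == "-") %% 2 == 0
  expect_equal(unname(flagged), parity)
  expect_true(sign_pattern("+", "+", "+"))
  expect_false(sign_pattern("+", "+", "-"))
  expect_true(sign_pattern("-", "-", "+"))
  expect_error(sign_pattern("+", "x", "-"), "signs")
})

test_that("overlap percentage follows the min/max window rule without clipping", {
  win <- function(b, d) list(start = b, duration = d)
  expect_equal(overlap_percent(win(0, 10), win(0, 10), win(0, 10)), 100)
  # O = 60 exactly: not flagged under the strict > 60 rule
  expect_equal(overlap_percent(win(0, 10), win(4, 10), win(0, 10)), 60)
  expect_false(overlap_percent(win(0, 10), win(4, 10), win(0, 10)) > 60)
  # disjoint windows go negative
  expect_equal(overlap_percent(win(0, 10), win(12, 8), win(12, 8)), -20)
  expect_error(overlap_percent(win(0, 0), win(0, 10), win(0, 10)),
               "zero length")
})

test_that("DPI flags the smallest mutual information, ties included", {
  expect_true(dpi_flag(0.1, 0.5, 0.3))
  expect_false(dpi_flag(0.4, 0.5, 0.3))
  expect_true(dpi_flag(0.3, 0.3, 0.5))
  expect_error(dpi_flag(-0.1, 0.5, 0.3), ">= 0")
})

make_triplet_data <- function(n = 64, seed = 21) {
  # v and w strongly coupled, f unrelated: DPI should not blame the factor
  set.seed(seed)
  v <- runif(n)
  w <- v + runif(n, 0, 0.05)
  f <- runif(n)
  abund <- rbind(t1 = v, t2 = w)
  colnames(abund) <- paste0("s", seq_len(n))
  env <- rbind(F1 = f)
  colnames(env) <- colnames(abund)
  nodes <- data.frame(id = c("t1", "t2", "F1"),
                      kind = c("taxon", "taxon", "env"))
  edge <- function(a, b, s, b0 = 0, d = n)
    data.frame(node1 = a, node2 = b, score = s, p = 0.001, q = 0.001,
               start = b0, duration = d)
  net <- assoc_network(nodes, rbind(edge("t1", "t2", 0.9),
                                    edge("t1", "F1", 0.5),
                                    edge("t2", "F1", 0.5)), n)
  list(net = net, abund = abund, env = env)
}

test_that("evaluate_triplet computes only the requested methods", {
  d <- make_triplet_data()
  tr <- find_environmental_triplets(d$net)[1, ]

  sp_only <- evaluate_triplet(tr, d$net, d$abund, d$env,
                              ended_params(methods = "SP",
                                           combination = "single"))
  expect_true(sp_only$sp)            # signs (+,+,+)
  expect_true(is.na(sp_only$ol) && is.na(sp_only$ii) && is.na(sp_only$dpi))

  set.seed(1)
  full <- evaluate_triplet(tr, d$net, d$abund, d$env,
                           ended_params(ii_iterations = 200))
  expect_equal(full$overlap_O, 100)  # all windows span all samples
  expect_true(full$ol)
  # tightly coupled taxa, independent factor: MI(v,w) dominates
  expect_gt(full$mi_vw, full$mi_vf)
  expect_gt(full$mi_vw, full$mi_wf)
  expect_false(full$dpi)
})

test_that("identical series give negative II and a DPI tie", {
  n <- 64
  set.seed(31)
  x <- runif(n)
  abund <- rbind(t1 = x, t2 = x)
  colnames(abund) <- paste0("s", seq_len(n))
  env <- rbind(F1 = x)
  colnames(env) <- colnames(abund)
  nodes <- data.frame(id = c("t1", "t2", "F1"),
                      kind = c("taxon", "taxon", "env"))
  edge <- function(a, b) data.frame(node1 = a, node2 = b, score = 0.9,
                                    p = 0.001, q = 0.001, start = 0,
                                    duration = n)
  net <- assoc_network(nodes, rbind(edge("t1", "t2"), edge("t1", "F1"),
                                    edge("t2", "F1")), n)
  tr <- find_environmental_triplets(net)[1, ]
  set.seed(2)
  fl <- evaluate_triplet(tr, net, abund, env, ended_params(ii_iterations = 100))
  expect_lt(fl$ii_value, 0)
  expect_equal(fl$ii_value, -fl$mi_vw)
  expect_true(fl$dpi)                # mi_vw == mi_vf == mi_wf, tie flagged
})

test_that("combination rules: intersection keeps, union and single remove", {
  # SP and OL flag the triplet, DPI does not (coupled taxa, unrelated f)
  d <- make_triplet_data()
  params <- function(comb, methods = c("SP", "OL", "DPI"))
    ended_params(methods = methods, combination = comb)

  res_int <- apply_ended(d$net, d$abund, d$env, params("intersection"),
                         seed = 1)
  expect_equal(nrow(res_int$removed), 0L)

  res_union <- apply_ended(d$net, d$abund, d$env, params("union"), seed = 1)
  expect_equal(nrow(res_union$removed), 1L)

  res_sp <- apply_ended(d$net, d$abund, d$env, params("single", "SP"),
                        seed = 1)
  expect_equal(nrow(res_sp$removed), 1L)
  expect_equal(sort(unlist(res_sp$removed[1, ], use.names = FALSE)),
               c("t1", "t2"))

  # verdict bookkeeping
  v <- res_int$verdicts
  micro <- v$node1 == "t1" & v$node2 == "t2"
  expect_equal(v$n_triplets[micro], 1L)
  expect_equal(v$sp_flags[micro], 1L)
  expect_equal(v$dpi_flags[micro], 0L)
  # taxon-factor edges are never removed and carry no triplet counts
  expect_true(all(v$n_triplets[!micro] == 0L))
  expect_false(any(v$removed[!micro]))
})

test_that("edges outside any triplet are always kept", {
  nodes <- data.frame(id = c("a", "b", "T"), kind = c("taxon", "taxon", "env"))
  edges <- data.frame(node1 = c("a", "a"), node2 = c("b", "T"),
                      score = c(0.5, 0.5), p = 0.001, q = 0.001,
                      start = 0, duration = 10)
  net <- assoc_network(nodes, edges, 10)
  for (comb in c("intersection", "union")) {
    res <- apply_ended(net, params = ended_params(methods = c("SP", "OL"),
                                                  combination = comb))
    expect_equal(nrow(res$removed), 0L)
    expect_true(all(res$verdicts$n_triplets == 0L))
  }
})

test_that("agreement across different triplets is opt-in", {
  # t1-t2 sits in two triplets: OL flags only the F1 triplet (full overlap),
  # SP flags only the F2 triplet (sign parity). Per-triplet intersection
  # keeps the edge; across-triplet agreement removes it.
  n <- 20
  nodes <- data.frame(id = c("t1", "t2", "F1", "F2"),
                      kind = c("taxon", "taxon", "env", "env"))
  edge <- function(a, b, s, b0, d)
    data.frame(node1 = a, node2 = b, score = s, p = 0.001, q = 0.001,
               start = b0, duration = d)
  net <- assoc_network(nodes, rbind(
    edge("t1", "t2", 0.9, 0, n),
    edge("t1", "F1", 0.5, 0, n), edge("t2", "F1", -0.5, 0, n),  # SP: odd
    edge("t1", "F2", 0.5, 15, 5), edge("t2", "F2", 0.5, 15, 5)  # OL: 25%
  ), n)
  params_pt <- ended_params(methods = c("SP", "OL"))
  res_pt <- apply_ended(net, params = params_pt)
  expect_equal(nrow(res_pt$removed), 0L)

  params_at <- ended_params(methods = c("SP", "OL"),
                            agree_across_triplets = TRUE)
  res_at <- apply_ended(net, params = params_at)
  expect_equal(nrow(res_at$removed), 1L)
})

test_that("removal sets are monotone across combinations and seeded", {
  cfg <- sim_config(n_taxa = 12, seed = 77)
  sim <- simulate_community(cfg)
  net <- construct_network(sim$abundances, env_matrix(sim),
                           assoc_params(permutations = 500, q_threshold = 1),
                           seed = 77)
  ab <- sim$abundances; env <- env_matrix(sim)
  params <- ended_params(ii_iterations = 200)
  res_int <- apply_ended(net, ab, env, params, seed = 5)
  key <- function(d) paste(d$node1, d$node2)
  singles <- lapply(c("SP", "OL", "II", "DPI"), function(m) {
    apply_ended(net, ab, env,
                ended_params(methods = m, combination = "single",
                             ii_iterations = 200), seed = 5)
  })
  union <- apply_ended(net, ab, env,
                       ended_params(combination = "union",
                                    ii_iterations = 200), seed = 5)
  for (s in singles) {
    expect_true(all(key(res_int$removed) %in% key(s$removed)))
    expect_true(all(key(s$removed) %in% key(union$removed)))
  }

  # same seed reproduces p-values and the removal set exactly
  res_int2 <- apply_ended(net, ab, env, params, seed = 5)
  expect_identical(res_int$flags$ii_p, res_int2$flags$ii_p)
  expect_identical(res_int$removed, res_int2$removed)
})
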