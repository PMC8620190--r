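#' Configuration of the community simulator
#'
#' Defaults reproduce the benchmark conditions: 50 taxa, a sparse modular
#' scale-free interaction matrix at interaction probability 0.01 with 30%
#' positive off-diagonal coefficients and self-limitation -0.5, one external
#' sinusoidal environmental driver (period 12 months) acting through
#' Gaussian niche growth-rate functions, one internal environmental factor
#' embedded in the interaction matrix (half the taxa affected positively,
#' half negatively, magnitudes U(0.2, 0.8)), and a time grid from 0 to 49.5
#' at resolution 0.5, i.e. 100 samples.
#'
#' @param n_taxa number of taxa.
#' @param interaction_probability probability that an unordered taxon pair
#'   interacts; the topology generator targets this density.
#' @param positive_fraction fraction of positive off-diagonal taxon-taxon
#'   coefficients.
#' @param diagonal self-interaction coefficient (carrying capacity).
#' @param coupling_range magnitude range for interaction and
#'   internal-factor coupling coefficients.
#' @param gmax_range,sigma_range ranges for the niche maximum growth rate
#'   and tolerance (niche width).
#' @param period_T external signal periodicity in months.
#' @param t_start,t_end,dt time grid (months); `(t_end - t_start)/dt + 1`
#'   samples.
#' @param internal_env internal-factor niche constants and initial value.
#' @param clique_size,rewiring_mu Klemm-Eguiluz topology parameters.
#' @param gmax_squared use the squared maximum growth rate as the amplitude
#'   of the niche response (default); `FALSE` uses `gmax` unsquared.
#' @param seed integer seed used by [simulate_community()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 50,
                       interaction_probability = 0.01,
                       positive_fraction = 0.30,
                       diagonal = -0.5,
                       coupling_range = c(0.2, 0.8),
                       gmax_range = c(0.3, 1),
                       sigma_range = c(0.3, 1),
                       period_T = 12,
                       t_start = 0, t_end = 49.5, dt = 0.5,
                       internal_env = list(gmax = 0.8, eopt = 0.5,
                                           sigma = 0.5, init = 0.001),
                       clique_size = 5,
                       rewiring_mu = 0.1,
                       gmax_squared = TRUE,
                       seed = 1L) {
  stopifnot(interaction_probability > 0, interaction_probability < 1,
            dt > 0, n_taxa >= 1, period_T > 0)
  structure(list(n_taxa = n_taxa,
                 interaction_probability = interaction_probability,
                 positive_fraction = positive_fraction,
                 diagonal = diagonal,
                 coupling_range = coupling_range,
                 gmax_range = gmax_range, sigma_range = sigma_range,
                 period_T = period_T,
                 t_start = t_start, t_end = t_end, dt = dt,
                 internal_env = internal_env,
                 clique_size = clique_size, rewiring_mu = rewiring_mu,
                 gmax_squared = isTRUE(gmax_squared),
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_times <- function(cfg) seq(cfg$t_start, cfg$t_end, by = cfg$dt)

#' Modular scale-free topology (Klemm-Eguiluz growth process)
#'
#' Grows a network from a seed clique of `clique_size` active nodes: each
#' new node attaches to every active node, each attachment being rewired
#' with probability `rewiring_mu` to a random non-active node chosen
#' preferentially by degree; the new node becomes active and one active node
#' is deactivated with probability inversely proportional to its degree.
#' The resulting edge set is then subsampled (or augmented with uniform
#' random non-edges) to hit `density_target` within one edge.
#'
#' Uses R's RNG; seed with [set.seed()].
#'
#' @param n number of nodes (`>= clique_size`).
#' @param density_target target edge density over the `n(n-1)/2` pairs.
#' @param clique_size size of the fully connected seed / active set.
#' @param rewiring_mu per-attachment rewiring probability in `[0, 1]`.
#' @return symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
klemm_eguiluz_topology <- function(n, density_target,
                                   clique_size = 5, rewiring_mu = 0.1) {
  m <- clique_size
  if (n < m || m < 2) stop("need n >= clique_size >= 2")
  if (rewiring_mu < 0 || rewiring_mu > 1) stop("rewiring_mu must be in [0,1]")
  adj <- matrix(0L, n, n)
  active <- seq_len(m)
  adj[active, active] <- 1L
  diag(adj) <- 0L
  if (n > m) for (v in (m + 1):n) {
    deg <- rowSums(adj[, seq_len(v - 1L), drop = FALSE])
    for (a in active) {
      target <- a
      if (runif(1) < rewiring_mu) {
        # rewire to a random non-active existing node, degree-preferential
        cand <- setdiff(seq_len(v - 1L), c(active, v))
        cand <- cand[adj[v, cand] == 0L]
        if (length(cand)) {
          wts <- deg[cand] + 1
          target <- cand[sample.int(length(cand), 1L, prob = wts)]
        }
      }
      adj[v, target] <- adj[target, v] <- 1L
    }
    # deactivate one active node with probability inversely prop. to degree
    deg_act <- rowSums(adj)[active]
    drop <- active[sample.int(length(active), 1L, prob = 1 / deg_act)]
    active <- c(setdiff(active, drop), v)
  }
  n_target <- round(density_target * n * (n - 1) / 2)
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  present <- ut[adj[ut] == 1L, , drop = FALSE]
  absent <- ut[adj[ut] == 0L, , drop = FALSE]
  have <- nrow(present)
  if (n_target > have + nrow(absent) || n_target < 0)
    stop("density_target unreachable")
  if (have > n_target) {
    keep <- sample.int(have, n_target)
    dropped <- present[setdiff(seq_len(have), keep), , drop = FALSE]
    adj[dropped] <- 0L
    adj[dropped[, c(2, 1), drop = FALSE]] <- 0L
  } else if (have < n_target) {
    addn <- absent[sample.int(nrow(absent), n_target - have), , drop = FALSE]
    adj[addn] <- 1L
    adj[addn[, c(2, 1), drop = FALSE]] <- 1L
  }
  adj
}

#' Build the interaction matrix
#'
#' Assigns every adjacency edge a directed coefficient pair with magnitudes
#' drawn uniformly from `cfg$coupling_range`; `cfg$positive_fraction` of the
#' non-zero off-diagonal taxon-taxon coefficients are positive. All diagonal
#' entries are set to `cfg$diagonal`. A final column couples the internal
#' environmental factor to the taxa: a random half of the taxa is affected
#' positively, the other half negatively, magnitudes again from
#' `cfg$coupling_range`. The internal factor's row is zero off-diagonal (the
#' community does not feed back on the factor).
#'
#' Uses R's RNG; seed with [set.seed()].
#'
#' @param adjacency symmetric 0/1 matrix over the taxa.
#' @param cfg a [sim_config()].
#' @return `(n_taxa + 1) x (n_taxa + 1)` matrix; entry `[j, i]` is the
#'   effect of column organism `i` on row organism `j`, the last index being
#'   the internal factor.
#' @export
build_interaction_matrix <- function(adjacency, cfg = sim_config()) {
  n <- nrow(adjacency)
  A <- matrix(0, n + 1L, n + 1L)
  ut <- which(upper.tri(adjacency) & adjacency == 1L, arr.ind = TRUE)
  n_coef <- 2L * nrow(ut)
  if (n_coef > 0) {
    mag <- runif(n_coef, cfg$coupling_range[1L], cfg$coupling_range[2L])
    n_pos <- round(cfg$positive_fraction * n_coef)
    sgn <- sample(c(rep(1, n_pos), rep(-1, n_coef - n_pos)))
    coef <- mag * sgn
    for (k in seq_len(nrow(ut))) {
      i <- ut[k, 1L]; j <- ut[k, 2L]
      A[i, j] <- coef[2L * k - 1L]
      A[j, i] <- coef[2L * k]
      # a reciprocal mutualistic pair with coefficient product exceeding the
      # self-limitation bound diag^2 has no positive equilibrium and blows up
      # in finite time; shrink both coefficients to keep the product at 90%
      # of the bound while preserving their ratio and signs
      if (A[i, j] > 0 && A[j, i] > 0) {
        bound <- 0.9 * cfg$diagonal^2
        if (A[i, j] * A[j, i] > bound) {
          s <- sqrt(bound / (A[i, j] * A[j, i]))
          A[i, j] <- A[i, j] * s
          A[j, i] <- A[j, i] * s
        }
      }
    }
  }
  # internal environmental factor: affects half the taxa positively
  half <- sample(n, floor(n / 2))
  emag <- runif(n, cfg$coupling_range[1L], cfg$coupling_range[2L])
  esign <- rep(-1, n)
  esign[half] <- 1
  A[seq_len(n), n + 1L] <- emag * esign
  diag(A) <- cfg$diagonal
  ids <- c(paste0("sp", seq_len(n)), "env_internal")
  dimnames(A) <- list(ids, ids)
  A
}

#' Seasonal external environmental signal
#'
#' `round(sin(omega * t), 3)` with `omega = -2 * pi / T`: a sinusoid of
#' period `T` months, phase-shifted so it decreases from 0 at `t = 0`,
#' rounded to 3 digits.
#'
#' @param t time (months), vectorized.
#' @param T signal periodicity in months (default 12).
#' @return signal value(s) in `[-1, 1]`.
#' @export
environmental_signal <- function(t, T = 12) {
  round(sin(-2 * pi / T * t), 3)
}

#' Gaussian niche growth-rate response
#'
#' `g = gmax^2 * exp(-(eopt - eps)^2 / (2 sigma^2))`: the growth rate peaks
#' at the organism's optimal environmental value `eopt`, with amplitude
#' `gmax^2` (the squared maximum growth rate) and niche width `sigma`. With
#' `gmax_squared = FALSE` the amplitude is `gmax` instead.
#'
#' @param eps environmental value(s).
#' @param gmax maximum growth rate (> 0).
#' @param eopt optimal environmental value.
#' @param sigma ecological tolerance / niche width (> 0).
#' @param gmax_squared square the amplitude (default `TRUE`).
#' @return growth rate(s).
#' @export
growth_rate <- function(eps, gmax, eopt, sigma, gmax_squared = TRUE) {
  if (any(sigma <= 0) || any(gmax <= 0)) stop("gmax and sigma must be > 0")
  amp <- if (gmax_squared) gmax^2 else gmax
  amp * exp(-0.5 * (eopt - eps)^2 / sigma^2)
}

#' Random broken-stick initial abundances
#'
#' Partitions the unit interval at `n - 1` uniform random cut points and
#' returns the `n` strictly positive segment lengths: uneven initial
#' relative abundances summing to 1, with no zeros (almost surely).
#'
#' Uses R's RNG; seed with [set.seed()].
#'
#' @param n number of taxa (>= 1).
#' @return positive numeric vector of length `n` summing to 1.
#' @export
stick_breaking_abundances <- function(n) {
  if (n < 1) stop("n must be >= 1")
  if (n == 1) return(1)
  diff(c(0, sort(runif(n - 1)), 1))
}

#' Simulate an environment-coupled community time series
#'
#' Integrates the generalized Lotka-Volterra system
#' `dy/dt = y * (b(t) + A y)` with [deSolve::lsoda()], where the growth-rate
#' vector `b(t)` follows each organism's Gaussian niche response
#' ([growth_rate()]) to the external sinusoidal signal
#' ([environmental_signal()]), and the interaction matrix `A`
#' ([build_interaction_matrix()]) embeds the internal environmental factor
#' as an extra state with no feedback from the taxa. Initial taxon
#' abundances come from [stick_breaking_abundances()]; the state is sampled
#' on the configured grid and negative values are clipped to 0 at each
#' output step. Integrator tolerances are `rtol = atol = 1e-6`.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds all randomness.
#' @return list of class `community_ts`:
#'   \describe{
#'     \item{abundances}{`n_taxa x n_samples` matrix (rows `sp1..spN`).}
#'     \item{external_env}{the sampled external signal.}
#'     \item{internal_env}{the internal factor's trajectory.}
#'     \item{truth_edges}{data.frame of unordered taxon pairs with a nonzero
#'       off-diagonal interaction coefficient in either direction.}
#'     \item{A, niche, times, config}{the interaction matrix, per-taxon
#'       niche parameters, sampling times, and the configuration.}
#'   }
#' @export
simulate_community <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_taxa
  adj <- if (n == 1) matrix(0L, 1, 1)
         else klemm_eguiluz_topology(n, cfg$interaction_probability,
                                     min(cfg$clique_size, n),
                                     cfg$rewiring_mu)
  A <- build_interaction_matrix(adj, cfg)
  niche <- data.frame(
    gmax = runif(n, cfg$gmax_range[1L], cfg$gmax_range[2L]),
    eopt = runif(n, -1, 1),
    sigma = runif(n, cfg$sigma_range[1L], cfg$sigma_range[2L]))
  rownames(niche) <- paste0("sp", seq_len(n))
  y0 <- c(stick_breaking_abundances(n), cfg$internal_env$init)
  times <- sim_times(cfg)
  ie <- cfg$internal_env
  gmax <- c(niche$gmax, ie$gmax)
  eopt <- c(niche$eopt, ie$eopt)
  sigma <- c(niche$sigma, ie$sigma)
  sq <- cfg$gmax_squared
  Tper <- cfg$period_T
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    eps <- environmental_signal(t, Tper)
    b <- growth_rate(eps, gmax, eopt, sigma, gmax_squared = sq)
    list(y * (b + as.vector(A %*% y)))
  }
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-6, atol = 1e-6)
  if (nrow(sol) < length(times))
    stop("gLV integration failed (seed ", cfg$seed, ")")
  states <- t(sol[, -1L, drop = FALSE])
  states[states < 0] <- 0
  ab <- states[seq_len(n), , drop = FALSE]
  rownames(ab) <- paste0("sp", seq_len(n))
  colnames(ab) <- paste0("s", seq_along(times))
  internal <- states[n + 1L, ]
  names(internal) <- colnames(ab)
  ext <- environmental_signal(times, Tper)
  names(ext) <- colnames(ab)
  ut <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  truth <- data.frame(v = paste0("sp", ut[, 1L]), w = paste0("sp", ut[, 2L]),
                      stringsAsFactors = FALSE)
  structure(list(abundances = ab, external_env = ext, internal_env = internal,
                 truth_edges = truth, A = A, niche = niche, times = times,
                 config = cfg),
            class = "community_ts")
}

#' @export
print.community_ts <- function(x, ...) {
  cat("Simulated community:", nrow(x$abundances), "taxa x",
      ncol(x$abundances), "samples;",
      nrow(x$truth_edges), "true interaction pairs\n")
  invisible(x)
}

#' Environment matrix of a simulated community
#'
#' Stacks the external signal and internal factor trajectory into the
#' factors-x-samples matrix expected by [construct_network()] and
#' [apply_ended()].
#'
#' @param sim a [simulate_community()] result.
#' @return 2 x n_samples matrix with rows `env_external`, `env_internal`.
#' @export
env_matrix <- function(sim) {
  m <- rbind(env_external = sim$external_env,
             env_internal = sim$internal_env)
  colnames(m) <- colnames(sim$abundances)
  attr(m, "role") <- "environment"
  m
}

#' Add Poisson sampling noise to an abundance matrix
#'
#' Each cell is replaced by `rpois(1, scale * value) / scale`. With
#' `scale = 1` the draw's mean is the abundance itself; larger scales emulate
#' count-like sampling at higher sequencing depth (relative noise shrinks as
#' `1/sqrt(scale * value)`).
#'
#' Uses R's RNG; seed with [set.seed()].
#'
#' @param abundances non-negative matrix.
#' @param scale positive scale factor (default 1).
#' @return noisy matrix of the same shape.
#' @export
add_poisson_noise <- function(abundances, scale = 1) {
  if (scale <= 0) stop("scale must be > 0")
  if (any(abundances < 0)) stop("abundances must be >= 0")
  noisy <- matrix(rpois(length(abundances), scale * abundances) / scale,
                  nrow = nrow(abundances), dimnames = dimnames(abundances))
  noisy
}
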