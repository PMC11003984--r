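## Ensemble ODE simulation: random kinetic-parameter sampling, shifted-Hill
## dynamics, steady-state solving, and knockdown re-simulation.
##
## For a gene Y with transcriptional regulators X_i the model is
##   dY/dt = G_Y / prod(lambda+_{X_i Y}) * prod_i Hs(X_i, X_iY_0, n, lambda)
##           - k_Y * Y
## where Hs is the shifted Hill function and the leading product runs over
## the excitatory in-edges only, so that G_Y keeps the meaning of the
## maximum production rate.

#' Shifted Hill regulation factor
#'
#' `Hs(X) = lambda + (1 - lambda) / (1 + (X / X0)^n)`.  For an excitatory
#' interaction `lambda > 1` and `Hs` ranges over (1, lambda); for an
#' inhibitory interaction `0 < lambda < 1` and `Hs` ranges over
#' (lambda, 1).  `Hs(0) = 1` always.
#'
#' @param x Regulator level (>= 0); vectorized.
#' @param x0 Threshold level (> 0).
#' @param n Hill coefficient (integer >= 1).
#' @param lambda Maximum fold change.
#' @return Regulation factor(s).
#' @export
shifted_hill <- function(x, x0, n, lambda) {
  stopifnot(all(x >= 0), x0 > 0, n >= 1)
  lambda + (1 - lambda) / (1 + (x / x0)^n)
}

#' Kinetic-parameter sampling ranges
#'
#' Uniform sampling ranges for the random ensemble: maximum production rate
#' G in (1, 100), degradation rate k in (0.1, 1), integer Hill coefficient
#' n in 1..6, excitatory fold change lambda+ in (1, 100) (inhibitory fold
#' changes are reciprocals of draws from the same range), and Hill
#' thresholds uniform on (0.02 M, 1.98 M) where M is the median
#' unregulated level under the half-functional rule.
#'
#' @param g,k Length-2 numeric ranges for production and degradation.
#' @param n Length-2 integer range for Hill coefficients.
#' @param lambda Length-2 range for fold changes (before inversion for
#'   inhibitory edges).
#' @param threshold_span Length-2 multipliers of M bounding the threshold
#'   range.
#' @param M Median Hill threshold; `NULL` means estimate it by Monte Carlo
#'   when sampling (see [estimate_median_threshold()]).
#' @return List of class `sampling_ranges`.
#' @export
sampling_ranges <- function(g = c(1, 100), k = c(0.1, 1), n = c(1L, 6L),
                            lambda = c(1, 100),
                            threshold_span = c(0.02, 1.98), M = NULL) {
  stopifnot(g[1] <= g[2], k[1] <= k[2], n[1] <= n[2], lambda[1] <= lambda[2],
            threshold_span[1] < threshold_span[2])
  if (!is.null(M)) stopifnot(M > 0)
  structure(list(g = g, k = k, n = as.integer(n), lambda = lambda,
                 threshold_span = threshold_span, M = M),
            class = "sampling_ranges")
}

#' Median Hill threshold by the half-functional rule
#'
#' Monte-Carlo estimate of the median unregulated expression level
#' `G / k` over the sampling ranges, used to anchor the Hill threshold
#' range.
#'
#' @param ranges A [sampling_ranges()].
#' @param n_draws Number of Monte-Carlo draws (default 1e5).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The scalar median M.
#' @export
estimate_median_threshold <- function(ranges, n_draws = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ranges$g[2] == 0 && ranges$k[2] == 0)
    stop("degenerate sampling ranges")
  g <- runif(n_draws, ranges$g[1], ranges$g[2])
  k <- runif(n_draws, ranges$k[1], ranges$k[2])
  median(g / k)
}

# edge bookkeeping shared by the samplers and integrator wrappers
edge_arrays <- function(net) {
  ed <- net$edges
  list(src = match(ed$from, net$nodes) - 1L,
       tgt = match(ed$to, net$nodes) - 1L,
       sign = ifelse(ed$sign == "activation", 1L, -1L))
}

#' Sample a random kinetic-parameter ensemble for a network
#'
#' Draws `n_models` independent parameter sets: per gene G and k, per edge
#' an integer Hill coefficient, a fold change (excitatory lambda+ from the
#' lambda range; inhibitory lambda- as the inverse of a draw from the same
#' range), and a Hill threshold on `(0.02 M, 1.98 M)`.
#'
#' @param net A `gene_network`.
#' @param ranges A [sampling_ranges()].
#' @param n_models Number of parameter sets.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List with matrices `G`, `K` (models x genes), `hn`, `lam`, `x0`
#'   (models x edges), the scalar `M`, and the gene/edge ordering.
#' @export
sample_parameters <- function(net, ranges = sampling_ranges(), n_models,
                              seed = NULL) {
  stopifnot(n_models >= 1)
  if (!is.null(seed)) set.seed(seed)
  genes <- net$nodes
  n_genes <- length(genes)
  ea <- edge_arrays(net)
  n_edges <- length(ea$src)
  M <- ranges$M
  if (is.null(M)) M <- estimate_median_threshold(ranges)
  G <- matrix(runif(n_models * n_genes, ranges$g[1], ranges$g[2]),
              n_models, n_genes, dimnames = list(NULL, genes))
  K <- matrix(runif(n_models * n_genes, ranges$k[1], ranges$k[2]),
              n_models, n_genes, dimnames = list(NULL, genes))
  hn <- matrix(sample(seq(ranges$n[1], ranges$n[2]),
                      n_models * max(n_edges, 1), replace = TRUE),
               n_models, max(n_edges, 1))[, seq_len(n_edges), drop = FALSE]
  raw <- matrix(runif(n_models * max(n_edges, 1), ranges$lambda[1],
                      ranges$lambda[2]),
                n_models, max(n_edges, 1))[, seq_len(n_edges), drop = FALSE]
  lam <- raw
  if (n_edges) {
    inhib <- ea$sign < 0
    lam[, inhib] <- 1 / raw[, inhib, drop = FALSE]
  }
  x0 <- matrix(runif(n_models * max(n_edges, 1),
                     ranges$threshold_span[1] * M,
                     ranges$threshold_span[2] * M),
               n_models, max(n_edges, 1))[, seq_len(n_edges), drop = FALSE]
  list(G = G, K = K, hn = hn, lam = lam, x0 = x0, M = M,
       genes = genes, edges = ea, n_models = n_models)
}

# log-uniform initial conditions between (G/k) * prod(lambda-)/prod(lambda+)
# over the gene's in-edges (minimum) and G/k (maximum)
sample_inits <- function(params) {
  n_models <- params$n_models
  n_genes <- length(params$genes)
  ymax <- params$G / params$K
  logfac <- matrix(0, n_models, n_genes)
  ea <- params$edges
  for (e in seq_along(ea$src)) {
    g <- ea$tgt[e] + 1L
    logfac[, g] <- logfac[, g] +
      if (ea$sign[e] > 0) -log(params$lam[, e]) else log(params$lam[, e])
  }
  lmin <- log(ymax) + logfac
  lmax <- log(ymax)
  u <- matrix(runif(n_models * n_genes), n_models, n_genes)
  init <- exp(lmin + u * (lmax - lmin))
  colnames(init) <- params$genes
  init
}

#' Integrate one model to steady state
#'
#' Single-model convenience wrapper around the ensemble integrator: fixed
#' time-step Euler with relative convergence test
#' `max |dY/dt| / max(Y, eps) < tol`.
#'
#' @param net A `gene_network`.
#' @param params One parameter set: list with numeric vectors `G`, `k`
#'   (per gene, in `net$nodes` order) and per-edge vectors `n`, `lambda`,
#'   `x0` (in `net$edges` row order).
#' @param init Initial expression vector (per gene).
#' @param dt,t_max Euler step and horizon (defaults 0.02, 100).
#' @param tol Relative convergence tolerance (default 1e-3).
#' @return List with `state` (named steady-state vector) and `converged`.
#' @export
simulate_model <- function(net, params, init, dt = 0.02, t_max = 100,
                           tol = 1e-3) {
  ea <- edge_arrays(net)
  res <- racipe_integrate(ea$src, ea$tgt, ea$sign,
                          matrix(params$G, 1), matrix(params$k, 1),
                          matrix(params$lambda, 1), matrix(params$x0, 1),
                          matrix(as.integer(params$n), 1),
                          matrix(init, 1), dt, t_max, tol, 25L)
  list(state = setNames(drop(res$steady), net$nodes),
       converged = res$converged[[1]])
}

#' Simulate a random-parameter ensemble of a network
#'
#' Samples `n_models` random parameter sets and one random initial
#' condition each, integrates every model to a fixed point, and stores the
#' raw steady states together with their standardized form (log2 then
#' z-scored per gene across converged models), which is the shared space
#' used for all downstream expression/activity comparisons.  Models that
#' fail the convergence test are retried once from a fresh initial
#' condition, then flagged; flagged models are excluded downstream.
#'
#' @param net A `gene_network`.
#' @param ranges A [sampling_ranges()].
#' @param n_models Ensemble size (default 10000).
#' @param seed Integer seed for the ensemble's generator stream.
#' @param dt,t_max,tol Integrator settings (defaults 0.02, 100, 1e-3).
#' @return Object of class `racipe_ensemble` with elements `network`,
#'   `genes`, `params`, `init`, `states` (models x genes raw steady
#'   states), `expr` (standardized), `converged`, `seed`.
#' @export
simulate_ensemble <- function(net, ranges = sampling_ranges(),
                              n_models = 10000, seed = 1, dt = 0.02,
                              t_max = 100, tol = 1e-3) {
  set.seed(seed)
  params <- sample_parameters(net, ranges, n_models)
  init <- sample_inits(params)
  ea <- params$edges
  res <- racipe_integrate(ea$src, ea$tgt, ea$sign, params$G, params$K,
                          params$lam, params$x0, params$hn, init,
                          dt, t_max, tol, 25L)
  states <- res$steady
  converged <- res$converged
  if (any(!converged)) {  # one retry from a fresh random init
    bad <- which(!converged)
    params_bad <- params
    for (f in c("G", "K")) params_bad[[f]] <- params[[f]][bad, , drop = FALSE]
    for (f in c("hn", "lam", "x0"))
      params_bad[[f]] <- params[[f]][bad, , drop = FALSE]
    params_bad$n_models <- length(bad)
    init2 <- sample_inits(params_bad)
    res2 <- racipe_integrate(ea$src, ea$tgt, ea$sign, params_bad$G,
                             params_bad$K, params_bad$lam, params_bad$x0,
                             params_bad$hn, init2, dt, t_max, tol, 25L)
    states[bad, ] <- res2$steady
    converged[bad] <- res2$converged
    init[bad, ] <- init2
  }
  colnames(states) <- params$genes
  ens <- structure(list(network = net, genes = params$genes, params = params,
                        init = init, states = states,
                        expr = racipe_normalize(states, converged),
                        converged = converged, seed = seed,
                        settings = list(dt = dt, t_max = t_max, tol = tol),
                        kd = NULL),
                   class = "racipe_ensemble")
  nfail <- sum(!converged)
  if (nfail > 0)
    message(sprintf("racipe ensemble: %d/%d models not converged (flagged)",
                    nfail, n_models))
  ens
}

#' Standardize steady states for profile comparison
#'
#' log2-transform, then z-score each gene across (converged) models.
#'
#' @param states Models x genes matrix of positive steady states.
#' @param converged Logical vector; standardization statistics use the
#'   converged rows only (default all).
#' @return Standardized matrix of the same shape.
#' @export
racipe_normalize <- function(states, converged = rep(TRUE, nrow(states))) {
  lg <- log2(states)
  ref <- lg[converged, , drop = FALSE]
  mu <- colMeans(ref)
  sdev <- apply(ref, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  out <- sweep(sweep(lg, 2, mu), 2, sdev, "/")
  colnames(out) <- colnames(states)
  out
}

#' @export
print.racipe_ensemble <- function(x, ...) {
  cat(sprintf("racipe_ensemble: %d models x %d genes (%.1f%% converged)%s\n",
              nrow(x$states), length(x$genes),
              100 * mean(x$converged),
              if (is.null(x$kd)) "" else
                paste0(" [KD: ", paste(x$kd$genes, collapse = "+"), "]")))
  invisible(x)
}

#' Re-simulate an ensemble under gene knockdown
#'
#' For each model of the unperturbed ensemble, the maximum production rate
#' of every knocked-down gene is multiplied by `1 - kd_factor` (default:
#' a 95 percent reduction) and the model is re-integrated with all other
#' parameters and its stored initial condition unchanged, preserving the
#' 1:1 pairing with the unperturbed models.
#'
#' @param ensemble A `racipe_ensemble`.
#' @param genes Character vector of 1 or 2 genes to knock down.
#' @param kd_factor Fractional reduction of the production rate in
#'   `[0, 1]` (default 0.95).
#' @return A new `racipe_ensemble` with the `kd` field set.
#' @export
simulate_knockdown <- function(ensemble, genes, kd_factor = 0.95) {
  stopifnot(length(genes) >= 1, kd_factor >= 0, kd_factor <= 1)
  unknown <- setdiff(genes, ensemble$genes)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  params <- ensemble$params
  params$G[, genes] <- params$G[, genes, drop = FALSE] * (1 - kd_factor)
  ea <- params$edges
  st <- ensemble$settings
  res <- racipe_integrate(ea$src, ea$tgt, ea$sign, params$G, params$K,
                          params$lam, params$x0, params$hn, ensemble$init,
                          st$dt, st$t_max, st$tol, 25L)
  states <- res$steady
  colnames(states) <- params$genes
  structure(list(network = ensemble$network, genes = params$genes,
                 params = params, init = ensemble$init, states = states,
                 expr = racipe_normalize(states, res$converged),
                 converged = res$converged, seed = ensemble$seed,
                 settings = st,
                 kd = list(genes = genes, kd_factor = kd_factor)),
            class = "racipe_ensemble")
}

#' Residuals of the governing equations at the stored steady states
#'
#' Direct evaluation of dY/dt at each model's stored state; useful as a
#' post-hoc convergence check independent of the integrator loop.
#'
#' @param ensemble A `racipe_ensemble`.
#' @return Models x genes matrix of dY/dt values.
#' @export
steady_state_residuals <- function(ensemble) {
  params <- ensemble$params
  ea <- params$edges
  out <- racipe_dydt(ea$src, ea$tgt, ea$sign, params$G, params$K,
                     params$lam, params$x0, params$hn, ensemble$states)
  colnames(out) <- params$genes
  out
}
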