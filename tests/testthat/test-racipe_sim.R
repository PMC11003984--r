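test_that("shifted Hill function hits its analytic landmarks", {
  expect_equal(shifted_hill(0, x0 = 2, n = 3, lambda = 5), 1)
  expect_equal(shifted_hill(2, x0 = 2, n = 3, lambda = 5), (1 + 5) / 2)
  expect_equal(shifted_hill(200, x0 = 2, n = 6, lambda = 4), 4,
               tolerance = 1e-9)
  # inhibitory fold change: range (lambda, 1]
  expect_equal(shifted_hill(0, 1, 2, 0.1), 1)
  expect_gt(shifted_hill(50, 1, 2, 0.1), 0.1)
})

test_that("median Hill threshold matches a brute-force median of G/k", {
  r <- sampling_ranges(g = c(1, 1), k = c(1, 1))
  expect_equal(estimate_median_threshold(r, n_draws = 1e4, seed = 1), 1)

  M <- estimate_median_threshold(sampling_ranges(), n_draws = 1e5, seed = 2)
  set.seed(999)
  oracle <- median(runif(1e6, 1, 100) / runif(1e6, 0.1, 1))
  expect_lt(abs(M - oracle) / oracle, 0.02)

  # scale equivariance in the production range
  M10 <- estimate_median_threshold(sampling_ranges(g = c(10, 1000)),
                                   n_draws = 1e5, seed = 2)
  expect_equal(M10 / M, 10, tolerance = 1e-12)
})

test_that("parameter sampling follows the declared distributions", {
  net <- toggle_network()
  p <- sample_parameters(net, sampling_ranges(), n_models = 1e5, seed = 5)
  freqs <- table(p$hn) / length(p$hn)
  expect_true(all(abs(freqs - 1 / 6) < 0.01))
  expect_true(all(p$lam > 0.01 & p$lam < 1))  # both edges inhibitory
  expect_true(all(p$G > 1 & p$G < 100))
  expect_true(all(p$K > 0.1 & p$K < 1))
  expect_true(all(p$x0 > 0.02 * p$M & p$x0 < 1.98 * p$M))

  p2 <- sample_parameters(net, sampling_ranges(), n_models = 1e5, seed = 5)
  expect_identical(p, p2)
})

test_that("single-model integration solves analytic fixed points", {
  iso <- singleton_network()
  res <- simulate_model(iso, list(G = 40, k = 0.5, n = integer(),
                                  lambda = numeric(), x0 = numeric()),
                        init = 1)
  expect_true(res$converged)
  expect_equal(unname(res$state), 80, tolerance = 1e-2)

  # an activator held at saturation: the lambda+ scaling cancels and the
  # target settles at G/k
  act <- gene_network(c("X", "Y"),
                      data.frame(from = "X", to = "Y", sign = "activation",
                                 provenance = "curated", correlation = 1))
  res <- simulate_model(act, list(G = c(50, 40), k = c(0.5, 0.5),
                                  n = 4, lambda = 20, x0 = 1),
                        init = c(100, 1))
  expect_equal(unname(res$state["Y"]), 80, tolerance = 0.1)
})

test_that("toggle switch is bistable, in agreement with a fixed-point scan", {
  net <- toggle_network()
  p <- toggle_params()
  gk <- p$G[1] / p$k[1]
  # oracle: fixed points of y1 = gk * Hs(gk * Hs(y1)); count sign changes
  # over a dense grid of levels
  f <- function(y1) gk * shifted_hill(gk * shifted_hill(y1, p$x0[1], p$n[1],
                                                        p$lambda[1]),
                                      p$x0[2], p$n[2], p$lambda[2]) - y1
  grid <- seq(1e-3, gk, length.out = 20000)
  signs <- sign(f(grid))
  n_fixed <- sum(diff(signs) != 0)
  expect_identical(n_fixed, 3L)  # two stable states + one saddle

  hi_lo <- simulate_model(net, p, init = c(gk, 1e-2))
  lo_hi <- simulate_model(net, p, init = c(1e-2, gk))
  expect_true(hi_lo$converged && lo_hi$converged)
  expect_gt(hi_lo$state["A"], 10 * hi_lo$state["B"])
  expect_gt(lo_hi$state["B"], 10 * lo_hi$state["A"])
  # the two states are the oracle's outer roots
  roots <- grid[which(diff(signs) != 0)]
  expect_equal(unname(hi_lo$state["A"]), max(roots), tolerance = 0.01)
  expect_equal(unname(lo_hi$state["A"]), min(roots), tolerance = 0.05)
})

test_that("euler steady states agree with an adaptive solver", {
  skip_if_not_installed("deSolve")
  net <- toggle_network()
  set.seed(31)
  for (i in 1:5) {
    p <- list(G = runif(2, 1, 100), k = runif(2, 0.1, 1),
              n = sample(1:6, 2, replace = TRUE),
              lambda = 1 / runif(2, 1, 100), x0 = runif(2, 5, 200))
    init <- runif(2, 0.1, 500)
    mine <- simulate_model(net, p, init)
    rhs <- function(t, y, parms) {
      list(c(p$G[1] * shifted_hill(y[2], p$x0[2], p$n[2], p$lambda[2]) -
               p$k[1] * y[1],
             p$G[2] * shifted_hill(y[1], p$x0[1], p$n[1], p$lambda[1]) -
               p$k[2] * y[2]))
    }
    ode <- deSolve::lsoda(init, c(0, 200), rhs, NULL)
    expect_equal(unname(mine$state), unname(ode[2, 2:3]), tolerance = 0.02)
  }
})

test_that("one-gene ensemble reproduces the unregulated level distribution", {
  net <- singleton_network()
  ens <- simulate_ensemble(net, n_models = 5000, seed = 11)
  expect_true(all(ens$converged))
  set.seed(77)
  oracle <- runif(5000, 1, 100) / runif(5000, 0.1, 1)
  ks <- suppressWarnings(stats::ks.test(ens$states[, 1], oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensembles are reproducible and satisfy the steady-state test", {
  ens <- planted_ensemble()
  ens2 <- simulate_ensemble(ens$network, n_models = 400, seed = 21)
  expect_identical(ens$states, ens2$states)
  expect_identical(ens$converged, ens2$converged)

  expect_true(all(ens$states > 0))
  rel <- abs(steady_state_residuals(ens)) / pmax(ens$states, 1e-12)
  expect_lt(max(rel[ens$converged, ]), 1e-3)
})

test_that("toggle ensemble shows at least two expression clusters", {
  net <- toggle_network()
  ens <- simulate_ensemble(net, n_models = 1000, seed = 3)
  x <- ens$expr[ens$converged, ]
  d <- stats::as.dist(1 - cor(t(x), method = "spearman"))
  hc <- stats::hclust(d, method = "complete")
  sil <- vapply(2:4, function(k) {
    mean(cluster::silhouette(stats::cutree(hc, k), d)[, "sil_width"])
  }, 0)
  expect_gt(max(sil), 0.4)  # a clear multi-cluster structure exists
  cl <- stats::cutree(hc, 2)
  contrast <- x[, 1] - x[, 2]
  expect_gt(abs(mean(contrast[cl == 1]) - mean(contrast[cl == 2])), 1)
})

test_that("knockdowns scale production and preserve pairing", {
  iso <- singleton_network()
  ens <- simulate_ensemble(iso, n_models = 50, seed = 9)
  kd <- simulate_knockdown(ens, "A", kd_factor = 0.95)
  expect_equal(kd$states[, 1], 0.05 * ens$states[, 1], tolerance = 1e-2)

  expect_error(simulate_knockdown(ens, "nope"), "unknown gene")

  # kd_factor 0 -> bitwise identical trajectory
  kd0 <- simulate_knockdown(ens, "A", kd_factor = 0)
  expect_identical(kd0$states, ens$states)

  # KD of a sink gene leaves all other genes unchanged
  chain <- gene_network(c("U", "S"),
                        data.frame(from = "U", to = "S", sign = "activation",
                                   provenance = "curated", correlation = 1))
  ens_c <- simulate_ensemble(chain, n_models = 100, seed = 13)
  kd_s <- simulate_knockdown(ens_c, "S")
  expect_identical(kd_s$states[, "U"], ens_c$states[, "U"])
  expect_true(all(kd_s$states[, "S"] < ens_c$states[, "S"]))
})
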