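# fabricate an ensemble-like object holding given standardized profiles
fake_ensemble <- function(z, genes = colnames(z)) {
  structure(list(states = 2^z, expr = z, genes = genes,
                 converged = rep(TRUE, nrow(z))),
            class = "racipe_ensemble")
}

make_clusters <- function(n_per_class, n_genes, sep, seed = 1) {
  set.seed(seed)
  mu <- rep(c(-sep / 2, sep / 2), each = n_per_class)
  z <- matrix(rnorm(2 * n_per_class * n_genes), 2 * n_per_class, n_genes) +
    mu
  colnames(z) <- sprintf("g%02d", seq_len(n_genes))
  z
}

test_that("ridge mapper separates planted clusters and is deterministic", {
  z <- make_clusters(100, 10, sep = 6)
  ens <- fake_ensemble(z)
  asn <- structure(list(state = factor(rep(c("control", "case"), each = 100),
                                       levels = c("control", "case",
                                                  "unassigned"))),
                   class = "state_assignment")
  mapper <- train_state_mapper(ens, asn, ridge_penalty = 1)
  pred <- predict(mapper, ens)
  expect_gte(mean(as.character(pred) == as.character(asn$state)), 0.99)

  mapper2 <- train_state_mapper(ens, asn, ridge_penalty = 1)
  expect_identical(mapper$coefficients, mapper2$coefficients)

  # shuffled labels -> chance-level training accuracy; with p features and
  # n samples the expected overfit excess is about 0.5 * sqrt(p/n), so use
  # n large enough (2000 x 10) that 0.06 bounds chance plus overfit
  z_big <- make_clusters(1000, 10, sep = 6, seed = 8)
  ens_big <- fake_ensemble(z_big)
  set.seed(12)
  shuffled <- factor(sample(rep(c("control", "case"), each = 1000)),
                     levels = c("control", "case", "unassigned"))
  asn_shuf <- structure(list(state = shuffled), class = "state_assignment")
  m_shuf <- train_state_mapper(ens_big, asn_shuf, ridge_penalty = 1)
  acc <- mean(as.character(predict(m_shuf, ens_big)) ==
                as.character(asn_shuf$state))
  expect_lt(abs(acc - 0.5), 0.06)

  # a class absent from training labels is an error
  asn_one <- asn
  asn_one$state <- factor(rep("control", 200),
                          levels = levels(asn$state))
  expect_error(train_state_mapper(ens, asn_one), "10 assigned")
})

test_that("chi-squared knockdown significance matches the closed form", {
  expect_equal(kd_significance(c(5000, 5000), c(5000, 5000)), 1)

  # closed-form Pearson statistic for (5000,5000) vs (9000,1000)
  obs <- rbind(c(5000, 5000), c(9000, 1000))
  rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
  expd <- outer(rs, cs) / n
  stat <- sum((obs - expd)^2 / expd)
  oracle <- pchisq(stat, df = 1, lower.tail = FALSE)
  p <- kd_significance(c(5000, 5000), c(9000, 1000))
  expect_lt(abs(p - oracle) / max(oracle, 1e-300), 1e-6)

  # a moderate table with a finite p-value
  obs <- rbind(c(520, 480), c(478, 522))
  rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
  stat <- sum((obs - outer(rs, cs) / n)^2 / (outer(rs, cs) / n))
  oracle <- pchisq(stat, df = 1, lower.tail = FALSE)
  expect_lt(abs(kd_significance(obs[1, ], obs[2, ]) - oracle) / oracle,
            1e-6)

  expect_warning(p0 <- kd_significance(c(0, 0), c(10, 20)), "zero margin")
  expect_identical(p0, 1)
})

test_that("knockdown screen preserves pairing and detects planted drivers", {
  fx <- planted_default()
  ens <- planted_ensemble()
  asn <- assign_states(ens, fx$act, fx$expr$labels, n_null = 300, seed = 5)
  mapper <- train_state_mapper(ens, asn)

  # pseudo-knockdown: proportions identical to baseline
  base <- kd_screen(fx$sys$network, ens, mapper,
                    kd_sets = list("TF01"), kd_factor = 0)
  base_pred <- predict(mapper, ens)
  expect_equal(base$m_control,
               mean(base_pred == "control"), tolerance = 1e-12)
  expect_equal(base$chisq_p, 1)

  # knocking down a case-state driver (module B TF) moves models toward
  # control; oracle: the distance/null assignment shows the same shift
  kd_b <- simulate_knockdown(ens, "TF20", 0.95)
  expect_identical(nrow(kd_b$states), nrow(ens$states))
  mapped <- kd_screen(fx$sys$network, ens, mapper, kd_sets = list("TF20"))
  expect_gt(mapped$m_control, base$m_control)
  asn_kd <- assign_states(kd_b, fx$act, fx$expr$labels, n_null = 300,
                          seed = 5)
  p_kd <- state_proportions(asn_kd)
  p_0 <- state_proportions(asn)
  expect_lt(p_kd[["case"]], p_0[["case"]])

  expect_error(kd_screen(fx$sys$network, ens, mapper,
                         kd_sets = list("nope")), "unknown gene")
})

test_that("automatic screen covers singles plus star pairs", {
  fx <- planted_default()
  ens <- planted_ensemble()
  asn <- assign_states(ens, fx$act, fx$expr$labels, n_null = 200, seed = 5)
  mapper <- train_state_mapper(ens, asn)
  small_net <- fx$sys$network
  screen <- kd_screen(small_net, ens, mapper)
  n_tfs <- length(small_net$nodes)
  expect_identical(sum(screen$n_genes == 1), n_tfs)
  expect_equal(sum(screen$n_genes == 2), choose(10, 2))
  destab <- rank_destabilizers(screen)
  expect_identical(destab$rank, seq_len(n_tfs))
  expect_true(all(diff(destab$m_control) <= 0))
})

test_that("PCA projection is anchored on the unperturbed ensemble", {
  set.seed(3)
  x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, sprintf("g%d", 1:6)))
  y <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, sprintf("g%d", 1:6)))
  pr <- project_pca(x, list(kd = y))
  base <- prcomp(x)
  expect_equal(pr$unperturbed, base$x[, 1:2])
  expect_gte(pr$explained_variance[1], pr$explained_variance[2])

  # rigid rotation of the feature space preserves pairwise score distances
  q <- qr.Q(qr(matrix(rnorm(36), 6)))
  xr <- x %*% q; colnames(xr) <- colnames(x)
  pr_rot <- project_pca(xr)
  d0 <- dist(pr$unperturbed); d1 <- dist(pr_rot$unperturbed)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-6)

  expect_error(project_pca(x[, 1, drop = FALSE]), "2 genes")
})
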