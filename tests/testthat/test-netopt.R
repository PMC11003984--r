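# helper: fabricate a state_assignment with given per-state counts
fake_assignment <- function(n_control, n_case, n_unassigned) {
  structure(list(state = factor(rep(c("control", "case", "unassigned"),
                                    c(n_control, n_case, n_unassigned)),
                                levels = c("control", "case", "unassigned"))),
            class = "state_assignment")
}

test_that("a model identical to a sample profile is assigned to its state", {
  fx <- planted_default()
  act_z <- t(apply(fx$act, 1, function(r) (r - mean(r)) / sd(r)))
  # ensemble whose first model is exactly a control sample profile
  ens <- planted_ensemble()
  fake <- ens
  fake$expr[1, ] <- act_z[fake$genes, 1]  # sample 1 is a control sample
  asn <- assign_states(fake, fx$act, fx$expr$labels, n_null = 200, seed = 4)
  expect_identical(as.character(asn$state[1]), "control")
  expect_equal(unname(asn$dmin[1, "control"]), 0)
})

test_that("exchangeable profiles are assigned at most at the nominal rate", {
  fx <- planted_default()
  ens <- planted_ensemble()
  fake <- ens
  set.seed(88)
  n <- sum(fake$converged)
  fake$expr[fake$converged, ] <- matrix(rnorm(n * length(fake$genes)),
                                        n)  # i.i.d. -> exchangeable null
  asn <- assign_states(fake, fx$act, fx$expr$labels, n_null = 1000,
                       alpha = 0.05, seed = 6)
  prop <- state_proportions(asn)
  bound <- 0.05 + 2 / sqrt(1000)
  expect_lte(prop[["control"]], bound)
  expect_lte(prop[["case"]], bound)

  asn2 <- assign_states(fake, fx$act, fx$expr$labels, n_null = 1000,
                        alpha = 0.05, seed = 6)
  expect_identical(asn$state, asn2$state)
})

test_that("state proportions sum to one and drive the accuracy metric", {
  # reference two-state split of an ensemble: 24.43% / 69.15% assigned with
  # 6.62% unassigned gives accuracy 0.934 (the printed percentages carry
  # rounding, so the counts below reproduce them only to ~0.1%)
  asn <- fake_assignment(2443, 6915, 662)
  p <- state_proportions(asn)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(p[["control"]], 0.2443, tolerance = 2e-3)
  expect_equal(p[["case"]], 0.6915, tolerance = 2e-3)
  expect_equal(accuracy(asn), 0.9338, tolerance = 2e-4)

  expect_equal(accuracy(fake_assignment(5, 5, 0)), 1)
  expect_equal(accuracy(fake_assignment(0, 0, 10)), 0)
  expect_equal(accuracy(asn) + p[["unassigned"]], 1)
})

test_that("flexibility follows the mean euclidean proportion shift", {
  u <- c(control = 0.5, case = 0.4, unassigned = 0.1)
  expect_equal(flexibility(u, list(u, u)), 0)
  kd <- c(control = 0.2, case = 0.0, unassigned = 0.8)
  expect_equal(flexibility(u, list(kd)), 0.5)  # 3-4-5 triangle
  kd2 <- c(control = 0.3, case = 0.2, unassigned = 0.5)
  expect_equal(flexibility(u, list(kd2, u)), sqrt(0.08) / 2,
               tolerance = 1e-12)
  expect_error(flexibility(u, list()), "no knockdown")
})

test_that("combined ranking orders candidates and breaks ties as documented", {
  sc <- data.frame(id = c("c1", "c2"), accuracy = c(0.9, 0.8),
                   flexibility = c(0.2, 0.3), n_edges = c(10, 10))
  r <- rank_candidates(sc)
  expect_identical(r$combined_index, c(3L, 3L))
  expect_identical(r$id[1], "c1")  # tie broken by higher accuracy

  sc <- data.frame(id = c("a", "b", "c"), accuracy = c(0.7, 0.9, 0.8),
                   flexibility = c(0.1, 0.3, 0.2), n_edges = c(5, 6, 7))
  r <- rank_candidates(sc)
  expect_identical(r$id[1], "b")  # best on both metrics -> combined 2
  expect_identical(r$combined_index[1], 2L)

  perm <- sc[c(3, 1, 2), ]
  expect_identical(rank_candidates(perm), rank_candidates(sc))
})

test_that("ranking agrees with a brute-force re-sort on random tables", {
  set.seed(55)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    sc <- data.frame(id = sprintf("c%02d", seq_len(n)),
                     accuracy = round(runif(n), 2),
                     flexibility = round(runif(n), 2),
                     n_edges = sample(10:99, n))
    r <- rank_candidates(sc)
    # oracle: explicit position-of-each-candidate computation
    acc_order <- sc$id[order(-sc$accuracy, sc$id)]
    flex_order <- sc$id[order(-sc$flexibility, sc$id)]
    combined <- match(sc$id, acc_order) + match(sc$id, flex_order)
    expect_identical(r$combined_index[match(sc$id, r$id)], combined)
    expect_identical(r$id[1],
                     sc$id[order(combined, -sc$accuracy, sc$n_edges,
                                 sc$id)][1])
  }
})

test_that("identical topologies receive identical stability scores", {
  fx <- planted_default()
  net <- fx$sys$network
  cands <- list(list(id = "one", network = net, activity = fx$act),
                list(id = "two", network = net, activity = fx$act))
  st <- rerank_stability(cands, fx$expr$labels, n_models = 120,
                         n_null = 100, n_repeats = 2, seed = 2)
  expect_identical(st$scores[, 1], st$scores[, 2])
  expect_equal(unname(st$p_values), 1)
  st2 <- rerank_stability(cands, fx$expr$labels, n_models = 120,
                          n_null = 100, n_repeats = 2, seed = 2)
  expect_identical(st$scores, st2$scores)
})

test_that("a planted network consistently outranks a sign-scrambled rival", {
  fx <- planted_default()
  net <- fx$sys$network
  flipped <- net$edges
  flipped$sign <- ifelse(flipped$sign == "activation", "inhibition",
                         "activation")
  flipped$correlation <- -flipped$correlation
  weak <- gene_network(net$nodes, flipped)
  cands <- list(list(id = "planted", network = net, activity = fx$act),
                list(id = "scrambled", network = weak, activity = fx$act))
  st <- rerank_stability(cands, fx$expr$labels, n_models = 150,
                         n_null = 100, n_repeats = 4, seed = 31)
  expect_lt(st$p_values[["scrambled"]], 0.05)
  expect_true(all(st$scores[, "planted"] < st$scores[, "scrambled"]))
})
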