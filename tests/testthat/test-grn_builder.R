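test_that("ranked TF lists combine by top-k union", {
  lists <- list(c("A", "B", "C"), c("C", "D", "E"))
  expect_setequal(combine_tf_lists(lists, 2), c("A", "B", "C", "D"))
  expect_identical(combine_tf_lists(list(c("A", "B"), c("A", "B")), 2),
                   c("A", "B"))
  expect_warning(out <- combine_tf_lists(list(c("A", "B")), 5), "exceeds")
  expect_identical(out, c("A", "B"))
  # restriction to database TFs
  db <- sets_to_db(list(A = sprintf("g%d", 1:8)))
  expect_identical(combine_tf_lists(lists, 2, db), "A")
})

test_that("candidate edges require database support and strong correlation", {
  tfs <- c("A", "B", "C")
  db <- sets_to_db(list(A = c("B", "C"), B = c("A")))
  corr <- matrix(c(1, 0.9, 0.2,
                   0.9, 1, 0.1,
                   0.2, 0.1, 1), 3, 3, dimnames = list(tfs, tfs))
  net <- build_candidate(tfs, db, corr, cutoff = 0.5, min_tfs = 2,
                         min_frac = 0.5)
  expect_identical(net$edges$from, c("A", "B"))
  expect_identical(net$edges$to, c("B", "A"))
  expect_true(all(net$edges$sign == "activation"))

  corr["A", "B"] <- corr["B", "A"] <- -0.9
  net <- build_candidate(tfs, db, corr, cutoff = 0.5, min_tfs = 2,
                         min_frac = 0.5)
  expect_true(all(net$edges$sign == "inhibition"))

  # no db support for C -> C never gains edges even at high correlation
  corr["A", "C"] <- corr["C", "A"] <- 0.95
  net <- build_candidate(tfs, db, corr, cutoff = 0.5, min_tfs = 2,
                         min_frac = 0.5)
  expect_false("C" %in% net$edges$to[net$edges$from == "C"])
})

test_that("largest-component and minimum-size rules discard candidates", {
  # two components of 6 and 4 TFs: largest holds 60% < 80% -> discarded
  tfs <- sprintf("T%02d", 1:10)
  ring <- function(v) data.frame(from = v, to = c(v[-1], v[1]))
  pairs <- rbind(ring(tfs[1:6]), ring(tfs[7:10]))
  db <- sets_to_db(split(pairs$to, pairs$from))
  corr <- matrix(0.9, 10, 10, dimnames = list(tfs, tfs)); diag(corr) <- 1
  expect_null(build_candidate(tfs, db, corr, cutoff = 0.5, min_tfs = 2))

  # one component of 6 on its own passes the 80% rule but can fail min_tfs
  db6 <- sets_to_db(split(ring(tfs[1:6])$to, ring(tfs[1:6])$from))
  expect_null(build_candidate(tfs, db6, corr, cutoff = 0.5, min_tfs = 15))
  net <- build_candidate(tfs, db6, corr, cutoff = 0.5, min_tfs = 6)
  expect_length(net$nodes, 6)
})

test_that("self-loops are excluded unless requested", {
  tfs <- c("A", "B")
  db <- sets_to_db(list(A = c("A", "B"), B = c("A")))
  corr <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(tfs, tfs))
  net <- build_candidate(tfs, db, corr, 0.5, min_tfs = 2, min_frac = 0.5)
  expect_false(any(net$edges$from == net$edges$to))
  net2 <- build_candidate(tfs, db, corr, 0.5, min_tfs = 2, min_frac = 0.5,
                          allow_self_loops = TRUE)
  expect_true(any(net2$edges$from == net2$edges$to))
})

test_that("edge count is monotone non-increasing in the cutoff", {
  fx <- planted_default()
  corr <- activity_spearman(fx$act)
  counts <- vapply(seq(0, 0.9, by = 0.1), function(co) {
    net <- build_candidate(fx$sys$tfs, fx$db, corr, co, min_tfs = 2,
                           min_frac = 0)
    if (is.null(net)) 0L else nrow(net$edges)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("enumeration tags candidates, bounds the grid, and is deterministic", {
  fx <- planted_default()
  lists <- emit_ranked_tf_lists(fx$sys)
  grid_args <- list(binding_grid = c(0.1, 0.2), k_grid = c(15, 20),
                    cutoff_grid = c(0.3, 0.5))
  cands <- do.call(enumerate_candidates,
                   c(list(lists, fx$expr, fx$sys$curated, fx$sys$binding),
                     grid_args))
  expect_lte(length(cands), 8)
  expect_gte(length(cands), 1)
  for (cand in cands) {
    net <- cand$network
    expect_gte(length(net$nodes), 15)
    g <- igraph::graph_from_data_frame(net$edges[c("from", "to")],
                                       vertices = net$nodes)
    expect_equal(igraph::components(g, mode = "weak")$no, 1)
    expect_true(all(c("binding_threshold", "k", "cutoff") %in%
                      names(cand$hyper)))
    expect_identical(rownames(cand$activity), net$nodes)
  }
  # rerun -> identical candidate list
  cands2 <- do.call(enumerate_candidates,
                    c(list(lists, fx$expr, fx$sys$curated, fx$sys$binding),
                      grid_args))
  expect_identical(vapply(cands, `[[`, "", "id"),
                   vapply(cands2, `[[`, "", "id"))
  expect_equal(cands2[[1]]$network, cands[[1]]$network)

  # a cutoff close to 1 leaves nothing that survives the 15-TF rule
  none <- enumerate_candidates(lists, fx$expr, fx$sys$curated,
                               fx$sys$binding, binding_grid = 0.1,
                               k_grid = 20, cutoff_grid = 0.99)
  expect_length(none, 0)
})
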