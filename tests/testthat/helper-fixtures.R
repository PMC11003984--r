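# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# default planted system + derived inputs (the study conditions)
planted_default <- function() memo("sys_default", function() {
  sys <- make_planted_system(seed = 17)
  expr <- emit_expression(sys)
  db <- build_merged_db(sys$curated, sys$binding, 0.1,
                        genes = rownames(expr$expr))
  act <- infer_activity(expr, db, sys$tfs)
  list(sys = sys, expr = expr, db = db, act = act)
})

# small ensemble of the planted network, shared by simulator-level tests
planted_ensemble <- function() memo("ens_default", function() {
  fx <- planted_default()
  simulate_ensemble(fx$sys$network, n_models = 400, seed = 21)
})

# two-gene toggle switch (mutual inhibition)
toggle_network <- function() {
  gene_network(c("A", "B"),
               data.frame(from = c("A", "B"), to = c("B", "A"),
                          sign = "inhibition", provenance = "curated",
                          correlation = c(-1, -1)))
}

# one isolated gene (no edges)
singleton_network <- function() gene_network("A")

# symmetric toggle parameters used with simulate_model
toggle_params <- function(g = 50, k = 0.5, n = 4, lambda = 0.05, x0 = 40) {
  list(G = c(g, g), k = c(k, k), n = c(n, n), lambda = c(lambda, lambda),
       x0 = c(x0, x0))
}
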