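# shared fixtures and a cache so the expensive replicated studies are
# computed once per test run

des22 <- function() testlet_design(c(1, 1, 2, 2))
des45 <- function() testlet_design_blocks(4, 5)

tiny_truth <- function(n = 50, design = testlet_design_blocks(2, 5),
                       sigma2_eta = 0.25, seed = 7) {
  sim_true_params(n, design, sigma2_eta, seed = seed)
}

tiny_data <- function(n = 50, design = testlet_design_blocks(2, 5),
                      seed = 8, ...) {
  sim_responses(tiny_truth(n, design, seed = seed - 1, ...), design,
                "n2plt", seed = seed)
}

# a fully clamped fit: every stored draw equals the initial state
clamped_fit <- function(Y, design, params, model = "n2plt", iter = 300,
                        burnin = 100, seed = 1) {
  fit_testlet(Y, design, model, iter = iter, burnin = burnin, seed = seed,
              identify = FALSE,
              prior = prior_config(sigma2_a = 1, sigma2_b = 1,
                                   update_sigma2 = FALSE),
              inits = list(a = params$a, b = params$b, theta = params$theta,
                           eta = params$eta %||%
                             matrix(0, length(params$theta), design$K)),
              update = list(a = FALSE, b = FALSE, theta = FALSE, eta = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# slow acceptance artefacts, computed lazily and shared across blocks
.acc_cache <- new.env(parent = emptyenv())

acc_recovery <- function() {
  if (is.null(.acc_cache$recovery))
    .acc_cache$recovery <- run_recovery_study(reps = 25, iter = 5000,
                                              burnin = 2500, seed = 424)
  .acc_cache$recovery
}

acc_selection <- function() {
  if (is.null(.acc_cache$selection))
    .acc_cache$selection <- run_selection_study(reps = 10, iter = 5000,
                                                burnin = 2500, seed = 425)
  .acc_cache$selection
}
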