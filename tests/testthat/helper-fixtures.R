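# Shared fixtures: small parameter sets and cached simulations so expensive
# runs are shared between tests within a file.

best_fit_params <- function(T = 100, ...) {
  cr_params(N = 50, M = 30, S = 0.1, sigma = 0.2, k = 0.8, T = T, ...)
}

tiny_params <- function(...) {
  args <- list(N = 8, M = 6, S = 0.1, sigma = 0.2, k = 0.8, T = 30)
  do.call(cr_params, modifyList(args, list(...)))
}

# A deterministic toy series built by hand (3 taxa, 6 times).
toy_series <- function(detect = 1e-4) {
  x <- rbind(
    c(0.60, 0.50, 0.70, 0.60, 0.50, 0.60),
    c(0.39, 0.49, 0.29, 0.40, 0.50, 0.40),
    c(0.01, 0.01, 0.01, 1e-6, 1e-6, 1e-6))
  cr_series(x, detect = detect)
}

# Cache one moderately sized best-fit simulation per test session.
cached_bestfit_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_timeseries(best_fit_params(), seed = 424L)
    sim
  }
})
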