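# shared fixtures: small parameter sets used across test files

# the classic single-environment parameterisation with order-1 numbers
# (D_max = 5, R_max = 5, R_min = 1 => D_eq(1) = 5, K = 2.5)
unit_params <- function(K = 2.5, ...) {
  model_params(R_min = 1, K = K, ...)
}

# random but valid parameter draw for property-style loops
random_params <- function() {
  R_max <- stats::runif(1, 2, 8)
  R_min <- stats::runif(1, 0.2, 0.9 * R_max)
  model_params(
    g_max = 1,
    D_max = stats::runif(1, 1, 8),
    R_max = R_max,
    R_min = R_min,
    repair_slope = stats::runif(1, 0.25, 1),
    K = stats::runif(1, 0.5, 5),
    alpha = sample(c(2, 4, 10), 1),
    delta_t = stats::runif(1, 0, 1)
  )
}

# shared cache so expensive sweeps are computed once per test run
acceptance_cache <- new.env(parent = emptyenv())

constant_sweep_10 <- function() {
  if (is.null(acceptance_cache$constant10)) {
    spec <- sweep_spec(c("constant_1.0", "constant_2.0"),
                       replicates = 10, N = 1000, generations = 1000,
                       master_seed = 48109)
    acceptance_cache$constant10 <- run_sweep(spec)
  }
  acceptance_cache$constant10
}
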