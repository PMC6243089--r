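# shared simulation fixtures, built once per test run
.fx <- new.env(parent = emptyenv())

fx_get <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

fx_model <- function(name, noise_sd = 0)
  fx_get(paste0("m_", name, "_", noise_sd),
         function() p450_fixture(name, noise_sd = noise_sd))

fx_series <- function(name, noise_sd = 0, seed = NULL) {
  key <- paste0("s_", name, "_", noise_sd, "_", seed %||% "x")
  fx_get(key, function()
    simulate_tw_series(fx_model(name, noise_sd), seed = seed))
}

fx_linear <- function(name, noise_sd = 0, seed = NULL) {
  key <- paste0("l_", name, "_", noise_sd, "_", seed %||% "x")
  fx_get(key, function()
    synth_linear_mixture(fx_model(name, noise_sd), seed = seed,
                         noise_sd = noise_sd))
}

# single-component series from one fixture component (2 = low band)
fx_component_series <- function(name, comp = 2) {
  key <- paste0("c_", name, "_", comp)
  fx_get(key, function() {
    cm <- fx_model(name)$components[[comp]]
    simulate_tw_series(mixture_model(
      list(spectral_component(cm$nu_0, cm$ffcf)), noise_sd = 0))
  })
}

fx_analysis <- function(name) {
  fx_get(paste0("a_", name), function()
    analyze_sample(fx_series(name), fx_linear(name)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wt_ffcf_ref <- function() ffcf_params(1.6, 3.0, 20.7, 4.1, t1_lifetime = 16)

expect_rel_error <- function(value, target, tol) {
  expect_true(all(abs(value - target) / abs(target) <= tol),
              label = sprintf("%s within %g%% of %s",
                              paste(signif(value, 4), collapse = "/"),
                              100 * tol,
                              paste(signif(target, 4), collapse = "/")))
}
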