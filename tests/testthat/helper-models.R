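# Shared fixtures: fitted surrogates are expensive, so they are built once
# per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

default_dataset <- function() {
  memo("default_dataset", function() generate_dataset(seed = 1))
}

default_fit <- function() {
  memo("default_fit", function() fit_surrogate(default_dataset(), seed = 1))
}

noiseless_dataset <- function() {
  memo("noiseless_dataset", function() {
    generate_dataset(response_surface_params(noise_sd = 0), seed = 1)
  })
}

noiseless_fit <- function() {
  memo("noiseless_fit", function() {
    fit_surrogate(noiseless_dataset(), seed = 1, epochs = 2000)
  })
}

# surface with equal protocol effects up to epsilon: the protocol factor is
# (numerically) inert, used for inert-factor and null-difference checks
near_inert_protocol_params <- function() {
  response_surface_params(emax_405_580 = 0.8, emax_580_405 = 0.8 - 1e-9,
                          noise_sd = 0)
}

inert_fit <- function() {
  memo("inert_fit", function() {
    fit_surrogate(generate_dataset(near_inert_protocol_params(), seed = 3),
                  seed = 1, epochs = 2000)
  })
}

grid_conditions <- function(dataset) {
  as.data.frame(dataset)[c("concentration_mg_ml", "protocol",
                           "pdt_time_min", "input_power_mw")]
}
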