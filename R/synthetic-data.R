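#' Sequential lighting protocols
#'
#' The two sequential dual-wavelength lighting protocols under study:
#' `"405-580"` (405 nm micelle-degradation phase first, then the 580 nm
#' photoactivation phase) and `"580-405"` (the reverse order). All functions
#' taking a `protocol` argument accept exactly these two labels.
#'
#' @return Character vector of the two protocol labels.
#' @export
#' @examples
#' pdt_protocols()
pdt_protocols <- function() {
  c("405-580", "580-405")
}

check_protocol <- function(protocol) {
  if (!is.character(protocol) || !all(protocol %in% pdt_protocols())) {
    stop_invalid("`protocol` must be one of \"405-580\", \"580-405\"")
  }
  invisible(protocol)
}

#' Convert a transmitter dBm setting to milliwatts
#'
#' The wireless LED transmitter's power setting is programmed in dBm; the
#' delivered input power follows `10^((level + 43) / 10)` mW, i.e. each +1 dBm
#' multiplies the power by `10^0.1` with a fixed +43 dB system offset
#' (calibration: a setting of -13 dBm delivers 1000 mW).
#'
#' @param level Numeric vector of dBm settings.
#' @return Input power in mW.
#' @export
#' @examples
#' dbm_to_milliwatts(-13) # 1000 mW
#' dbm_to_milliwatts(-18:-12)
dbm_to_milliwatts <- function(level) {
  if (!is.numeric(level) || length(level) < 1L || any(!is.finite(level))) {
    stop_invalid("`level` must be finite numeric")
  }
  10^((level + 43) / 10)
}

# the seven transmitter settings used in the factorial design
power_grid_mw <- function() {
  dbm_to_milliwatts(seq(-18, -12))
}

#' Ground-truth response-surface parameters
#'
#' Parameters of the synthetic ground-truth viability surface: a Hill curve
#' in photosensitizer concentration multiplied by a saturating function of
#' light dose (input power x time), with a protocol-specific maximal effect.
#' The 405-580 protocol (release before activation) is the more potent one,
#' so `emax_405_580 > emax_580_405`. Defaults are calibrated so that at
#' 2 mg/mL, 60 min, 400 mW the surface returns ~0.21 viability for 405-580
#' and ~0.45 for 580-405, the simulation endpoints of the study.
#'
#' @param ec50 Concentration of half-maximal effect, mg/mL (> 0).
#' @param hill Hill coefficient (> 0).
#' @param emax_405_580,emax_580_405 Maximal kill fraction per protocol; must
#'   satisfy `0 < emax_580_405 < emax_405_580 <= 1`.
#' @param d50 Light dose (mW min) of half-maximal dose effect (> 0).
#' @param noise_sd Standard deviation of the additive measurement noise on
#'   the viability fraction (>= 0).
#' @return An object of class `response_surface_params`.
#' @export
#' @examples
#' response_surface_params()
response_surface_params <- function(ec50 = 0.8, hill = 2,
                                    emax_405_580 = 0.93,
                                    emax_580_405 = 0.65,
                                    d50 = 500, noise_sd = 0.08) {
  check_number(ec50, "ec50", min = 0, strict = TRUE)
  check_number(hill, "hill", min = 0, strict = TRUE)
  check_number(d50, "d50", min = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(emax_405_580, "emax_405_580")
  check_number(emax_580_405, "emax_580_405")
  if (!(emax_580_405 > 0 && emax_580_405 < emax_405_580 &&
        emax_405_580 <= 1)) {
    stop_invalid("need 0 < emax_580_405 < emax_405_580 <= 1 ",
                 "(the 405-580 protocol is the more potent one)")
  }
  structure(
    list(ec50 = ec50, hill = hill, emax_405_580 = emax_405_580,
         emax_580_405 = emax_580_405, d50 = d50, noise_sd = noise_sd),
    class = "response_surface_params"
  )
}

#' @export
print.response_surface_params <- function(x, ...) {
  cat("Ground-truth viability response surface\n")
  cat(sprintf("  Hill: EC50 = %g mg/mL, h = %g\n", x$ec50, x$hill))
  cat(sprintf("  Emax: 405-580 = %g, 580-405 = %g\n",
              x$emax_405_580, x$emax_580_405))
  cat(sprintf("  light-dose D50 = %g mW min, noise SD = %g\n",
              x$d50, x$noise_sd))
  invisible(x)
}

check_condition <- function(concentration, protocol, pdt_time, input_power,
                            vectorized = FALSE) {
  len <- if (vectorized) NULL else 1L
  check_number(concentration, "concentration", min = 0, len = len)
  check_protocol(protocol)
  check_number(pdt_time, "pdt_time", min = 0, strict = TRUE, len = len)
  check_number(input_power, "input_power", min = 0, strict = TRUE, len = len)
  invisible(NULL)
}

#' Noise-free viability under the ground-truth surface
#'
#' Evaluates the synthetic ground-truth surface
#' \deqn{V = 1 - E_{max}(protocol) \cdot \frac{c^h}{EC_{50}^h + c^h}
#'           \cdot \frac{D}{D_{50} + D}, \qquad D = P \cdot t,}
#' the expected surviving fraction at a treatment condition. `V = 1` exactly
#' at zero concentration, and V is non-increasing in concentration, time and
#' power.
#'
#' @param concentration Photosensitizer-micelle concentration, mg/mL (>= 0).
#' @param protocol One of [pdt_protocols()].
#' @param pdt_time Total PDT irradiation time, minutes (> 0).
#' @param input_power Transmitter input power, mW (> 0).
#' @param params A [response_surface_params()] object.
#' @return Viability fraction in \eqn{[0, 1]} (vectorized over the condition
#'   arguments).
#' @export
#' @examples
#' true_viability(2, "405-580", 60, 400) # ~ 0.215
#' true_viability(2, "580-405", 60, 400) # ~ 0.451
true_viability <- function(concentration, protocol, pdt_time, input_power,
                           params = response_surface_params()) {
  stopifnot(inherits(params, "response_surface_params"))
  check_condition(concentration, protocol, pdt_time, input_power,
                  vectorized = TRUE)
  emax <- ifelse(protocol == "405-580", params$emax_405_580,
                 params$emax_580_405)
  hill_eff <- concentration^params$hill /
    (params$ec50^params$hill + concentration^params$hill)
  hill_eff[concentration == 0] <- 0 # exact no-drug limit
  dose <- input_power * pdt_time
  v <- 1 - emax * hill_eff * dose / (params$d50 + dose)
  pmin(pmax(v, 0), 1)
}

#' Generate the synthetic factorial viability dataset
#'
#' Builds the full factorial treatment grid — 9 concentrations (0.25 to
#' 2.25 mg/mL in 0.25 steps), both sequential protocols, 3 PDT times (20,
#' 40, 60 min) and the 7 transmitter power settings (-18 to -12 dBm,
#' converted to mW) — evaluates the ground-truth surface at each of the
#' 378 conditions, adds Gaussian measurement noise (SD `params$noise_sd`)
#' clipped to \eqn{[0, 1]}, and assigns a seeded uniformly-random 252/126
#' train/validation split. Deterministic given `(params, seed)`.
#'
#' @param params A [response_surface_params()] object.
#' @param seed Integer RNG seed for the noise draws and the split.
#' @return A `viability_dataset`: a data frame with columns
#'   `concentration_mg_ml`, `protocol`, `pdt_time_min`, `input_power_mw`,
#'   `viability`, `split`, carrying the generator `params` and `seed` as
#'   attributes.
#' @export
#' @examples
#' d <- generate_dataset(seed = 1)
#' table(d$split)
generate_dataset <- function(params = response_surface_params(), seed = 1L) {
  stopifnot(inherits(params, "response_surface_params"))
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)

  grid <- expand.grid(
    concentration_mg_ml = seq(0.25, 2.25, by = 0.25),
    protocol = pdt_protocols(),
    pdt_time_min = c(20, 40, 60),
    input_power_mw = power_grid_mw(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  truth <- true_viability(grid$concentration_mg_ml, grid$protocol,
                          grid$pdt_time_min, grid$input_power_mw, params)
  dat <- with_seed(seed, {
    v <- truth + rnorm(n, sd = params$noise_sd)
    split <- sample(rep(c("TRAIN", "VALIDATION"), times = c(252L, n - 252L)))
    data.frame(grid, viability = pmin(pmax(v, 0), 1), split = split,
               stringsAsFactors = FALSE)
  })
  structure(dat, params = params, seed = seed,
            class = c("viability_dataset", "data.frame"))
}

#' @export
print.viability_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic PDT viability dataset: %d records (%d TRAIN / %d VALIDATION), seed %d\n",
    nrow(x), sum(x$split == "TRAIN"), sum(x$split == "VALIDATION"),
    attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read or write a viability dataset as CSV
#'
#' The on-disk format is a plain CSV with header
#' `concentration_mg_ml,protocol,pdt_time_min,input_power_mw,viability,split`;
#' protocols are serialized as `405-580` / `580-405`.
#'
#' @param dataset A `viability_dataset` (or compatible data frame).
#' @param path File path.
#' @return `read_dataset_csv()` returns the data frame; `write_dataset_csv()`
#'   returns `path` invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("concentration_mg_ml", "protocol", "pdt_time_min",
              "input_power_mw", "viability", "split")
  if (!all(needed %in% names(dat))) {
    stop_invalid("dataset CSV must have columns: ",
                 paste(needed, collapse = ", "))
  }
  check_protocol(dat$protocol)
  structure(dat, class = c("viability_dataset", "data.frame"))
}
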