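# Tanh network surrogate: fit quality, prediction contract, importance.

test_that("noiseless fit recovers the true surface (interpolation oracle)", {
  fit <- noiseless_fit()
  d <- noiseless_dataset()
  expect_gte(fit$report$r2_train, 0.99)
  truth <- true_viability(d$concentration_mg_ml, d$protocol, d$pdt_time_min,
                          d$input_power_mw,
                          response_surface_params(noise_sd = 0))
  mae <- mean(abs(predict(fit, d) - truth))
  expect_lte(mae, 0.02)
  # queries at TRAIN grid points sit on the recorded viability
  tr <- d[d$split == "TRAIN", ]
  expect_true(all(abs(predict(fit, tr) - tr$viability) <= 0.05))
})

test_that("default noisy fit generalizes to the validation split", {
  fit <- default_fit()
  expect_gte(fit$report$r2_validation, 0.80)
  expect_lte(fit$report$r2_validation, 0.97)
  expect_lte(fit$report$r2_train, 1)
  expect_gte(fit$report$sse_train, 0)
  expect_identical(fit$report$n_train + fit$report$n_validation, 378L)
})

test_that("a comparable off-the-shelf network reaches similar skill", {
  skip_if_not_installed("nnet")
  d <- default_dataset()
  tr <- d[d$split == "TRAIN", ]
  val <- d[d$split == "VALIDATION", ]
  scale_by <- function(x, ref) (x - mean(ref)) / sd(ref)
  enc <- function(s) data.frame(
    c = scale_by(s$concentration_mg_ml, tr$concentration_mg_ml),
    p = as.numeric(s$protocol == "405-580"),
    t = scale_by(s$pdt_time_min, tr$pdt_time_min),
    w = scale_by(s$input_power_mw, tr$input_power_mw))
  set.seed(1)
  ref <- nnet::nnet(enc(tr), tr$viability, size = 20, linout = TRUE,
                    decay = 0.1, maxit = 2000, trace = FALSE)
  pv <- pmin(pmax(predict(ref, enc(val)), 0), 1)
  r2_ref <- 1 - sum((pv - val$viability)^2) /
    sum((val$viability - mean(val$viability))^2)
  expect_lt(abs(default_fit()$report$r2_validation - r2_ref), 0.05)
})

test_that("predictions are clipped to [0, 1] and reject non-finite input", {
  fit <- default_fit()
  extreme <- expand.grid(concentration_mg_ml = c(0, 5, 50),
                         protocol = pdt_protocols(),
                         pdt_time_min = c(1, 600),
                         input_power_mw = c(1, 5000),
                         stringsAsFactors = FALSE)
  p <- predict(fit, extreme)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict_viability(fit, NA_real_, "405-580", 60, 400))
  expect_error(
    predict(fit, data.frame(concentration_mg_ml = NaN, protocol = "405-580",
                            pdt_time_min = 60, input_power_mw = 400)),
    "non-finite")
})

test_that("fit is reproducible bit-for-bit and degenerate targets are flagged", {
  d <- generate_dataset(seed = 5)
  f1 <- fit_surrogate(d, seed = 2, epochs = 50)
  f2 <- fit_surrogate(d, seed = 2, epochs = 50)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$report, f2$report)
  f3 <- fit_surrogate(d, seed = 3, epochs = 50)
  expect_false(identical(f1$theta, f3$theta))

  const <- d
  const$viability <- 0.5
  fc <- fit_surrogate(const, seed = 1, epochs = 500)
  expect_true(fc$report$r2_undefined)
  expect_true(is.na(fc$report$r2_train))
  expect_lt(fc$report$sse_train, 0.05)
})

test_that("R2 of a perfect predictor is exactly 1", {
  # computed with the same metric the fit report uses
  y <- c(0.2, 0.5, 0.9, 0.4)
  sse <- sum((y - y)^2)
  sst <- sum((y - mean(y))^2)
  expect_identical(1 - sse / sst, 1)
})

test_that("permutation importance ranks concentration first, is seeded", {
  fit <- default_fit()
  d <- default_dataset()
  imp <- factor_importance(fit, d, seed = 1, reps = 20)
  expect_identical(imp$factor[1], "concentration")
  expect_true(all(diff(imp$delta_sse) <= 0))
  imp2 <- factor_importance(fit, d, seed = 1, reps = 20)
  expect_identical(imp, imp2)
  expect_error(factor_importance(fit, d, seed = 1, reps = 0), ">=")
})

test_that("an inert protocol factor has near-zero importance", {
  fit <- inert_fit()
  d <- generate_dataset(near_inert_protocol_params(), seed = 3)
  imp <- factor_importance(fit, d, seed = 1, reps = 20)
  prot <- imp$delta_sse[imp$factor == "protocol"]
  conc <- imp$delta_sse[imp$factor == "concentration"]
  expect_lt(abs(prot), 0.05 * conc)
})

test_that("protocol curves behave like the underlying surface", {
  fit <- default_fit()
  cc <- seq(1, 2.25, by = 0.25)
  pc <- protocol_curve(fit, pdt_time = 60, input_power = 400,
                       concentrations = cc)
  expect_true(all(pc$difference >= 0.1 & pc$difference <= 0.3))
  # near-monotone non-increasing in concentration
  full <- protocol_curve(fit, 60, 400, seq(0.25, 2.25, by = 0.25))
  expect_true(all(diff(full$viability_405_580) <= 0.03))
  expect_true(all(diff(full$viability_580_405) <= 0.03))
  # no-drug limit, up to extrapolation error
  at0 <- protocol_curve(fit, 60, 400, 0)
  expect_true(all(abs(c(at0$viability_405_580, at0$viability_580_405) - 1)
                  <= 0.1))
  expect_error(protocol_curve(fit, 60, 400, numeric(0)), "non-empty")
})

test_that("model JSON round-trips predictions and report", {
  fit <- default_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  d <- default_dataset()
  expect_equal(predict(back, d), predict(fit, d), tolerance = 1e-12)
  expect_equal(back$report$r2_validation, fit$report$r2_validation,
               tolerance = 1e-12)
})
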