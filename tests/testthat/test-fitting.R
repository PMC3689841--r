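test_that("max-normalization has the documented algebraic properties", {
  expect_equal(normalize_profile(c(2, 4, 8, 4)), c(0.25, 0.5, 1, 0.5))
  x <- c(0.3, 2.5, 1.1, 0.2)
  expect_equal(normalize_profile(17 * x), normalize_profile(x))
  expect_equal(normalize_profile(normalize_profile(x)), normalize_profile(x))
  expect_error(normalize_profile(c(0, 0)), "positive")
})

test_that("blot datasets enforce their invariants", {
  expect_error(blot_dataset(c(0, 5, 10), c(1, 2, 3)), "4 time points")
  expect_error(blot_dataset(c(0, 5, 5, 10), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_error(blot_dataset(c(0, 5, 10, 20), c(1, -2, 3, 4)), ">= 0")
})

test_that("SSE objective matches a brute-force residual loop and is order-invariant", {
  m <- base_model()
  data <- generate_blot_dataset(blot_generator_spec("pR2", cv = 0.1,
                                                    seed = 7), m)
  p <- m$params[trafficking_parameter_names()] * 1.5
  sse <- sse_objective(p, data, m)
  # independent recomputation: explicit loop over normalized residuals
  m2 <- m; m2$params[names(p)] <- p
  tc <- simulate_model(m2, t_end = 120, n_out = 241, rtol = 1e-6,
                       atol = 1e-4)
  obs <- evaluate_observable(tc, "pR2")
  sim <- approx(obs$time_min, obs$value, xout = data$time_min)$y
  a <- sim / max(sim); b <- data$intensity / max(data$intensity)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(sse, acc, tolerance = 1e-12, ignore_attr = TRUE)

  # permuting dataset rows leaves the SSE unchanged
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  data_perm <- data
  data_perm$time_min <- data$time_min[perm]
  data_perm$intensity <- data$intensity[perm]
  o <- order(data_perm$time_min)
  data_perm$time_min <- data_perm$time_min[o]
  data_perm$intensity <- data_perm$intensity[o]
  expect_equal(sse_objective(p, data_perm, m), sse, ignore_attr = TRUE)
})

test_that("noise-free self-generated data give a near-zero objective", {
  m <- base_model()
  data <- generate_blot_dataset(blot_generator_spec("pR2", cv = 0), m)
  sse <- sse_objective(m$params[trafficking_parameter_names()], data, m)
  expect_lt(sse, 1e-10)
})

test_that("multistart fitting is deterministic and respects the bounds", {
  m <- base_model()
  data <- generate_blot_dataset(blot_generator_spec("pR2", cv = 0.05,
                                                    seed = 9), m)
  e1 <- fit_multistart(m, data, n_starts = 2, seed = 42)
  e2 <- fit_multistart(m, data, n_starts = 2, seed = 42)
  expect_identical(e1$fits, e2$fits)
  for (p in trafficking_parameter_names()) {
    expect_true(all(e1$fits[[p]] >= 1e-4 - 1e-12))
    expect_true(all(e1$fits[[p]] <= 1e-1 + 1e-12))
  }
})

test_that("fitting refuses more parameters than data points", {
  m <- base_model()
  data <- blot_dataset(c(0, 10, 30, 60), c(0.1, 1, 0.7, 0.3), "pR2")
  expect_error(fit_multistart(m, data, n_starts = 1),
               "more fitted parameters")
  # a four-parameter subset is allowed on four points
  ens <- fit_multistart(m, data, n_starts = 1, seed = 3,
                        fit_params = c("kintb", "krecb", "kdegb", "kdegf"))
  expect_s3_class(ens, "fit_ensemble")
})

test_that("ensemble summaries agree with direct recomputation and aggregate sizes", {
  fits <- data.frame(start = 1:3, kintf = c(1e-3, 2e-3, 4e-3),
                     kintb = c(1e-2, 2e-2, 3e-2), sse = c(1, 2, 3),
                     feasible = 1)
  ens <- structure(list(fits = fits, bounds = c(1e-4, 1e-1),
                        fit_params = c("kintf", "kintb"), n_starts = 3,
                        data_source = "x", observable = "pR2"),
                   class = "fit_ensemble")
  s <- summarize_ensemble(ens)
  expect_equal(s$mean[s$parameter == "kintf"], mean(fits$kintf))
  expect_equal(s$median[s$parameter == "kintb"], median(fits$kintb))
  # singleton ensemble: mean = median = the value
  ens1 <- ens; ens1$fits <- fits[1, ]
  s1 <- summarize_ensemble(ens1)
  expect_equal(s1$mean, s1$median)
  # aggregated "All" summary counts both ensembles
  s_all <- summarize_ensemble(ens, ens1)
  expect_equal(unique(s_all$n), nrow(fits) + 1L)
})
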