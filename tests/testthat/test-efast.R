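test_that("frequency assignment satisfies the interference-avoidance rules", {
  # single parameter: one distinguished frequency, no complementary set
  f1 <- assign_frequencies(1, M = 4, Ns = 257)
  expect_equal(f1$omega_poi, 32)
  expect_length(f1$omega_comp, 0)
  # no complementary frequency's first M harmonics touch the distinguished
  # frequency, for a range of parameter counts
  for (k in c(2, 5, 9, 20)) {
    f <- assign_frequencies(k, M = 4, Ns = 257)
    harmonics <- as.vector(outer(f$omega_comp, 1:4))
    expect_false(f$omega_poi %in% harmonics)
    expect_true(all(harmonics < f$omega_poi))
    expect_length(f$omega_comp, k - 1)
  }
})

test_that("the Nyquist condition is enforced", {
  # Ns = 2*M*omega_max + 1 with omega_max = 8 passes; two fewer samples
  # leave no room for complementary frequencies
  expect_silent(assign_frequencies(3, M = 4, Ns = 65))
  expect_error(assign_frequencies(3, M = 4, Ns = 63), "Ns too small")
  expect_error(assign_frequencies(2, M = 4, Ns = 7), "Nyquist")
})

test_that("search-curve samples stay in range, are near-uniform, and are seeded", {
  rng <- list(a = c(1e-4, 1e-1), b = structure(c(0, 10),
                                              transform = "uniform"))
  d <- efast_design(c("a", "b"), rng, Nr = 2, Ns = 257, seed = 4)
  s1 <- sample_search_curves(d)
  s2 <- sample_search_curves(d)
  expect_identical(s1, s2)
  X <- s1[[1]][[1]]
  expect_true(all(X[, "a"] >= 1e-4 & X[, "a"] <= 1e-1))
  expect_true(all(X[, "b"] >= 0 & X[, "b"] <= 10))
  # untransformed marginal approximately uniform on (0,1)
  u <- (log10(X[, "a"]) - log10(1e-4)) / 3
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  d2 <- efast_design(c("a", "b"), rng, Nr = 2, Ns = 257, seed = 5)
  expect_false(identical(sample_search_curves(d2), s1))
})

test_that("indices match the analytic Ishigami decomposition", {
  a <- 7; b <- 0.1
  rng <- lapply(1:3, function(i) structure(c(-pi, pi),
                                           transform = "uniform"))
  names(rng) <- c("x1", "x2", "x3")
  d <- efast_design(c("x1", "x2", "x3"), rng, Nr = 5, Ns = 257, seed = 2)
  fn <- function(p) sin(p[["x1"]]) + a * sin(p[["x2"]])^2 +
    b * p[["x3"]]^4 * sin(p[["x1"]])
  res <- efast_run(fn, d)
  # closed-form variance decomposition
  D <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  S_true <- c(x1 = 0.5 * (1 + b * pi^4 / 5)^2 / D, x2 = (a^2 / 8) / D,
              x3 = 0)
  for (p in names(S_true))
    expect_lt(abs(res$Si[res$parameter == p] - S_true[[p]]), 0.05)
  # first-order never exceeds total (within estimation tolerance)
  expect_true(all(res$Si <= res$STi + 0.02))
  # x3 acts only through its interaction with x1
  expect_gt(res$STi[res$parameter == "x3"],
            res$Si[res$parameter == "x3"] + 0.1)
})

test_that("a purely additive function shows no interactions", {
  rng <- lapply(1:3, function(i) structure(c(0, 1), transform = "uniform"))
  names(rng) <- c("a", "b", "c")
  d <- efast_design(c("a", "b", "c"), rng, Nr = 3, Ns = 129, seed = 3)
  res <- efast_run(function(p) 2 * p[["a"]] + 5 * p[["b"]] - 3 * p[["c"]], d)
  expect_true(all(res$STi - res$Si < 0.03))
  expect_true(all(res$Si <= res$STi + 0.02))
})

test_that("constant outputs are signaled as undefined", {
  rng <- list(a = structure(c(0, 1), transform = "uniform"))
  d <- efast_design("a", rng, Nr = 1, Ns = 65, seed = 1)
  expect_error(efast_run(function(p) 1.0, d), "constant output")
})

test_that("index estimates are stable under resample doubling", {
  rng <- lapply(1:3, function(i) structure(c(-pi, pi),
                                           transform = "uniform"))
  names(rng) <- c("x1", "x2", "x3")
  fn <- function(p) sin(p[["x1"]]) + 7 * sin(p[["x2"]])^2 +
    0.1 * p[["x3"]]^4 * sin(p[["x1"]])
  r1 <- efast_run(fn, efast_design(names(rng), rng, Nr = 2, Ns = 257,
                                   seed = 6))
  r2 <- efast_run(fn, efast_design(names(rng), rng, Nr = 4, Ns = 257,
                                   seed = 6))
  expect_true(all(abs(r1$Si - r2$Si) < 0.05))
})
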