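test_that("compiled RHS implements mass-action kinetics on a bimolecular toy net", {
  tm <- toy_model(
    species = c("A", "B", "C"),
    components = list(A = c(A = 1), B = c(B = 1), C = c(A = 1, B = 1)),
    reactions = list(toy_rxn(1L, c("A", "B"), "C", "k")),
    params = c(k = 2e-3),
    init = c(A = 10, B = 5, C = 0))
  rhs <- compile_rhs(tm)
  d <- rhs$func(0, tm$init, NULL)[[1]]
  flux <- 2e-3 * 10 * 5
  expect_equal(unname(d), c(-flux, -flux, flux))
})

test_that("reversible first-order pair reaches the closed-form equilibrium", {
  kf <- 0.05; kr <- 0.02
  tm <- toy_model(
    species = c("A", "C"),
    components = list(A = c(A = 1), C = c(A = 1)),
    reactions = list(toy_rxn(1L, "A", "C", "kf", "kr")),
    params = c(kf = kf, kr = kr),
    init = c(A = 1000, C = 0))
  tc <- simulate_model(tm, t_end = 60, n_out = 61)
  final <- tc$mat[nrow(tc$mat), ]
  expect_equal(final[["C"]] / final[["A"]], kf / kr, tolerance = 1e-6)
  # analytic transient: A(t) = A_eq + (A0 - A_eq) exp(-(kf+kr) t)
  A_eq <- 1000 * kr / (kf + kr)
  t_s <- tc$time * 60
  expect_equal(tc$mat[, "A"], A_eq + (1000 - A_eq) * exp(-(kf + kr) * t_s),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("stiff solver matches an independent fixed-step RK4 reference", {
  kf <- 1e-3; kr <- 0.01
  tm <- toy_model(
    species = c("A", "B", "C"),
    components = list(A = c(A = 1), B = c(B = 1), C = c(A = 1, B = 1)),
    reactions = list(toy_rxn(1L, c("A", "B"), "C", "kf", "kr")),
    params = c(kf = kf, kr = kr),
    init = c(A = 100, B = 80, C = 0))
  tc <- simulate_model(tm, t_end = 10, n_out = 11, rtol = 1e-10,
                       atol = 1e-10)
  f <- function(y) {
    v <- kf * y[1] * y[2] - kr * y[3]
    c(-v, -v, v)
  }
  ref <- rk4(f, c(100, 80, 0), t_end = 600, dt = 0.01)
  expect_equal(unname(tc$mat[11, ]), ref, tolerance = 1e-6)
})

test_that("the VEGF-free model is quiescent", {
  m <- base_model()
  ss <- find_prestimulus_steady_state(m)
  # stationary up to the slow endosomal degradation drain
  expect_lt(attr(ss, "residual"), 1e-9 * max(m$init))
  # simulating without ligand leaves every phospho-species at zero
  m0 <- build_network(list(vegf_molecules = 0))
  tc <- simulate_model(m0, t_end = 120)
  phospho <- names(Filter(length, m0$phospho))
  expect_lt(max(tc$mat[, intersect(phospho, colnames(tc$mat))]), 1e-9)
  # and free cytosolic pools do not move
  for (nm in c("Gab1", "Gab2", "PI3K", "Shp2", "Akt"))
    expect_equal(tc$mat[, nm], rep(m0$init[[nm]], nrow(tc$mat)),
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("protein totals are conserved to 1e-6 relative over 120 minutes", {
  expect_lt(conservation_residual(base_tc()), 1e-6)
})

test_that("phosphorylated receptor scales linearly with receptor density", {
  m1 <- build_network(list(init = list(R2_total = 5000)))
  m2 <- build_network(list(init = list(R2_total = 10000)))
  p1 <- evaluate_observable(simulate_model(m1), "pR2")$value
  p2 <- evaluate_observable(simulate_model(m2), "pR2")$value
  sel <- p1 > 0.01 * max(p1)
  expect_true(all(abs(p2[sel] / p1[sel] - 2) < 0.02))
})

test_that("reported observables are robust to halving the solver tolerance", {
  m <- base_model()
  p1 <- max(evaluate_observable(base_tc(), "pAkt")$value)
  p2 <- max(evaluate_observable(simulate_model(m, rtol = 5e-9), "pAkt")$value)
  expect_lt(abs(p1 - p2) / p1, 1e-3)
})

test_that("solver rejects a non-positive horizon", {
  expect_error(simulate_model(base_model(), t_end = 0), "t_end")
})
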