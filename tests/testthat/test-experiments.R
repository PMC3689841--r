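test_that("zero knockdown reproduces the control exactly", {
  m <- base_model()
  sc <- knockdown_scan(m, "Gab1", fractions = c(0, 0.5))
  expect_identical(sc$grid$peak_pAkt[1], sc$control$peak_pAkt)
  expect_equal(sc$grid$pct_change[1], 0)
  expect_error(knockdown_scan(m, "Gab1", fractions = c(0.5, 1)),
               "fractions")
})

test_that("Gab1 knockdown lowers and Gab2 knockdown raises peak Akt phosphorylation", {
  m <- base_model()
  k1 <- knockdown_scan(m, "Gab1", fractions = c(0, 0.9))
  k2 <- knockdown_scan(m, "Gab2", fractions = c(0, 0.9))
  expect_lt(k1$grid$pct_change[2], -20)
  expect_gt(k2$grid$pct_change[2], 5)
})

test_that("degradation scan: factor 1 is the control; slower degradation sustains pR2 and pAkt", {
  m <- base_model()
  sc <- degradation_scan(m, factors = c(0.2, 0.5, 1, 3))
  ctrl_pakt <- evaluate_observable(sc$control$tc, "pAkt")
  row1 <- sc$grid[sc$grid$factor == 1, ]
  expect_identical(row1$peak_pAkt, max(ctrl_pakt$value))
  # monotone: AUC(pR2) decreases as degradation speeds up
  expect_true(all(diff(sc$grid$auc_pR2) < 0))
  # half-maximum duration of pAkt is non-increasing in the rate (up to
  # sub-grid interpolation wiggle at the window edge)
  expect_true(all(diff(sc$grid$hmd_pAkt) <= 0.05))
})

test_that("a degradation-slowing intervention is recoverable from its own data", {
  m <- base_model()
  # emulate a lactacystin experiment: data generated at factor 1/3
  m_slow <- perturb_model(perturb_model(m, "parameter_scale", "kdegf", 1/3),
                          "parameter_scale", "kdegb", 1/3)
  data <- generate_blot_dataset(
    blot_generator_spec("pAkt", cv = 0, time_min = c(0, 5, 10, 20, 30,
                                                     60, 90, 120)),
    m_slow)
  sc <- degradation_scan(m, factors = c(0.2, 1/3, 0.5, 1, 2), data = data)
  expect_equal(sc$grid$factor[which.min(sc$grid$sse)], 1/3)
})

test_that("ratio scans are baseline-anchored, monotone, and mode-agnostic", {
  m <- base_model()
  sc <- ratio_scan(m, "Gab1/Gab2", ratios = c(0.1, 1, 10))
  g <- sc$grid
  expect_equal(g$rel_pAkt[g$ratio == 1], c(1, 1))
  for (md in unique(g$mode)) {
    sub <- g[g$mode == md, ]
    expect_true(all(diff(sub$rel_pAkt[order(sub$ratio)]) >= 0))
  }
  # the ratio matters more than the individual concentrations
  wide <- split(g$rel_pAkt, g$ratio)
  for (w in wide) expect_lt(abs(w[1] - w[2]) / mean(w), 0.10)
})

test_that("titrations reproduce dose timing and density scaling behavior", {
  m <- base_model()
  tt <- titration(m, vegf_doses = c(5, 50, 500),
                  receptor_densities = c(5000, 10000))
  g <- tt$grid
  v <- g[g$vary == "vegf", ]
  # decreasing dose strictly delays the pR2 peak
  expect_true(all(diff(v$ttp_pR2[order(v$value)]) < 0))
  # doubling receptor density doubles the pR2 peak, same timing
  r <- g[g$vary == "receptor", ]
  expect_equal(r$peak_pR2[r$value == 10000] / r$peak_pR2[r$value == 5000],
               2, tolerance = 0.01)
  expect_lt(abs(r$ttp_pR2[r$value == 10000] - r$ttp_pR2[r$value == 5000]),
            0.51)
  # no ligand, no signal
  m0 <- build_network(list(vegf_molecules = 0))
  tc0 <- simulate_model(m0, t_end = 60)
  expect_lt(max(evaluate_observable(tc0, "pR2")$value), 1e-9)
  expect_lt(max(evaluate_observable(tc0, "pAkt")$value), 1e-9)
})

test_that("Gab2 dissociation-rate scan shows the saturating threshold", {
  m <- base_model()
  sc <- gab2_dissociation_scan(m, k2d_values = c(1e-7, 1e-5, 1e-3, 1e-2))
  g <- sc$grid
  # Gab1-associated complexes increase with the dissociation rate
  expect_true(all(diff(g$auc_R2p_Gab1) >= 0))
  # near-zero rate maximizes the Gab2-bound receptor pool
  expect_equal(which.max(g$auc_R2p_Gab2), 1L)
  # saturation: outputs at 1e-3 vs 1e-2 differ by < 2%
  r3 <- g[g$k_2dShp2 == 1e-3, -1]
  r2 <- g[g$k_2dShp2 == 1e-2, -1]
  expect_true(all(abs(r2 - r3) / r3 < 0.02))
})

test_that("low Shp2 shifts flux toward the cytosolic Shp2:Gab2p:PI3Kp product", {
  shares <- vapply(c(1e5, 1e6, 1e7), function(s0) {
    m <- build_network(list(init = list(Shp2 = s0)))
    tc <- simulate_model(m)
    cyt <- auc(evaluate_observable(tc, "Shp2_Gab2_PI3K_cyt"))
    rec <- auc(evaluate_observable(tc, c("R2p_Shcp_Grb2_Gab2p_Shp2",
                                         "iR2p_Shcp_Grb2_Gab2p_Shp2")))
    cyt / (cyt + rec)
  }, numeric(1))
  expect_true(all(diff(shares) < 0))
})

test_that("knockdown dose-responses follow the published shapes", {
  m <- base_model()
  fr <- c(0.3, 0.5, 0.7, 0.8, 0.9, 0.95)
  k1 <- knockdown_scan(m, "Gab1", fr)
  k2 <- knockdown_scan(m, "Gab2", fr)
  # Gab1: response log-linear in residual concentration
  r2_log <- summary(stats::lm(pct_change ~ log10(1 - fraction),
                              data = k1$grid))$r.squared
  # Gab2: response linear in knocked-down fraction
  r2_lin <- summary(stats::lm(pct_change ~ fraction,
                              data = k2$grid))$r.squared
  expect_gt(r2_log, 0.95)
  expect_gt(r2_lin, 0.95)
})
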