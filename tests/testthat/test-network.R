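test_that("base network reproduces the documented structure counts", {
  m <- base_model()
  expect_length(m$reactions, 71L)
  expect_length(kinetic_parameter_names(m), 43L)
  expect_setequal(unique(unlist(lapply(m$components, names))),
                  protein_alphabet())
  expect_length(protein_alphabet(), 14L)
  # every parameter named in reactions has a value and vice versa
  expect_setequal(kinetic_parameter_names(m), names(m$params))
})

test_that("disabling each module removes exactly its reaction span", {
  spans <- c(activation = 5L, gab1 = 5L, gab2 = 5L, akt = 16L,
             trafficking_int_rec = 14L, trafficking_deg = 14L,
             vegf_dissociation = 12L)
  for (tag in names(spans)) {
    m <- build_network(list(modules = setdiff(module_tags(), tag)))
    expect_length(m$reactions, 71L - spans[[tag]])
  }
  # the ligand-disintegration module alone accounts for rows 59-70
  m <- build_network(list(modules = setdiff(module_tags(),
                                            "vegf_dissociation")))
  expect_length(m$reactions, 59L)
})

test_that("Shp2-mediated Gab2 dissociation is 10x the ordinary Shp2 association", {
  p <- default_parameters()
  expect_equal(p[["k_2dShp2"]], 10 * p[["k_2_Shp2"]])
  expect_equal(p[["k_2dShp2"]], 10 * p[["k_1_Shp2"]])
})

test_that("validation passes on the base model and flags corruptions", {
  m <- base_model()
  expect_length(validate_network(m), 0L)

  # undefined rate-constant reference is named in the finding
  m_bad <- m
  m_bad$reactions[[7]]$kf <- "k_nonexistent"
  f <- validate_network(m_bad)
  expect_true(any(grepl("k_nonexistent", f)))
  expect_true(any(grepl(sprintf("reaction %d", m$reactions[[7]]$id), f)))

  # protein-balance violation
  m_bad2 <- m
  m_bad2$reactions[[5]]$products <- "R2p_Shcp_Grb2_Gab2"  # Gab1 -> Gab2 complex
  expect_true(any(grepl("balance", validate_network(m_bad2))))

  # degradation edge skipping the endosome
  m_bad3 <- m
  i <- which(vapply(m$reactions, function(r) r$id == 45L, logical(1)))
  m_bad3$reactions[[i]]$reactants <- "R2"   # surface -> degraded
  expect_true(any(grepl("illegal compartment move",
                        validate_network(m_bad3))))
})

test_that("configuration errors are reported", {
  expect_error(build_network(list(modules = "nonsense")), "unknown module")
  expect_error(build_network(list(params = list(k_bogus = 1))),
               "nonexistent parameter")
  expect_error(build_network(list(init = list(NotAProtein = 1))),
               "nonexistent initial pool")
})

test_that("VEGF dose conversion is linear and matches a unit-analysis hand computation", {
  expect_equal(vegf_dose_to_molecules(0), 0)
  expect_equal(vegf_dose_to_molecules(50) / vegf_dose_to_molecules(5), 10)
  # independent computation: dose [g/L] / MW [g/mol] * N_A * medium volume,
  # medium volume = footprint area (cubic cell) x depth
  dose_g_per_L <- 50e-6
  mw <- 45e3
  area_m2 <- (1e-15)^(2 / 3)          # 1 pL cell, cubic footprint
  vol_L <- area_m2 * 0.010 * 1e3      # 10 mm depth
  expected <- dose_g_per_L / mw * 6.02214076e23 * vol_L
  expect_equal(vegf_dose_to_molecules(50), expected, tolerance = 1e-12)
  expect_error(vegf_dose_to_molecules(10, list(vegf_mw_kda = -1)),
               "positive")
})

test_that("trafficking rows pair each surface complex with its endosomal and degraded forms", {
  m <- base_model()
  intrec <- Filter(function(r) r$tag == "trafficking_int_rec", m$reactions)
  deg <- Filter(function(r) r$tag == "trafficking_deg", m$reactions)
  expect_length(intrec, 14L)
  expect_length(deg, 14L)
  for (r in intrec) {
    expect_true(r$reversible)
    expect_identical(paste0("i", r$reactants), r$products)
  }
  for (r in deg) {
    expect_false(r$reversible)
    expect_identical(sub("^i", "d", r$reactants), r$products)
  }
  # all ligated complexes share the bound-receptor trafficking rates
  bound <- Filter(function(r) r$reactants != "R2", intrec)
  expect_true(all(vapply(bound, function(r) r$kf, "") == "kintb"))
  expect_true(all(vapply(bound, function(r) r$kr, "") == "krecb"))
})
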