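# Shared fixtures: the base model and its 120-min simulation are reused
# across test files (simulation results are deterministic).

base_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_network()
    m
  }
})

base_tc <- local({
  tc <- NULL
  function() {
    if (is.null(tc)) tc <<- simulate_model(base_model())
    tc
  }
})

# Minimal hand-built model for engine fixtures: species are their own
# proteins, one compartment, arbitrary reactions.
toy_model <- function(species, components, reactions, params, init) {
  structure(list(
    species = data.frame(id = species,
                         compartment = rep("cytosol", length(species)),
                         display = species, stringsAsFactors = FALSE),
    components = components,
    phospho = stats::setNames(rep(list(character(0)), length(species)),
                              species),
    reactions = reactions,
    params = params,
    init = init,
    basal = init,
    modules = "activation",
    vegf_molecules = 0), class = "nw_model")
}

toy_rxn <- function(id, reactants, products, kf, kr = NA_character_) {
  list(id = id, tag = "activation", reactants = reactants,
       products = products, kf = kf, kr = kr, reversible = !is.na(kr))
}

# Fixed-step RK4 integrator, used as an independent reference on tiny
# fixtures.
rk4 <- function(f, y0, t_end, dt) {
  y <- y0
  t <- 0
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

gab1_module_kinetics <- function()
  c("k_a_Gab1", "kd_a_Gab1", "k_p_Gab1", "k_1_PI3K", "k_1_Shp2",
    "kd_1_Shp2", "k_PIP2", "kd_PIP2")

gab2_module_kinetics <- function()
  c("k_a_Gab2", "kd_a_Gab2", "k_p_Gab2", "k_2_PI3K", "k_2_Shp2",
    "kd_2_Shp2", "k_2dShp2", "kd_2dShp2")
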