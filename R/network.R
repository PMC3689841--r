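AVOGADRO <- 6.02214076e23

#' Names of the fourteen base proteins/lipids in the reaction alphabet
#'
#' The model tracks VEGF (as covalently pre-dimerized ligand), pre-dimerized
#' VEGFR2, the adaptors Shc and Grb2, the scaffolds Gab1 and Gab2, the
#' enzymes PI3K, Shp2, PTEN, PDK1 and PP2A, the kinase substrate Akt, and
#' the membrane lipids PIP2 and PIP3.
#'
#' @return character vector of length 14.
#' @export
protein_alphabet <- function() {
  c("VEGF", "R2", "Shc", "Grb2", "Gab1", "Gab2", "PI3K", "Shp2",
    "PIP2", "PIP3", "PTEN", "PDK1", "Akt", "PP2A")
}

# Receptor-complex base names, in pathway order.  Each exists in three
# compartments: surface (bare name), internal ("i" prefix), degraded
# ("d" prefix).
receptor_base_names <- function() {
  c("R2",
    "R2p",
    "R2p_Shc",
    "R2p_Shcp",
    "R2p_Shcp_Grb2",
    "R2p_Shcp_Grb2_Gab1",
    "R2p_Shcp_Grb2_Gab1p",
    "R2p_Shcp_Grb2_Gab1p_PI3Kp",
    "R2p_Shcp_Grb2_Gab1p_PI3Kp_PIP2",
    "R2p_Shcp_Grb2_Gab1p_Shp2",
    "R2p_Shcp_Grb2_Gab2",
    "R2p_Shcp_Grb2_Gab2p",
    "R2p_Shcp_Grb2_Gab2p_PI3Kp",
    "R2p_Shcp_Grb2_Gab2p_Shp2")
}

# Component multiset and phospho flags for each receptor-complex base name.
receptor_composition <- function() {
  comp <- list(
    R2                             = c(R2 = 1),
    R2p                            = c(VEGF = 1, R2 = 1),
    R2p_Shc                        = c(VEGF = 1, R2 = 1, Shc = 1),
    R2p_Shcp                       = c(VEGF = 1, R2 = 1, Shc = 1),
    R2p_Shcp_Grb2                  = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1),
    R2p_Shcp_Grb2_Gab1             = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab1 = 1),
    R2p_Shcp_Grb2_Gab1p            = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab1 = 1),
    R2p_Shcp_Grb2_Gab1p_PI3Kp      = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab1 = 1, PI3K = 1),
    R2p_Shcp_Grb2_Gab1p_PI3Kp_PIP2 = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab1 = 1, PI3K = 1, PIP2 = 1),
    R2p_Shcp_Grb2_Gab1p_Shp2       = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab1 = 1, Shp2 = 1),
    R2p_Shcp_Grb2_Gab2             = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab2 = 1),
    R2p_Shcp_Grb2_Gab2p            = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab2 = 1),
    R2p_Shcp_Grb2_Gab2p_PI3Kp      = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab2 = 1, PI3K = 1),
    R2p_Shcp_Grb2_Gab2p_Shp2       = c(VEGF = 1, R2 = 1, Shc = 1, Grb2 = 1, Gab2 = 1, Shp2 = 1))
  flags <- list(
    R2                             = character(0),
    R2p                            = "R2",
    R2p_Shc                        = "R2",
    R2p_Shcp                       = c("R2", "Shc"),
    R2p_Shcp_Grb2                  = c("R2", "Shc"),
    R2p_Shcp_Grb2_Gab1             = c("R2", "Shc"),
    R2p_Shcp_Grb2_Gab1p            = c("R2", "Shc", "Gab1"),
    R2p_Shcp_Grb2_Gab1p_PI3Kp      = c("R2", "Shc", "Gab1", "PI3K"),
    R2p_Shcp_Grb2_Gab1p_PI3Kp_PIP2 = c("R2", "Shc", "Gab1", "PI3K"),
    R2p_Shcp_Grb2_Gab1p_Shp2       = c("R2", "Shc", "Gab1"),
    R2p_Shcp_Grb2_Gab2             = c("R2", "Shc"),
    R2p_Shcp_Grb2_Gab2p            = c("R2", "Shc", "Gab2"),
    R2p_Shcp_Grb2_Gab2p_PI3Kp      = c("R2", "Shc", "Gab2", "PI3K"),
    R2p_Shcp_Grb2_Gab2p_Shp2       = c("R2", "Shc", "Gab2"))
  list(components = comp, phospho = flags)
}

# Cytosolic species: free pools and soluble complexes.
cytosol_composition <- function() {
  list(
    Shc  = c(Shc = 1),  Grb2 = c(Grb2 = 1),
    Gab1 = c(Gab1 = 1), Gab2 = c(Gab2 = 1),
    PI3K = c(PI3K = 1), Shp2 = c(Shp2 = 1),
    PIP2 = c(PIP2 = 1), PIP3 = c(PIP3 = 1),
    PTEN = c(PTEN = 1), PDK1 = c(PDK1 = 1),
    Akt = c(Akt = 1), Akt_p = c(Akt = 1), Akt_pp = c(Akt = 1),
    PP2A = c(PP2A = 1), PP2A_act = c(PP2A = 1),
    PTEN_PIP3       = c(PTEN = 1, PIP3 = 1),
    PDK1_PIP3       = c(PDK1 = 1, PIP3 = 1),
    PDK1_PIP3_Akt   = c(PDK1 = 1, PIP3 = 1, Akt = 1),
    PDK1_PIP3_Aktp  = c(PDK1 = 1, PIP3 = 1, Akt = 1),
    PP2Aa_Aktpp     = c(PP2A = 1, Akt = 1),
    PP2Aa_Aktp      = c(PP2A = 1, Akt = 1),
    Shp2_Gab2p_PI3Kp = c(Shp2 = 1, Gab2 = 1, PI3K = 1))
}

cytosol_phospho <- function() {
  list(Akt_p = "Akt", Akt_pp = c("Akt", "Akt"),
       PDK1_PIP3_Aktp = "Akt", PP2Aa_Aktpp = c("Akt", "Akt"),
       PP2Aa_Aktp = "Akt", Shp2_Gab2p_PI3Kp = c("Gab2", "PI3K"))
}

#' Default kinetic parameters of the base model
#'
#' All first-order rate constants are in 1/s; second-order constants are in
#' 1/((molecules/cell) s).  Association rates were converted from molar
#' units assuming a 1 pL cytosolic volume (1e7 /M/s ~ 1.66e-5, 1e6 /M/s ~
#' 1.66e-6 per molecule per second); the VEGF--VEGFR2 on-rate uses the
#' per-cell medium volume implied by the dose geometry (about 1 nL).
#' The Shp2-mediated Gab2 dissociation rate \code{k_2dShp2} is ten times
#' the ordinary Shp2 association rate with Gab scaffolds (reactions 8/12).
#'
#' @return named numeric vector with 43 entries.
#' @export
default_parameters <- function() {
  p <- c(
    # ligand binding / early activation
    k_on     = 1.66e-8,   # VEGF + R2 (per-cell medium volume basis)
    k_dV     = 1e-3,      # VEGF dissociation, typical ~1e-3 /s
    k_a_Shc  = 1.66e-6,
    k_p_Shc  = 0.1,
    k_a_Grb2 = 1.66e-6,
    kd_a_Grb2 = 0.05,
    # Gab1 module (association shared with Gab2; slower unbinding makes
    # Gab1 recruitment sustained)
    k_a_Gab1  = 1.66e-6,
    kd_a_Gab1 = 0.01,
    k_p_Gab1  = 0.1,
    k_1_PI3K  = 1.66e-6,
    k_1_Shp2  = 1.66e-6,
    kd_1_Shp2 = 0.01,
    k_PIP2    = 1.66e-6,
    kd_PIP2   = 0.1,
    # Gab2 module (PI3K/Shp2 kinetics shared with Gab1 in value)
    k_a_Gab2  = 1.66e-6,
    kd_a_Gab2 = 0.1,      # 10 x Gab1: transient Gab2 binding
    k_p_Gab2  = 0.1,
    k_2_PI3K  = 1.66e-6,
    k_2_Shp2  = 1.66e-6,
    kd_2_Shp2 = 0.01,
    k_2dShp2  = 1.66e-5,  # 10 x k_2_Shp2
    kd_2dShp2 = 1e-8,
    # Akt cascade
    kcat_PIP2 = 0.5,
    k_a_PTEN  = 1.66e-6,
    kd_a_PTEN = 0.1,
    kcat_PTEN = 1,
    k_a_PDK1  = 1.66e-6,
    kd_a_PDK1 = 0.1,
    k_a_Akt   = 1.66e-6,
    kd_a_Akt  = 0.1,
    kcat_Akt  = 1,
    k_fb_PP2A = 1e-7,   # gentle feedback: keeps the pAkt transient unimodal
    k_rev_PP2A = 1e-3,
    k_a_dpAkt = 1.66e-6,
    kd_a_dpAkt = 0.1,
    kcat_dpAkt = 1,
    k_bas_PP2A = 1e-8,
    # trafficking (fitted class; ligated receptors traffic faster)
    kintf = 2e-4,
    kintb = 2e-3,
    krecf = 1.5e-3,
    krecb = 1e-2,
    kdegf = 1e-4,
    kdegb = 1e-3)
  p
}

#' Default basal (pre-stimulus) free-protein concentrations
#'
#' Units: molecules/cell.  Gab1 and Gab2 basal levels are 1e5/cell; Shp2 is
#' 1e6/cell with a PI3K/Shp2 ratio of 0.1.  The VEGFR2 dimer density
#' default is 5000 dimers/cell, within the 1000--10000 range explored by
#' the receptor-density titrations.
#'
#' @return named numeric vector.
#' @export
default_initials <- function() {
  c(R2_total = 5000,
    Shc = 1e5, Grb2 = 1e5,
    Gab1 = 1e5, Gab2 = 1e5,
    PI3K = 1e5, Shp2 = 1e6,
    PIP2 = 5e5, PTEN = 1e5, PDK1 = 1e5,
    Akt = 1e5, PP2A = 1e5)
}

#' Convert a VEGF dose to a per-cell molecule count
#'
#' The culture geometry assumes one cell of volume \code{cell_volume_pl}
#' (default 1 pL) occupying a square footprint of area
#' \eqn{V_{cell}^{2/3}} under a medium column of depth
#' \code{medium_depth_mm} (default 10 mm), so each cell "owns" about 1 nL
#' of medium.  The per-cell ligand count is linear in dose.
#'
#' @param dose_ng_per_ml VEGF dose in ng/ml (>= 0).
#' @param geometry list with \code{cell_volume_pl}, \code{medium_depth_mm}
#'   and \code{vegf_mw_kda} (molar mass, default 45 kDa for the VEGF165
#'   homodimer).
#' @return molecules per cell (numeric).
#' @export
vegf_dose_to_molecules <- function(dose_ng_per_ml,
                                   geometry = default_geometry()) {
  g <- utils::modifyList(default_geometry(), as.list(geometry))
  if (any(dose_ng_per_ml < 0)) stop("dose must be >= 0")
  if (g$cell_volume_pl <= 0 || g$medium_depth_mm <= 0 || g$vegf_mw_kda <= 0)
    stop("geometry values must be positive")
  v_cell_m3 <- g$cell_volume_pl * 1e-15          # 1 pL = 1e-15 m^3
  footprint_m2 <- v_cell_m3^(2 / 3)
  medium_L <- footprint_m2 * (g$medium_depth_mm * 1e-3) * 1e3  # m^3 -> L
  dose_g_per_L <- dose_ng_per_ml * 1e-6
  dose_g_per_L / (g$vegf_mw_kda * 1e3) * AVOGADRO * medium_L
}

#' @rdname vegf_dose_to_molecules
#' @export
default_geometry <- function() {
  list(cell_volume_pl = 1, medium_depth_mm = 10, vegf_mw_kda = 45)
}

#' Per-cell medium volume implied by the dose geometry, in litres
#' @param geometry see \code{\link{vegf_dose_to_molecules}}
#' @export
medium_volume_per_cell <- function(geometry = default_geometry()) {
  g <- utils::modifyList(default_geometry(), as.list(geometry))
  v_cell_m3 <- g$cell_volume_pl * 1e-15
  v_cell_m3^(2 / 3) * (g$medium_depth_mm * 1e-3) * 1e3
}

module_tags <- function() {
  c("activation", "gab1", "gab2", "akt",
    "trafficking_int_rec", "trafficking_deg", "vegf_dissociation")
}

# One numbered reaction record.  reactants/products are species ids with
# unit stoichiometry; kinetic order is at most two.
rxn <- function(id, tag, reactants, products, kf, kr = NA_character_) {
  list(id = id, tag = tag, reactants = reactants, products = products,
       kf = kf, kr = kr, reversible = !is.na(kr))
}

# The full reaction table (71 rows), given the species naming scheme.
reaction_table <- function() {
  rb <- receptor_base_names()
  g1 <- "R2p_Shcp_Grb2_Gab1"
  g2 <- "R2p_Shcp_Grb2_Gab2"
  rx <- list()
  add <- function(...) rx[[length(rx) + 1L]] <<- rxn(...)

  ## 1-4: ligand binding (step autophosphorylation), Shc, Grb2
  add(1L, "activation", c("V", "R2"), "R2p", "k_on")
  add(2L, "activation", c("R2p", "Shc"), "R2p_Shc", "k_a_Shc")
  add(3L, "activation", "R2p_Shc", "R2p_Shcp", "k_p_Shc")
  add(4L, "activation", c("R2p_Shcp", "Grb2"), "R2p_Shcp_Grb2",
      "k_a_Grb2", "kd_a_Grb2")

  ## 5-8, 14: Gab1 recruitment, phosphorylation, PI3K, Shp2, PIP2
  add(5L, "gab1", c("R2p_Shcp_Grb2", "Gab1"), g1, "k_a_Gab1", "kd_a_Gab1")
  add(6L, "gab1", g1, paste0(g1, "p"), "k_p_Gab1")
  add(7L, "gab1", c(paste0(g1, "p"), "PI3K"), paste0(g1, "p_PI3Kp"),
      "k_1_PI3K")
  add(8L, "gab1", c(paste0(g1, "p"), "Shp2"), paste0(g1, "p_Shp2"),
      "k_1_Shp2", "kd_1_Shp2")

  ## 9-13: Gab2 recruitment, phosphorylation, PI3K, Shp2, Shp2-mediated
  ## dissociation (reaction 13)
  add(9L, "gab2", c("R2p_Shcp_Grb2", "Gab2"), g2, "k_a_Gab2", "kd_a_Gab2")
  add(10L, "gab2", g2, paste0(g2, "p"), "k_p_Gab2")
  add(11L, "gab2", c(paste0(g2, "p"), "PI3K"), paste0(g2, "p_PI3Kp"),
      "k_2_PI3K")
  add(12L, "gab2", c(paste0(g2, "p"), "Shp2"), paste0(g2, "p_Shp2"),
      "k_2_Shp2", "kd_2_Shp2")
  add(13L, "gab2", c("Shp2", paste0(g2, "p_PI3Kp")),
      c("R2p_Shcp_Grb2", "Shp2_Gab2p_PI3Kp"), "k_2dShp2", "kd_2dShp2")

  ## 14: PIP2 engagement by the Gab1-bound active PI3K
  add(14L, "gab1", c(paste0(g1, "p_PI3Kp"), "PIP2"),
      paste0(g1, "p_PI3Kp_PIP2"), "k_PIP2", "kd_PIP2")

  ## 15-30: Akt cascade
  add(15L, "akt", paste0(g1, "p_PI3Kp_PIP2"),
      c(paste0(g1, "p_PI3Kp"), "PIP3"), "kcat_PIP2")
  add(16L, "akt", c("PIP3", "PTEN"), "PTEN_PIP3", "k_a_PTEN", "kd_a_PTEN")
  add(17L, "akt", "PTEN_PIP3", c("PTEN", "PIP2"), "kcat_PTEN")
  add(18L, "akt", c("PIP3", "PDK1"), "PDK1_PIP3", "k_a_PDK1", "kd_a_PDK1")
  add(19L, "akt", c("PDK1_PIP3", "Akt"), "PDK1_PIP3_Akt",
      "k_a_Akt", "kd_a_Akt")
  add(20L, "akt", "PDK1_PIP3_Akt", c("PDK1_PIP3", "Akt_p"), "kcat_Akt")
  add(21L, "akt", c("PDK1_PIP3", "Akt_p"), "PDK1_PIP3_Aktp",
      "k_a_Akt", "kd_a_Akt")
  add(22L, "akt", "PDK1_PIP3_Aktp", c("PDK1_PIP3", "Akt_pp"), "kcat_Akt")
  add(23L, "akt", c("Akt_pp", "PP2A"), c("Akt_pp", "PP2A_act"), "k_fb_PP2A")
  add(24L, "akt", "PP2A_act", "PP2A", "k_rev_PP2A")
  add(25L, "akt", c("PP2A_act", "Akt_pp"), "PP2Aa_Aktpp",
      "k_a_dpAkt", "kd_a_dpAkt")
  add(26L, "akt", "PP2Aa_Aktpp", c("PP2A_act", "Akt_p"), "kcat_dpAkt")
  add(27L, "akt", c("PP2A_act", "Akt_p"), "PP2Aa_Aktp",
      "k_a_dpAkt", "kd_a_dpAkt")
  add(28L, "akt", "PP2Aa_Aktp", c("PP2A_act", "Akt"), "kcat_dpAkt")
  add(29L, "akt", c("PP2A", "Akt_pp"), c("PP2A", "Akt_p"), "k_bas_PP2A")
  add(30L, "akt", c("PP2A", "Akt_p"), c("PP2A", "Akt"), "k_bas_PP2A")

  ## 31-44: reversible internalization/recycling, one row per complex
  for (i in seq_along(rb)) {
    kin <- if (rb[i] == "R2") "kintf" else "kintb"
    kre <- if (rb[i] == "R2") "krecf" else "krecb"
    add(30L + i, "trafficking_int_rec", rb[i], paste0("i", rb[i]), kin, kre)
  }
  ## 45-58: irreversible degradation of internalized complexes
  for (i in seq_along(rb)) {
    kdg <- if (rb[i] == "R2") "kdegf" else "kdegb"
    add(44L + i, "trafficking_deg", paste0("i", rb[i]), paste0("d", rb[i]),
        kdg)
  }
  ## 59-70: VEGF dissociation with disintegration of the whole complex
  ## (surface multi-protein ligated complexes; products are the free pools)
  comp <- receptor_composition()$components
  lig <- setdiff(rb, c("R2", "R2p"))
  stopifnot(length(lig) == 12L)
  for (i in seq_along(lig)) {
    parts <- comp[[lig[i]]]
    free <- setdiff(names(parts), c("VEGF", "R2"))
    add(58L + i, "vegf_dissociation", lig[i], c("V", "R2", free), "k_dV")
  }
  ## 71: plain VEGF unbinding from the bare phosphorylated receptor
  add(71L, "activation", "R2p", c("V", "R2"), "k_dV")
  rx
}

# Assemble the species table (id, compartment, display, components,
# phospho flags).
species_table <- function() {
  rc <- receptor_composition()
  rb <- receptor_base_names()
  ids <- character(0); compartment <- character(0)
  components <- list(); phospho <- list(); display <- character(0)

  disp_base <- function(nm) {
    # "R2p_Shcp_Grb2_Gab1p_PI3Kp" -> "R2_p:Shc_p:Grb2:Gab1_p:PI3K_p"
    toks <- strsplit(nm, "_(?=[A-Z])", perl = TRUE)[[1]]
    toks <- sub("p$", "_p", toks)
    toks[toks == "PI3K_p"] <- "PI3K_p"   # keep as-is
    paste(toks, collapse = ":")
  }

  push <- function(id, comp, cmp, flg, disp) {
    ids <<- c(ids, id); compartment <<- c(compartment, comp)
    components[[id]] <<- cmp; phospho[[id]] <<- flg
    display <<- c(display, disp)
  }

  push("V", "medium", c(VEGF = 1), character(0), "VEGF")
  for (nm in rb)
    push(nm, "surface", rc$components[[nm]], rc$phospho[[nm]], disp_base(nm))
  for (nm in rb)
    push(paste0("i", nm), "internal", rc$components[[nm]], rc$phospho[[nm]],
         paste0("i[", disp_base(nm), "]"))
  for (nm in rb)
    push(paste0("d", nm), "degraded", rc$components[[nm]], rc$phospho[[nm]],
         paste0("d[", disp_base(nm), "]"))
  cy <- cytosol_composition(); cyp <- cytosol_phospho()
  for (nm in names(cy))
    push(nm, "cytosol", cy[[nm]],
         if (nm %in% names(cyp)) cyp[[nm]] else character(0),
         gsub("_", ":", nm))

  list(df = data.frame(id = ids, compartment = compartment,
                       display = display, stringsAsFactors = FALSE),
       components = components, phospho = phospho)
}

#' Build the VEGFR2--Gab1/Gab2--Akt reaction network
#'
#' Assembles the declarative network model: species across the medium,
#' surface, internal (early endosome), degraded and cytosol compartments;
#' the 71-reaction mass-action system; the 43 kinetic parameters; and the
#' pre-stimulus initial state with VEGF added as a step at t = 0.
#'
#' @param config optional list with elements
#'   \describe{
#'     \item{modules}{character vector of enabled module tags (default all:
#'       \code{activation}, \code{gab1}, \code{gab2}, \code{akt},
#'       \code{trafficking_int_rec}, \code{trafficking_deg},
#'       \code{vegf_dissociation}).}
#'     \item{params}{named list/vector of kinetic-parameter overrides.}
#'     \item{init}{named list/vector of basal-concentration overrides
#'       (names as in \code{\link{default_initials}}).}
#'     \item{vegf_ng_per_ml}{VEGF dose (default 50 ng/ml); alternatively
#'       \code{vegf_molecules} gives the per-cell count directly.}
#'     \item{geometry}{dose-conversion geometry, see
#'       \code{\link{vegf_dose_to_molecules}}.}
#'     \item{partition_free_receptor}{logical (default TRUE): start the free
#'       receptor split between surface and endosome at the
#'       internalization/recycling balance.}
#'   }
#' @return an object of class \code{nw_model}.
#' @export
build_network <- function(config = list()) {
  cfg <- config
  mods <- cfg$modules %||% module_tags()
  bad <- setdiff(mods, module_tags())
  if (length(bad)) stop("unknown module tag(s): ", paste(bad, collapse = ", "))

  params <- default_parameters()
  if (!is.null(cfg$params)) {
    ov <- unlist(cfg$params)
    unknown <- setdiff(names(ov), names(params))
    if (length(unknown))
      stop("override references nonexistent parameter(s): ",
           paste(unknown, collapse = ", "))
    params[names(ov)] <- ov
  }
  if (any(params < 0)) stop("rate constants must be >= 0")

  basal <- default_initials()
  if (!is.null(cfg$init)) {
    ov <- unlist(cfg$init)
    unknown <- setdiff(names(ov), names(basal))
    if (length(unknown))
      stop("override references nonexistent initial pool(s): ",
           paste(unknown, collapse = ", "))
    basal[names(ov)] <- ov
  }
  if (!is.null(cfg$r2_dimers)) basal[["R2_total"]] <- cfg$r2_dimers

  geometry <- utils::modifyList(default_geometry(),
                                as.list(cfg$geometry %||% list()))
  vegf <- if (!is.null(cfg$vegf_molecules)) cfg$vegf_molecules
          else vegf_dose_to_molecules(cfg$vegf_ng_per_ml %||% 50, geometry)

  sp <- species_table()
  rx <- reaction_table()
  rx <- Filter(function(r) r$tag %in% mods, rx)

  init <- stats::setNames(numeric(nrow(sp$df)), sp$df$id)
  init["V"] <- vegf
  part <- cfg$partition_free_receptor %||% TRUE
  r2tot <- basal[["R2_total"]]
  if (part && all(c("trafficking_int_rec") %in% mods)) {
    fs <- params[["krecf"]] / (params[["kintf"]] + params[["krecf"]])
    init["R2"] <- r2tot * fs
    init["iR2"] <- r2tot * (1 - fs)
  } else {
    init["R2"] <- r2tot
  }
  for (nm in setdiff(names(basal), "R2_total")) init[nm] <- basal[[nm]]

  model <- structure(list(
    species = sp$df,
    components = sp$components,
    phospho = sp$phospho,
    reactions = rx,
    params = params,
    init = init,
    basal = basal,
    modules = mods,
    geometry = geometry,
    vegf_molecules = vegf), class = "nw_model")
  model
}

#' @export
print.nw_model <- function(x, ...) {
  cat("VEGFR2-Gab1/Gab2-Akt network model\n")
  cat(sprintf("  %d species, %d reactions, %d kinetic parameters\n",
              nrow(x$species), length(x$reactions),
              length(kinetic_parameter_names(x))))
  cat("  modules:", paste(x$modules, collapse = ", "), "\n")
  cat(sprintf("  VEGF at t=0: %.3g molecules/cell\n", x$vegf_molecules))
  invisible(x)
}

#' Distinct kinetic-parameter names referenced by the model's reactions
#' @param model an \code{nw_model}
#' @export
kinetic_parameter_names <- function(model) {
  nm <- unlist(lapply(model$reactions, function(r) c(r$kf, r$kr)))
  sort(unique(nm[!is.na(nm)]))
}

#' Validate a network model
#'
#' Checks that every rate-constant reference resolves, that every reaction
#' conserves its protein component multiset (degradation rows move a
#' species between compartments without changing composition), that
#' compartment moves are legal (surface to/from internal; internal to
#' degraded only) and that every reaction has order at most two.
#'
#' @param model an \code{nw_model}
#' @return character vector of findings; empty if the model is valid.
#' @export
validate_network <- function(model) {
  findings <- character(0)
  sp_ids <- model$species$id
  comp_of <- stats::setNames(model$species$compartment, sp_ids)

  sum_components <- function(ids) {
    all <- unlist(lapply(ids, function(id) model$components[[id]]))
    if (is.null(all)) return(numeric(0))
    v <- tapply(all, names(all), sum)
    stats::setNames(as.numeric(v), names(v))
  }

  for (r in model$reactions) {
    lab <- sprintf("reaction %d", r$id)
    for (k in c(r$kf, if (r$reversible) r$kr)) {
      if (!is.na(k) && !(k %in% names(model$params)))
        findings <- c(findings,
                      sprintf("%s: undefined rate constant '%s'", lab, k))
    }
    unknown <- setdiff(c(r$reactants, r$products), sp_ids)
    if (length(unknown)) {
      findings <- c(findings, sprintf("%s: unknown species %s", lab,
                                      paste(unknown, collapse = ", ")))
      next
    }
    # kinetic order is set by the reactant side; disintegration rows may
    # release more than two products
    if (length(r$reactants) > 2L)
      findings <- c(findings, sprintf("%s: kinetic order > 2", lab))
    lhs <- sum_components(r$reactants)
    rhs <- sum_components(r$products)
    lhs <- lhs[sort(names(lhs))]; rhs <- rhs[sort(names(rhs))]
    # PIP2 <-> PIP3 interconversion conserves the lipid pool jointly
    merge_pip <- function(x) {
      pip <- sum(x[c("PIP2", "PIP3")], na.rm = TRUE)
      x <- x[setdiff(names(x), c("PIP2", "PIP3"))]
      if (pip > 0) x["PIP"] <- pip
      x[sort(names(x))]
    }
    if (!identical(merge_pip(lhs), merge_pip(rhs)))
      findings <- c(findings, sprintf("%s: protein balance violated", lab))
    # compartment legality for receptor movement rows
    if (r$tag %in% c("trafficking_int_rec", "trafficking_deg")) {
      from <- comp_of[[r$reactants[1]]]
      to <- comp_of[[r$products[1]]]
      ok <- (r$tag == "trafficking_int_rec" &&
               from == "surface" && to == "internal") ||
            (r$tag == "trafficking_deg" &&
               from == "internal" && to == "degraded")
      if (!ok)
        findings <- c(findings,
                      sprintf("%s: illegal compartment move %s -> %s",
                              lab, from, to))
    }
  }
  findings
}

`%||%` <- function(a, b) if (is.null(a)) b else a
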