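#' Apply a perturbation to a network model
#'
#' @param model an \code{nw_model}
#' @param kind one of \code{initial_concentration_scale},
#'   \code{parameter_scale}, \code{parameter_set_value}
#' @param target parameter or basal-pool name
#' @param value scale factor (> 0 for scales) or absolute value
#' @return the perturbed model (rebuilt, so derived initial conditions
#'   stay consistent)
#' @export
perturb_model <- function(model,
                          kind = c("initial_concentration_scale",
                                   "parameter_scale", "parameter_set_value"),
                          target, value) {
  kind <- match.arg(kind)
  params <- as.list(model$params)
  init <- as.list(model$basal)
  if (kind == "initial_concentration_scale") {
    if (!(target %in% names(init))) stop("unknown initial pool: ", target)
    if (value <= 0 && value != 0) stop("scale factor must be > 0 (or 0)")
    init[[target]] <- init[[target]] * value
  } else if (kind == "parameter_scale") {
    if (!(target %in% names(params))) stop("unknown parameter: ", target)
    if (value <= 0) stop("scale factor must be > 0")
    params[[target]] <- params[[target]] * value
  } else {
    if (!(target %in% names(params))) stop("unknown parameter: ", target)
    params[[target]] <- value
  }
  build_network(list(params = params, init = init,
                     vegf_molecules = model$vegf_molecules,
                     modules = model$modules))
}

scan_result <- function(kind, grid, control) {
  structure(list(kind = kind, grid = grid, control = control),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result '%s' (%d points)\n", x$kind, nrow(x$grid)))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

# Shared simulation settings for all scans so that the control point is
# bit-identical to an unperturbed simulation.
scan_sim <- function(model, t_end = 120)
  simulate_model(model, t_end = t_end, n_out = 241)

#' Simulated siRNA knockdown scan
#'
#' Knockdown of fraction f multiplies the target protein's basal
#' concentration by (1 - f); the model has no protein turnover, so an
#' initial-concentration scale is the natural representation of an siRNA
#' experiment.  Reports the peak of pAkt (maximum over the simulated
#' window) and its percent change versus the unperturbed control.
#'
#' @param model an \code{nw_model}
#' @param target free-protein name (e.g. "Gab1", "Gab2")
#' @param fractions knockdown fractions in [0, 1)
#' @return a \code{scan_result}; grid columns: fraction, peak_pAkt,
#'   pct_change.
#' @export
knockdown_scan <- function(model, target,
                           fractions = c(0, 0.25, 0.5, 0.75, 0.9)) {
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1)")
  ctrl_tc <- scan_sim(model)
  ctrl_peak <- max(evaluate_observable(ctrl_tc, "pAkt")$value)
  rows <- lapply(fractions, function(f) {
    m <- if (f == 0) model else
      perturb_model(model, "initial_concentration_scale", target, 1 - f)
    peak <- max(evaluate_observable(scan_sim(m), "pAkt")$value)
    data.frame(fraction = f, peak_pAkt = peak,
               pct_change = (peak - ctrl_peak) / ctrl_peak * 100)
  })
  scan_result(paste0("knockdown_", target), do.call(rbind, rows),
              list(peak_pAkt = ctrl_peak, tc = ctrl_tc))
}

#' VEGFR2 degradation-rate scan (lactacystin-type intervention)
#'
#' Scales both degradation rate constants (kdegf, kdegb) by each factor;
#' factors below 1 emulate proteasome inhibition.  Reports AUC and peak of
#' pR2 and pAkt and the half-maximum duration of pAkt, plus (optionally)
#' the SSE of the normalized pAkt profile against a measured dataset.
#'
#' @param model an \code{nw_model}
#' @param factors positive scale factors on the degradation rates
#' @param data optional \code{blot_dataset} for the SSE column
#' @return a \code{scan_result}
#' @export
degradation_scan <- function(model, factors = c(0.1, 0.33, 0.5, 1, 2, 5),
                             data = NULL) {
  if (any(factors <= 0)) stop("factors must be > 0")
  ctrl_tc <- scan_sim(model)
  rows <- lapply(factors, function(f) {
    m <- if (f == 1) model else {
      m1 <- perturb_model(model, "parameter_scale", "kdegf", f)
      perturb_model(m1, "parameter_scale", "kdegb", f)
    }
    tc <- if (f == 1) ctrl_tc else scan_sim(m)
    pr2 <- evaluate_observable(tc, "pR2")
    pakt <- evaluate_observable(tc, "pAkt")
    row <- data.frame(factor = f,
                      auc_pR2 = auc(pr2), peak_pR2 = max(pr2$value),
                      auc_pAkt = auc(pakt), peak_pAkt = max(pakt$value),
                      hmd_pAkt = half_max_duration(pakt))
    if (!is.null(data)) {
      sim <- stats::approx(pakt$time_min, pakt$value,
                           xout = data$time_min)$y
      row$sse <- sum((normalize_profile(sim) -
                        normalize_profile(data$intensity))^2)
    }
    row
  })
  scan_result("degradation", do.call(rbind, rows),
              list(tc = ctrl_tc))
}

#' Initial-concentration ratio scan
#'
#' Sweeps the Gab1/Gab2 (or PI3K/Shp2) initial-concentration ratio two
#' ways: varying the numerator at fixed denominator, and varying the
#' denominator at fixed numerator.  Maximum pAkt is reported relative to
#' the unperturbed baseline.
#'
#' @param model an \code{nw_model}
#' @param pair "Gab1/Gab2" or "PI3K/Shp2"
#' @param ratios ratio grid (relative to the baseline ratio)
#' @return a \code{scan_result}; grid columns: ratio, mode ("numerator" or
#'   "denominator"), peak_pAkt, rel_pAkt.
#' @export
ratio_scan <- function(model, pair = c("Gab1/Gab2", "PI3K/Shp2"),
                       ratios = 10^seq(-1, 1, by = 0.5)) {
  pair <- match.arg(pair)
  parts <- strsplit(pair, "/")[[1]]
  num <- parts[1]; den <- parts[2]
  base_ratio <- model$basal[[num]] / model$basal[[den]]
  ctrl_tc <- scan_sim(model)
  ctrl_peak <- max(evaluate_observable(ctrl_tc, "pAkt")$value)
  rows <- list()
  for (mode in c("numerator", "denominator")) {
    for (r in ratios) {
      rel <- r / base_ratio   # factor applied relative to baseline ratio
      m <- if (rel == 1) model
      else if (mode == "numerator")
        perturb_model(model, "initial_concentration_scale", num, rel)
      else
        perturb_model(model, "initial_concentration_scale", den, 1 / rel)
      peak <- if (rel == 1) ctrl_peak else
        max(evaluate_observable(scan_sim(m), "pAkt")$value)
      rows[[length(rows) + 1L]] <-
        data.frame(ratio = r, mode = mode, peak_pAkt = peak,
                   rel_pAkt = peak / ctrl_peak)
    }
  }
  scan_result(paste0("ratio_", gsub("/", "_", pair)),
              do.call(rbind, rows), list(peak_pAkt = ctrl_peak))
}

#' VEGF-dose and receptor-density titration
#'
#' Simulates each VEGF dose (ng/ml) at the model's receptor density, and
#' each receptor density (dimers/cell) at the model's dose, reporting the
#' peak and time-to-peak of pR2 and the peak of pAkt.
#'
#' @param model an \code{nw_model}
#' @param vegf_doses doses in ng/ml (default 5, 50, 500)
#' @param receptor_densities dimers/cell (default 1000, 5000, 10000)
#' @return a \code{scan_result}; grid columns: vary, value, peak_pR2,
#'   ttp_pR2, peak_pAkt.
#' @export
titration <- function(model, vegf_doses = c(5, 50, 500),
                      receptor_densities = c(1000, 5000, 10000)) {
  if (any(vegf_doses < 0) || any(receptor_densities <= 0))
    stop("doses must be >= 0 and densities > 0")
  run <- function(vary, value) {
    cfg <- list(params = as.list(model$params),
                init = as.list(model$basal),
                modules = model$modules,
                geometry = model$geometry)
    if (vary == "vegf") cfg$vegf_ng_per_ml <- value
    else { cfg$vegf_molecules <- model$vegf_molecules
           cfg$init$R2_total <- value }
    tc <- scan_sim(build_network(cfg))
    pr2 <- evaluate_observable(tc, "pR2")
    pakt <- evaluate_observable(tc, "pAkt")
    pm <- peak_metrics(pr2)
    data.frame(vary = vary, value = value, peak_pR2 = pm$peak,
               ttp_pR2 = pm$time_to_peak, peak_pAkt = max(pakt$value))
  }
  grid <- rbind(
    do.call(rbind, lapply(vegf_doses, function(d) run("vegf", d))),
    do.call(rbind, lapply(receptor_densities, function(d)
      run("receptor", d))))
  scan_result("titration", grid, list(model = model))
}

#' Scan of the Shp2-mediated Gab2 dissociation rate
#'
#' Sets \code{k_2dShp2} (the association rate of free Shp2 with the
#' PI3K-loaded Gab2 receptor complex that strips Gab2 off the receptor)
#' to each value and reports the time-integrated responses of the
#' Gab1- and Gab2-bound receptor pools, singly phosphorylated Akt, the
#' inactive receptor-bound Gab2:Shp2 complex, and the cytosolic
#' Shp2:Gab2_p:PI3K_p product.
#'
#' @param model an \code{nw_model}
#' @param k2d_values values of k_2dShp2 in 1/((molecules/cell) s)
#' @return a \code{scan_result}
#' @export
gab2_dissociation_scan <- function(model,
                                   k2d_values = 10^seq(-7, -2, by = 1)) {
  if (any(k2d_values < 0)) stop("values must be >= 0")
  ctrl_tc <- scan_sim(model)
  rows <- lapply(k2d_values, function(v) {
    m <- perturb_model(model, "parameter_set_value", "k_2dShp2", v)
    tc <- scan_sim(m)
    data.frame(k_2dShp2 = v,
               auc_R2p_Gab1 = auc(evaluate_observable(tc, "R2p_Gab1")),
               auc_R2p_Gab2 = auc(evaluate_observable(tc, "R2p_Gab2")),
               auc_Akt_p = auc(evaluate_observable(tc, "Akt_p")),
               auc_Gab2_Shp2_rec = auc(evaluate_observable(
                 tc, c("R2p_Shcp_Grb2_Gab2p_Shp2",
                       "iR2p_Shcp_Grb2_Gab2p_Shp2"))),
               auc_Shp2_Gab2_PI3K_cyt = auc(evaluate_observable(
                 tc, "Shp2_Gab2_PI3K_cyt")))
  })
  scan_result("gab2_dissociation", do.call(rbind, rows),
              list(tc = ctrl_tc))
}

#' One-at-a-time finite-difference local sensitivity
#'
#' Central-difference slope of an observable's peak with respect to a
#' parameter or basal pool, on a log2 scale.
#'
#' @param model an \code{nw_model}
#' @param target parameter or basal-pool name
#' @param observable built-in observable name
#' @param rel half-width of the relative perturbation (default 0.1)
#' @export
local_sensitivity <- function(model, target, observable = "pAkt",
                              rel = 0.1) {
  kind <- if (target %in% names(model$params)) "parameter_scale"
          else "initial_concentration_scale"
  up <- max(evaluate_observable(
    scan_sim(perturb_model(model, kind, target, 1 + rel)),
    observable)$value)
  dn <- max(evaluate_observable(
    scan_sim(perturb_model(model, kind, target, 1 - rel)),
    observable)$value)
  (up - dn) / (log2(1 + rel) - log2(1 - rel))
}
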