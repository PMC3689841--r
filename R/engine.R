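#' Compile a network model to a mass-action rate function
#'
#' Expands the reaction list into elementary unidirectional fluxes
#' (reversible reactions contribute a forward and a reverse flux), binds
#' the current rate constants, and returns a derivative function suitable
#' for \pkg{deSolve} together with the stoichiometry matrix.
#'
#' @param model an \code{nw_model}; \code{\link{validate_network}} must
#'   report no findings.
#' @return list with \code{func(t, y, parms)} (deSolve signature),
#'   \code{stoich} (species x flux matrix), \code{flux_rate} (rate-constant
#'   vector), and index vectors \code{i1}, \code{i2}.
#' @export
compile_rhs <- function(model) {
  findings <- validate_network(model)
  if (length(findings))
    stop("model fails validation: ", paste(findings, collapse = "; "))

  sp <- model$species$id
  idx <- stats::setNames(seq_along(sp), sp)
  k <- numeric(0); i1 <- integer(0); i2 <- integer(0)
  cols <- list()

  add_flux <- function(kname, reac, prod) {
    k <<- c(k, model$params[[kname]])
    i1 <<- c(i1, idx[[reac[1]]])
    i2 <<- c(i2, if (length(reac) > 1L) idx[[reac[2]]] else 0L)
    col <- numeric(length(sp))
    for (s in reac) col[idx[[s]]] <- col[idx[[s]]] - 1
    for (s in prod) col[idx[[s]]] <- col[idx[[s]]] + 1
    cols[[length(cols) + 1L]] <<- col
  }

  for (r in model$reactions) {
    add_flux(r$kf, r$reactants, r$products)
    if (r$reversible) add_flux(r$kr, r$products, r$reactants)
  }
  S <- do.call(cbind, cols)
  rownames(S) <- sp
  has2 <- i2 > 0L
  i2p <- ifelse(has2, i2, 1L)

  func <- function(t, y, parms) {
    v <- k * y[i1]
    v[has2] <- v[has2] * y[i2p[has2]]
    list(as.vector(S %*% v))
  }
  nflux <- length(k)
  nsp <- length(sp)
  jacfunc <- function(t, y, parms) {
    # d(flux)/dy: each flux depends on one or two state variables
    Dv <- matrix(0, nflux, nsp)
    d1 <- k
    d1[has2] <- d1[has2] * y[i2p[has2]]
    Dv[cbind(seq_len(nflux), i1)] <- d1
    w <- which(has2)
    Dv[cbind(w, i2[w])] <- Dv[cbind(w, i2[w])] + k[w] * y[i1[w]]
    S %*% Dv
  }
  list(func = func, jacfunc = jacfunc, stoich = S, flux_rate = k,
       i1 = i1, i2 = i2, species = sp)
}

#' Conserved-moiety weight matrix
#'
#' One row per conserved group: every base protein individually, except
#' that PIP2 and PIP3 (which interconvert) are pooled as "PIP".
#'
#' @param model an \code{nw_model}
#' @return numeric matrix (groups x species).
#' @export
conservation_matrix <- function(model) {
  present <- unique(unlist(lapply(model$components, names)))
  groups <- unique(ifelse(present %in% c("PIP2", "PIP3"), "PIP", present))
  sp <- model$species$id
  W <- matrix(0, length(groups), length(sp),
              dimnames = list(groups, sp))
  for (s in sp) {
    cm <- model$components[[s]]
    for (nm in names(cm)) {
      g <- if (nm %in% c("PIP2", "PIP3")) "PIP" else nm
      W[g, s] <- W[g, s] + cm[[nm]]
    }
  }
  W
}

#' Simulate the model over time
#'
#' Integrates the mass-action ODE system with a stiff solver
#' (\code{deSolve::ode}).  Internal integration is in seconds; the output
#' grid is in minutes.  Output concentrations are checked against the
#' negativity guard and protein conservation.
#'
#' @param model an \code{nw_model}
#' @param t_end horizon in minutes (default 120)
#' @param n_out number of output points (default one per minute)
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-6 molecules/cell)
#' @param method deSolve method (default "lsoda")
#' @param init optional replacement initial state (named as model species)
#' @param check_conservation relative tolerance for the conservation audit
#'   (default 1e-6); set NA to skip
#' @return a \code{time_course} object: list with \code{time} (minutes),
#'   \code{mat} (time x species matrix), \code{species} metadata,
#'   \code{model}, and solver \code{diagnostics}.
#' @export
simulate_model <- function(model, t_end = 120, n_out = t_end + 1,
                           rtol = 1e-8, atol = 1e-6, method = "lsoda",
                           init = NULL, check_conservation = 1e-6) {
  if (t_end <= 0) stop("t_end must be > 0")
  rhs <- compile_rhs(model)
  y0 <- model$init
  if (!is.null(init)) y0[names(init)] <- init
  times_min <- seq(0, t_end, length.out = n_out)
  out <- deSolve::ode(y = y0, times = times_min * 60, func = rhs$func,
                      parms = NULL, method = method, rtol = rtol,
                      atol = atol, maxsteps = 50000,
                      jacfunc = rhs$jacfunc, jactype = "fullusr")
  diag <- attributes(out)
  if (max(out[, "time"]) < t_end * 60 - 1e-9)
    stop(sprintf("solver failed at t = %.2f min",
                 max(out[, "time"]) / 60))
  mat <- out[, -1, drop = FALSE]
  # negativity guard: tiny undershoot is clipped, larger is an error
  if (any(mat < -100 * atol))
    stop("negative concentrations beyond guard (< -100*atol)")
  mat[mat < 0] <- 0

  tc <- structure(list(time = times_min, mat = mat,
                       species = model$species, model = model,
                       diagnostics = list(rtol = rtol, atol = atol,
                                          method = method,
                                          istate = diag$istate)),
                  class = "time_course")

  if (!is.na(check_conservation)) {
    res <- conservation_residual(tc)
    if (res > check_conservation)
      stop(sprintf("protein conservation violated: relative residual %.3g",
                   res))
  }
  tc
}

#' Maximum relative drift of any conserved protein total over a simulation
#' @param tc a \code{time_course}
#' @export
conservation_residual <- function(tc) {
  W <- conservation_matrix(tc$model)
  totals <- tc$mat %*% t(W)             # time x groups
  t0 <- totals[1, ]
  active <- t0 > 0
  if (!any(active)) return(0)
  drift <- sweep(abs(sweep(totals[, active, drop = FALSE], 2,
                           t0[active])), 2, t0[active], "/")
  max(drift)
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time_course: %d species x %d time points (0-%g min)\n",
              ncol(x$mat), length(x$time), max(x$time)))
  invisible(x)
}

#' Pre-stimulus (VEGF-free) quasi-steady state
#'
#' Computes the quiescent state before ligand addition: all signaling
#' complexes at zero, free pools at their basal values, and the free
#' receptor partitioned between the plasma membrane and the endosomal pool
#' at the internalization/recycling balance.  Because first-order
#' degradation without synthesis admits no non-trivial true steady state,
#' the returned state is stationary for every reaction except the slow
#' degradation drain; the residual derivative norm is attached as an
#' attribute and checked against \code{atol_ss}.
#'
#' @param model an \code{nw_model} (VEGF is forced to zero)
#' @param atol_ss acceptable residual on non-degradation derivatives
#'   (molecules/cell/s, default 1e-9 of the largest basal pool)
#' @return named state vector with attributes \code{residual} (max absolute
#'   derivative excluding degradation drains) and \code{degradation_drain}.
#' @export
find_prestimulus_steady_state <- function(model, atol_ss = NULL) {
  y <- model$init
  y["V"] <- 0
  if (is.null(atol_ss)) atol_ss <- 1e-9 * max(y)
  # partition free receptor (the only pre-stimulus trafficking flux)
  r2tot <- y[["R2"]] + y[["iR2"]]
  if ("trafficking_int_rec" %in% model$modules && r2tot > 0) {
    fs <- model$params[["krecf"]] /
      (model$params[["kintf"]] + model$params[["krecf"]])
    y["R2"] <- r2tot * fs
    y["iR2"] <- r2tot * (1 - fs)
  }
  rhs <- compile_rhs(model)
  d <- rhs$func(0, y, NULL)[[1]]
  names(d) <- model$species$id
  drain <- if ("trafficking_deg" %in% model$modules)
    model$params[["kdegf"]] * y[["iR2"]] else 0
  # derivatives net of the degradation drain acting on the endosomal pool
  d_adj <- d
  d_adj["iR2"] <- d_adj["iR2"] + drain
  dn <- setdiff(names(d_adj), grep("^d", model$species$id, value = TRUE))
  resid <- max(abs(d_adj[dn]))
  if (resid > max(atol_ss, 1e-12))
    stop(sprintf("pre-stimulus state not stationary: residual %.3g", resid))
  attr(y, "residual") <- resid
  attr(y, "degradation_drain") <- drain
  y
}
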