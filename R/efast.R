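#' Frequency assignment for an eFAST analysis
#'
#' For the parameter of interest, the distinguished frequency is the
#' largest that keeps its first \code{M} harmonics below the Nyquist limit
#' of an \code{Ns}-point search curve, \eqn{\omega_{max} =
#' \lfloor (Ns-1)/(2M) \rfloor}.  The complementary parameters receive low
#' frequencies at most \eqn{\lfloor \omega_{max}/(2M) \rfloor}, so that no
#' complementary frequency's first \code{M} harmonics collide with the
#' distinguished frequency.
#'
#' @param k number of parameters (>= 1)
#' @param M interference factor (number of harmonics; default 4)
#' @param Ns samples per curve (odd)
#' @return list with \code{omega_poi} (distinguished frequency) and
#'   \code{omega_comp} (frequencies for the k-1 complementary parameters;
#'   empty when k = 1).
#' @export
assign_frequencies <- function(k, M = 4, Ns = 257) {
  if (k < 1) stop("k must be >= 1")
  omega_max <- floor((Ns - 1) / (2 * M))
  if (omega_max < 1)
    stop("Ns too small for requested M (Nyquist condition violated)")
  if (k == 1L)
    return(list(omega_poi = omega_max, omega_comp = integer(0)))
  omega_c_max <- floor(omega_max / (2 * M))
  if (omega_c_max < 1)
    stop("Ns too small for requested M and k (no room for complementary ",
         "frequencies below the interference limit)")
  # favour the largest admissible complementary frequencies: they give
  # better space-filling search curves, hence steadier total-variance
  # estimates per curve
  omega_comp <- rep(rev(seq_len(omega_c_max)), length.out = k - 1L)
  list(omega_poi = omega_max, omega_comp = omega_comp)
}

#' Construct an eFAST sampling design
#'
#' @param parameters character vector of parameter names (the dummy, if
#'   wanted, must be included explicitly by the caller or via
#'   \code{\link{efast_on_model}})
#' @param ranges named list of length-2 ranges; each may carry
#'   \code{attr(.,"transform") = "uniform"} to sample arithmetically
#'   (default is log-uniform, appropriate for positive rate constants)
#' @param Nr resample (search-curve) count, default 5
#' @param Ns samples per curve (odd), default 257
#' @param M interference factor, default 4
#' @param seed integer seed for the random phase shifts
#' @return an \code{efast_design}
#' @export
efast_design <- function(parameters, ranges, Nr = 5, Ns = 257, M = 4,
                         seed = 1) {
  if (Ns %% 2 == 0) stop("Ns must be odd")
  missing_r <- setdiff(parameters, names(ranges))
  if (length(missing_r))
    stop("no range for parameter(s): ", paste(missing_r, collapse = ", "))
  freq <- assign_frequencies(length(parameters), M, Ns)
  structure(list(parameters = parameters, ranges = ranges[parameters],
                 Nr = Nr, Ns = Ns, M = M, seed = seed,
                 omega_poi = freq$omega_poi,
                 omega_comp = freq$omega_comp),
            class = "efast_design")
}

# The s-grid of an Ns-point search curve, symmetric in (-pi, pi).
efast_sgrid <- function(Ns) pi * (2 * seq_len(Ns) - 1 - Ns) / Ns

#' Sample the eFAST search curves
#'
#' For each parameter of interest and each resample, all parameters are
#' varied simultaneously along the sinusoidal search curve
#' \eqn{x(s) = 1/2 + (1/\pi) \arcsin(\sin(\omega s + \phi))} with a random
#' phase \eqn{\phi}, and mapped through each parameter's range transform.
#'
#' @param design an \code{\link{efast_design}}
#' @return nested list \code{samples[[poi]][[resample]]}: an Ns x k matrix
#'   of parameter values (columns named by parameter).
#' @export
sample_search_curves <- function(design) {
  k <- length(design$parameters)
  s <- efast_sgrid(design$Ns)
  phases <- with_seed(design$seed, {
    lapply(seq_len(k), function(i)
      lapply(seq_len(design$Nr), function(r) stats::runif(k, 0, 2 * pi)))
  })
  transform_one <- function(x, range) {
    tr <- attr(range, "transform") %||% "log"
    if (tr == "uniform") range[1] + x * (range[2] - range[1])
    else {
      if (any(range <= 0)) stop("log-transformed range must be positive")
      10^(log10(range[1]) + x * (log10(range[2]) - log10(range[1])))
    }
  }
  lapply(seq_len(k), function(i) {
    omega <- numeric(k)
    omega[i] <- design$omega_poi
    omega[-i] <- design$omega_comp
    lapply(seq_len(design$Nr), function(r) {
      phi <- phases[[i]][[r]]
      X <- vapply(seq_len(k), function(p) {
        x <- 0.5 + (1 / pi) * asin(sin(omega[p] * s + phi[p]))
        transform_one(x, design$ranges[[p]])
      }, numeric(design$Ns))
      colnames(X) <- design$parameters
      X
    })
  })
}

# Spectral decomposition of one output curve: returns total variance D,
# variance at the distinguished frequency's first M harmonics, and the
# low-frequency (complementary) variance.
efast_spectrum <- function(y, design) {
  Ns <- design$Ns
  s <- efast_sgrid(Ns)
  pmax <- (Ns - 1) %/% 2
  p <- seq_len(pmax)
  A <- as.vector(crossprod(y, cos(outer(s, p)))) / Ns
  B <- as.vector(crossprod(y, sin(outer(s, p)))) / Ns
  lambda <- A^2 + B^2
  D <- 2 * sum(lambda)
  harmonics <- design$omega_poi * seq_len(design$M)
  D_poi <- 2 * sum(lambda[harmonics])
  cutoff <- design$omega_poi %/% 2
  D_comp <- 2 * sum(lambda[seq_len(cutoff)])
  list(D = D, D_poi = D_poi, D_comp = D_comp)
}

#' First-order and total sensitivity indices from sampled outputs
#'
#' The first-order index Si of the parameter of interest is the output
#' variance at its distinguished frequency and its first M harmonics,
#' divided by total variance; the total index STi is one minus the
#' variance fraction in the low-frequency band attributed to the
#' complementary set.  Both are averaged over the Nr resample curves.
#'
#' @param outputs nested list \code{outputs[[poi]][[resample]]}: numeric
#'   vector of length Ns (one model output per sample), matching
#'   \code{\link{sample_search_curves}}
#' @param design an \code{\link{efast_design}}
#' @param output_name label for the result rows
#' @return data.frame with columns parameter, output, Si, STi, Si_sd,
#'   STi_sd.
#' @export
efast_indices <- function(outputs, design, output_name = "y") {
  k <- length(design$parameters)
  rows <- lapply(seq_len(k), function(i) {
    si <- sti <- numeric(design$Nr)
    for (r in seq_len(design$Nr)) {
      y <- outputs[[i]][[r]]
      if (any(!is.finite(y))) stop("non-finite output in eFAST sample")
      sp <- efast_spectrum(y, design)
      if (sp$D <= 1e-12 * (1 + mean(y)^2))
        stop("constant output: sensitivity indices are undefined")
      si[r] <- sp$D_poi / sp$D
      sti[r] <- 1 - sp$D_comp / sp$D
    }
    data.frame(parameter = design$parameters[i], output = output_name,
               Si = mean(si), STi = mean(sti),
               Si_sd = stats::sd(si), STi_sd = stats::sd(sti))
  })
  structure(do.call(rbind, rows), class = c("efast_result", "data.frame"))
}

#' Run eFAST on an arbitrary function
#'
#' Convenience wrapper: samples the search curves, evaluates \code{fn} on
#' every row, and computes the indices.
#'
#' @param fn function taking a named numeric vector of parameters and
#'   returning a scalar
#' @param design an \code{\link{efast_design}}
#' @export
efast_run <- function(fn, design) {
  samples <- sample_search_curves(design)
  outputs <- lapply(samples, function(per_poi)
    lapply(per_poi, function(X)
      apply(X, 1, function(row) fn(stats::setNames(row, colnames(X))))))
  efast_indices(outputs, design)
}

#' eFAST global sensitivity analysis of the signaling model
#'
#' Perturbs a subset of kinetic parameters and/or initial concentrations
#' (plus a dummy parameter that is sampled but never passed to the model)
#' along eFAST search curves, simulates each sample, and computes
#' sensitivity indices of time-integrated (AUC) observables.
#'
#' @param model an \code{nw_model}
#' @param parameters character vector of kinetic-parameter names and/or
#'   basal-pool names (as in \code{\link{default_initials}})
#' @param ranges named list of length-2 ranges; defaults to one order of
#'   magnitude either side of each nominal value, sampled log-uniformly
#' @param observables character vector of built-in observable names
#'   (default: the Gab-complex aggregates and pAkt), or a named list of
#'   member-species vectors for custom aggregates
#' @param Nr,Ns,M,seed passed to \code{\link{efast_design}}
#' @param include_dummy append the aliasing-floor dummy parameter
#'   (default TRUE)
#' @param t_end,n_out simulation grid for the AUC outputs
#' @param max_invalid_frac abort if more than this fraction of samples
#'   fails to simulate (default 0.01); failed samples otherwise take the
#'   median output of their curve
#' @return an \code{efast_result} data.frame covering every
#'   (parameter, output) pair.
#' @export
efast_on_model <- function(model, parameters, ranges = NULL,
                           observables = c("R2p_Gab1", "R2p_Gab2", "pAkt"),
                           Nr = 2, Ns = 65, M = 4, seed = 1,
                           include_dummy = TRUE, t_end = 120, n_out = 61,
                           max_invalid_frac = 0.01) {
  nominal <- c(model$params, model$basal)
  unknown <- setdiff(parameters, names(nominal))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  if (is.null(ranges))
    ranges <- stats::setNames(lapply(parameters, function(p)
      nominal[[p]] * c(0.1, 10)), parameters)
  pars <- parameters
  if (include_dummy) {
    pars <- c(pars, "dummy")
    ranges$dummy <- c(0.1, 10)
  }
  design <- efast_design(pars, ranges, Nr = Nr, Ns = Ns, M = M, seed = seed)
  samples <- sample_search_curves(design)

  if (!is.list(observables))
    observables <- stats::setNames(as.list(observables), observables)
  obs_names <- names(observables)

  is_init <- parameters %in% names(model$basal) &
    !(parameters %in% names(model$params))
  run_one <- function(vals) {
    m <- model
    kin <- parameters[!is_init]
    ini <- parameters[is_init]
    m$params[kin] <- vals[kin]
    if (length(ini)) {
      cfg <- list(params = as.list(m$params),
                  init = as.list(vals[ini]),
                  vegf_molecules = model$vegf_molecules,
                  modules = model$modules)
      m <- build_network(cfg)
    }
    tc <- simulate_model(m, t_end = t_end, n_out = n_out,
                         rtol = 1e-6, atol = 1e-4)
    vapply(obs_names, function(o)
      auc(evaluate_observable(tc, observables[[o]])), numeric(1))
  }

  n_total <- 0L; n_invalid <- 0L
  outputs <- lapply(samples, function(per_poi) lapply(per_poi, function(X) {
    Y <- matrix(NA_real_, nrow(X), length(obs_names),
                dimnames = list(NULL, obs_names))
    for (j in seq_len(nrow(X))) {
      n_total <<- n_total + 1L
      res <- tryCatch(run_one(X[j, ]), error = function(e) NULL)
      if (is.null(res)) n_invalid <<- n_invalid + 1L else Y[j, ] <- res
    }
    Y
  }))
  if (n_invalid > max_invalid_frac * n_total)
    stop(sprintf("%d/%d samples failed to simulate", n_invalid, n_total))

  res <- lapply(obs_names, function(o) {
    out_o <- lapply(outputs, function(per_poi) lapply(per_poi, function(Y) {
      y <- Y[, o]
      if (anyNA(y)) y[is.na(y)] <- stats::median(y, na.rm = TRUE)
      y
    }))
    efast_indices(out_o, design, output_name = o)
  })
  out <- do.call(rbind, res)
  class(out) <- c("efast_result", "data.frame")
  attr(out, "design") <- design
  out
}
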