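#' The six trafficking parameter names
#' @export
trafficking_parameter_names <- function() {
  c("kintf", "kintb", "krecf", "krecb", "kdegf", "kdegb")
}

#' Normalize an intensity series to its maximum
#'
#' Densitometry series are relative; both simulated and measured profiles
#' are divided by their own maxima before comparison, so the objective is
#' invariant to the arbitrary blot intensity scale.
#'
#' @param values numeric series with at least one positive entry
#' @return series scaled so its maximum is 1
#' @export
normalize_profile <- function(values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0) stop("series has no positive value")
  values / m
}

#' Construct a blot dataset
#'
#' A semi-quantitative phospho-protein time course: strictly increasing
#' time points (minutes), non-negative relative intensities on an
#' arbitrary scale, and the observable the blot detects.
#'
#' @param time_min time points (>= 4, strictly increasing)
#' @param intensity relative intensities (>= 0)
#' @param observable "pR2" or "pAkt" (any built-in observable is accepted)
#' @param source free-text label
#' @export
blot_dataset <- function(time_min, intensity, observable = "pR2",
                         source = "synthetic") {
  if (length(time_min) < 4L) stop("need at least 4 time points")
  if (any(diff(time_min) <= 0)) stop("time points must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (length(time_min) != length(intensity))
    stop("time and intensity lengths differ")
  structure(list(time_min = time_min, intensity = intensity,
                 observable = observable, source = source),
            class = "blot_dataset")
}

#' @export
print.blot_dataset <- function(x, ...) {
  cat(sprintf("blot_dataset '%s' (%s): %d points over %g-%g min\n",
              x$source, x$observable, length(x$time_min),
              min(x$time_min), max(x$time_min)))
  invisible(x)
}

# Simulate with a given trafficking-parameter set and evaluate the
# dataset's observable at the dataset's time points.
simulate_at_params <- function(model, params, data, rtol = 1e-6,
                               atol = 1e-4) {
  model$params[names(params)] <- params
  t_end <- max(data$time_min, 120)
  tc <- simulate_model(model, t_end = t_end, n_out = 241,
                       rtol = rtol, atol = atol)
  obs <- evaluate_observable(tc, data$observable)
  stats::approx(obs$time_min, obs$value, xout = data$time_min)$y
}

#' Sum-of-squares objective for trafficking parameters
#'
#' Simulates the model with the candidate trafficking parameters and
#' returns the sum of squared differences between the max-normalized
#' simulated profile (sampled at the dataset's time points) and the
#' max-normalized dataset.
#'
#' @param params named trafficking parameters (within bounds)
#' @param data a \code{blot_dataset}
#' @param model an \code{nw_model}
#' @return scalar SSE; \code{Inf} (with attribute \code{failed}) if the
#'   solver fails at these parameters.
#' @export
sse_objective <- function(params, data, model) {
  sim <- tryCatch(simulate_at_params(model, params, data),
                  error = function(e) NULL)
  if (is.null(sim) || any(!is.finite(sim)) || max(sim) <= 0)
    return(structure(Inf, failed = TRUE))
  r <- normalize_profile(sim) - normalize_profile(data$intensity)
  sum(r^2)
}

#' Multi-start bounded least-squares fit of the trafficking parameters
#'
#' For each start, initial values are drawn log-uniformly within the
#' bounds, and a bounded Levenberg--Marquardt refinement
#' (\code{minpack.lm::nls.lm} on log10-transformed parameters) minimizes
#' the normalized-profile residuals.  Runs are discarded as infeasible if
#' the solver fails, the negativity guard trips, or the fitted observable
#' never rises above 1\% of the receptor population.
#'
#' @param model an \code{nw_model}
#' @param data a \code{blot_dataset}
#' @param n_starts number of random starts (default 50)
#' @param bounds length-2 box applied to every parameter
#'   (default \code{c(1e-4, 1e-1)} 1/s)
#' @param seed integer seed controlling the random starts
#' @param fit_params subset of \code{\link{trafficking_parameter_names}}
#'   to fit (default all six).  Must not exceed the number of data points.
#' @return a \code{fit_ensemble}: data.frame of fitted sets (one row per
#'   retained start) plus metadata.
#' @export
fit_multistart <- function(model, data, n_starts = 50,
                           bounds = c(1e-4, 1e-1), seed = 1,
                           fit_params = trafficking_parameter_names()) {
  stopifnot(n_starts >= 1, length(bounds) == 2, bounds[1] > 0,
            bounds[2] > bounds[1])
  fit_params <- match.arg(fit_params, trafficking_parameter_names(),
                          several.ok = TRUE)
  if (length(fit_params) > length(data$time_min))
    stop("more fitted parameters than data time points")

  lb <- log10(bounds[1]); ub <- log10(bounds[2])
  y_data <- normalize_profile(data$intensity)
  r2_total <- model$basal[["R2_total"]]

  residual_fn <- function(logp) {
    p <- stats::setNames(10^logp, fit_params)
    sim <- tryCatch(simulate_at_params(model, p, data),
                    error = function(e) NULL)
    if (is.null(sim) || any(!is.finite(sim)) || max(sim) <= 0)
      return(rep(1e3, length(y_data)))
    normalize_profile(sim) - y_data
  }

  starts <- with_seed(seed, {
    matrix(stats::runif(n_starts * length(fit_params), lb, ub),
           nrow = n_starts)
  })

  rows <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[i, ],
                           lower = rep(lb, length(fit_params)),
                           upper = rep(ub, length(fit_params)),
                           fn = residual_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 40, ptol = 1e-8, ftol = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) { rows[[i]] <- NULL; next }
    p <- stats::setNames(10^fit$par, fit_params)
    sim <- tryCatch(simulate_at_params(model, p, data),
                    error = function(e) NULL)
    feasible <- !is.null(sim) && all(is.finite(sim)) &&
      max(sim) > 0.01 * r2_total
    sse <- if (is.null(sim) || max(sim) <= 0) Inf else
      sum((normalize_profile(sim) - y_data)^2)
    rows[[i]] <- c(start = i, p, sse = sse, feasible = as.numeric(feasible))
  }
  df <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
  ens <- df[df$feasible == 1, , drop = FALSE]
  if (!nrow(ens)) stop("all starts infeasible")
  structure(list(fits = ens, all_runs = df, data_source = data$source,
                 observable = data$observable, bounds = bounds,
                 fit_params = fit_params, n_starts = n_starts, seed = seed),
            class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf("fit_ensemble: %d/%d feasible fits to '%s' (%s)\n",
              nrow(x$fits), x$n_starts, x$data_source, x$observable))
  print(summarize_ensemble(x))
  invisible(x)
}

#' Per-parameter summary of a fit ensemble
#'
#' Mean, median and log-spaced histogram counts for each fitted parameter,
#' mirroring the dot-plus-histogram presentation of multi-start estimates.
#' Several ensembles can be aggregated (an "All" summary) by passing them
#' as additional arguments.
#'
#' @param ens a \code{fit_ensemble}
#' @param ... further ensembles to aggregate
#' @param n_bins number of log-spaced histogram bins
#' @return data.frame with one row per parameter: n, mean, median, and the
#'   bin counts as an attached attribute \code{"bins"}.
#' @export
summarize_ensemble <- function(ens, ..., n_bins = 12) {
  more <- list(...)
  fits <- ens$fits
  for (e in more) fits <- rbind(fits, e$fits[, colnames(fits)])
  pars <- ens$fit_params
  lo <- log10(ens$bounds[1]); hi <- log10(ens$bounds[2])
  breaks <- 10^seq(lo, hi, length.out = n_bins + 1)
  bins <- list()
  out <- data.frame(parameter = pars,
                    n = nrow(fits),
                    mean = vapply(pars, function(p) mean(fits[[p]]), 0),
                    median = vapply(pars, function(p) stats::median(fits[[p]]), 0),
                    row.names = NULL)
  for (p in pars)
    bins[[p]] <- graphics::hist(pmin(pmax(fits[[p]], breaks[1]),
                                     breaks[length(breaks)]),
                                breaks = breaks, plot = FALSE)$counts
  attr(out, "bins") <- bins
  attr(out, "breaks") <- breaks
  out
}

# Evaluate RNG-dependent code under a temporary seed, restoring the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
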