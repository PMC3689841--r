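#' Specification for a synthetic western-blot dataset
#'
#' Emulates the statistical structure of densitometry time courses used to
#' train the trafficking parameters: a transient rise-and-decay profile,
#' sampled at a handful of time points over 0--120 min, on an arbitrary
#' intensity scale, with multiplicative log-normal noise (always-positive
#' intensities, as densitometry produces).
#'
#' @param observable "pR2" or "pAkt"
#' @param trafficking named true trafficking parameters (defaults: the
#'   base-case values)
#' @param time_min sampling times; default the 8-point design
#'   \code{c(0, 2, 5, 10, 15, 30, 60, 120)} mirroring the densest
#'   published dataset
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.1)
#' @param scale arbitrary densitometry scale factor (default 100)
#' @param seed integer seed
#' @export
blot_generator_spec <- function(observable = "pR2", trafficking = NULL,
                                time_min = c(0, 2, 5, 10, 15, 30, 60, 120),
                                cv = 0.1, scale = 100, seed = 1) {
  if (cv < 0) stop("cv must be >= 0")
  if (any(time_min < 0 | time_min > 120))
    stop("time points must lie in [0, 120] minutes")
  structure(list(observable = observable, trafficking = trafficking,
                 time_min = time_min, cv = cv, scale = scale, seed = seed),
            class = "blot_generator_spec")
}

#' Generate a synthetic blot dataset from the model
#'
#' Simulates the model at the spec's true trafficking parameters, samples
#' the observable at the spec's time points, applies multiplicative
#' log-normal noise with the requested CV, and rescales to an arbitrary
#' densitometry scale.
#'
#' @param spec a \code{\link{blot_generator_spec}}
#' @param model an \code{nw_model} (default: the base network)
#' @return a \code{\link{blot_dataset}} whose attribute \code{"truth"}
#'   holds the true trafficking parameters.
#' @export
generate_blot_dataset <- function(spec, model = build_network()) {
  if (!is.null(spec$trafficking))
    model$params[names(spec$trafficking)] <- spec$trafficking
  tc <- simulate_model(model, t_end = max(spec$time_min, 120))
  obs <- evaluate_observable(tc, spec$observable)
  y <- stats::approx(obs$time_min, obs$value, xout = spec$time_min)$y
  if (max(y) <= 0)
    stop("observable profile is flat; refusing to generate a dataset")
  if (spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    noise <- with_seed(spec$seed,
                       stats::rlnorm(length(y), meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog))
    y <- y * noise
  }
  y <- y / max(y) * spec$scale
  out <- blot_dataset(spec$time_min, y, observable = spec$observable,
                      source = sprintf("synthetic-%s-seed%d",
                                       spec$observable, spec$seed))
  attr(out, "truth") <- model$params[trafficking_parameter_names()]
  out
}
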