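#' Built-in observable definitions
#'
#' Aggregates of model species matching what immunoblot / co-IP
#' experiments detect.  Signaling observables draw on the surface and
#' endosomal (internal) compartments only; degraded receptors are assumed
#' non-signaling and are excluded.
#'
#' \describe{
#'   \item{pR2}{all receptor complexes containing phosphorylated VEGFR2,
#'     surface + internal.}
#'   \item{pR2_surface / pR2_internal}{the two compartment shares of pR2.}
#'   \item{pAkt}{singly plus doubly phosphorylated Akt (Akt_p + Akt_pp).}
#'   \item{R2p_Gab1 / R2p_Gab2}{receptor complexes containing Gab1 (resp.
#'     Gab2), surface + internal.}
#'   \item{Shp2_Gab1}{receptor complexes in which Shp2 is bound to Gab1.}
#'   \item{Shp2_Gab2}{all species in which Shp2 is bound to Gab2,
#'     including the cytosolic Shp2:Gab2_p:PI3K_p complex.}
#'   \item{Shp2_Gab2_PI3K_cyt}{the cytosolic Shp2:Gab2_p:PI3K_p complex.}
#' }
#'
#' @param model an \code{nw_model}
#' @return named list of observable definitions (name + member species).
#' @export
builtin_observables <- function(model) {
  sp <- model$species
  live <- sp$id[sp$compartment %in% c("surface", "internal")]
  rec_live <- live[vapply(live, function(s)
    "R2" %in% names(model$components[[s]]), logical(1))]
  has_flag <- function(ids, flag) ids[vapply(ids, function(s)
    flag %in% model$phospho[[s]], logical(1))]
  has_part <- function(ids, part) ids[vapply(ids, function(s)
    part %in% names(model$components[[s]]), logical(1))]

  defs <- list(
    pR2 = has_flag(rec_live, "R2"),
    pR2_surface = intersect(has_flag(rec_live, "R2"),
                            sp$id[sp$compartment == "surface"]),
    pR2_internal = intersect(has_flag(rec_live, "R2"),
                             sp$id[sp$compartment == "internal"]),
    pAkt = c("Akt_p", "Akt_pp"),
    R2p_Gab1 = has_part(rec_live, "Gab1"),
    R2p_Gab2 = has_part(rec_live, "Gab2"),
    Shp2_Gab1 = has_part(has_part(rec_live, "Gab1"), "Shp2"),
    Shp2_Gab2 = c(has_part(has_part(rec_live, "Gab2"), "Shp2"),
                  "Shp2_Gab2p_PI3Kp"),
    Shp2_Gab2_PI3K_cyt = "Shp2_Gab2p_PI3Kp")
  lapply(names(defs), function(nm)
    structure(list(name = nm, members = defs[[nm]]), class = "observable")
  ) -> out
  stats::setNames(out, names(defs))
}

#' Evaluate an observable on a time course
#'
#' @param tc a \code{time_course}
#' @param obs an observable definition (from
#'   \code{\link{builtin_observables}}), its name, or a character vector of
#'   member species ids.
#' @return data.frame with columns \code{time_min} and \code{value}
#'   (pointwise sum over the member species).
#' @export
evaluate_observable <- function(tc, obs) {
  members <- if (inherits(obs, "observable")) obs$members
             else if (is.character(obs) && length(obs) == 1L &&
                      obs %in% names(builtin_observables(tc$model)))
               builtin_observables(tc$model)[[obs]]$members
             else obs
  unknown <- setdiff(members, colnames(tc$mat))
  if (length(unknown))
    stop("unknown member species: ", paste(unknown, collapse = ", "))
  if (!length(members)) stop("observable has no member species")
  value <- rowSums(tc$mat[, members, drop = FALSE])
  data.frame(time_min = tc$time, value = as.numeric(value))
}

#' Trapezoidal area under a time course
#'
#' @param x either a data.frame from \code{\link{evaluate_observable}} or a
#'   numeric time vector (minutes)
#' @param y values, when \code{x} is a time vector
#' @return area in (molecules/cell) x minutes
#' @export
auc <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$value; x <- x$time_min }
  if (length(x) < 2L) stop("need at least two time points")
  pracma::trapz(x, y)
}

#' Total time spent at or above half of the peak value
#'
#' Crossings of the half-maximum level are located by linear
#' interpolation; the durations of all super-half-maximum stretches are
#' summed.
#'
#' @param x,y as in \code{\link{auc}}
#' @return duration in minutes
#' @export
half_max_duration <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$value; x <- x$time_min }
  peak <- max(y)
  if (peak <= 0) stop("profile has no positive peak")
  h <- peak / 2
  above <- y >= h
  total <- 0
  n <- length(x)
  i <- 1L
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    t_in <- if (i == 1L) x[1] else
      x[i - 1] + (h - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
    j <- i
    while (j < n && above[j + 1L]) j <- j + 1L
    t_out <- if (j == n) x[n] else
      x[j] + (h - y[j]) / (y[j + 1L] - y[j]) * (x[j + 1L] - x[j])
    total <- total + (t_out - t_in)
    i <- j + 1L
  }
  total
}

#' Time-integrated surface share of the signaling receptor pool
#'
#' AUC of all surface receptor species divided by the AUC of surface plus
#' internal receptor species over \code{[0, horizon]} minutes.  Degraded
#' receptors are excluded (the non-signaling late-endosome pool); set
#' \code{include_degraded = TRUE} to count them in the denominator.
#'
#' @param tc a \code{time_course}
#' @param horizon minutes (default 100; must not exceed the simulated span)
#' @param include_degraded logical
#' @return fraction in [0, 1]
#' @export
surface_fraction <- function(tc, horizon = 100, include_degraded = FALSE) {
  if (horizon > max(tc$time) + 1e-9) stop("horizon exceeds simulated span")
  sel <- tc$time <= horizon + 1e-9
  sp <- tc$species
  is_rec <- vapply(sp$id, function(s)
    "R2" %in% names(tc$model$components[[s]]), logical(1))
  surf <- sp$id[is_rec & sp$compartment == "surface"]
  intl <- sp$id[is_rec & sp$compartment == "internal"]
  degr <- sp$id[is_rec & sp$compartment == "degraded"]
  t_min <- tc$time[sel]
  a_surf <- pracma::trapz(t_min, rowSums(tc$mat[sel, surf, drop = FALSE]))
  denom_ids <- c(surf, intl, if (include_degraded) degr)
  a_all <- pracma::trapz(t_min, rowSums(tc$mat[sel, denom_ids, drop = FALSE]))
  a_surf / a_all
}

#' Peak value and time-to-peak of an observable profile
#' @param x,y as in \code{\link{auc}}
#' @return list with \code{peak} and \code{time_to_peak} (minutes)
#' @export
peak_metrics <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$value; x <- x$time_min }
  i <- which.max(y)
  list(peak = y[i], time_to_peak = x[i])
}
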