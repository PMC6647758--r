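# Insulin-on-board and carbohydrates-on-board kinetics for the Combined
# Data view. IOB uses the open-source artificial-pancreas bilinear insulin
# activity curve by default (closed-form remaining fraction), with the
# exponential activity model available behind config. COB uses linear
# absorption after a fixed digestion delay.

# Cumulative absorbed fraction of a dose after `delta` minutes under the
# bilinear activity curve: activity rises linearly from 0 to its peak at
# `peak` minutes, then falls linearly to 0 at `dia` minutes, normalized to
# unit area (height 2/dia).
.bilinear_absorbed <- function(delta, dia, peak) {
  h <- 2 / dia
  ifelse(delta <= 0, 0,
  ifelse(delta <= peak, h * delta^2 / (2 * peak),
  ifelse(delta < dia, 1 - h * (dia - delta)^2 / (2 * (dia - peak)), 1)))
}

# Exponential activity model (tau parameterized by peak and dia); absorbed
# fraction = 1 - IOB fraction in the standard closed form.
.exponential_absorbed <- function(delta, dia, peak) {
  tau <- peak * (1 - peak / dia) / (1 - 2 * peak / dia)
  a <- 2 * tau / dia
  s <- 1 / (1 - a + (1 + a) * exp(-dia / tau))
  t <- pmin(pmax(delta, 0), dia)
  iob_frac <- 1 - s * (1 - a) *
    ((t^2 / (tau * dia * (1 - a)) - t / tau - 1) * exp(-t / tau) + 1)
  ifelse(delta <= 0, 0, ifelse(delta >= dia, 1, 1 - iob_frac))
}

#' Remaining insulin fraction of a dose
#'
#' Fraction of a dose still unabsorbed `delta` minutes after
#' administration, under the configured activity curve.
#'
#' @param delta minutes since the dose (vectorized).
#' @param dia duration of insulin action, minutes.
#' @param peak time of peak activity, minutes (`0 < peak < dia`).
#' @param curve `"bilinear"` (default) or `"exponential"`.
#' @return remaining fraction in `[0, 1]`; 1 at `delta = 0`, exactly 0 for
#'   `delta >= dia`.
#' @export
iob_fraction <- function(delta, dia = 180, peak = 75, curve = "bilinear") {
  stopifnot(peak > 0, peak < dia)
  absorbed <- switch(curve,
    bilinear = .bilinear_absorbed(delta, dia, peak),
    exponential = .exponential_absorbed(delta, dia, peak),
    stop("unknown iob curve: ", curve)
  )
  1 - absorbed
}

#' Insulin on board
#'
#' Total insulin administered but not yet absorbed at time `t`. Basal and
#' bolus doses can follow different activity profiles (`config$kinetics`
#' carries one parameter set per kind); doses at or before `t` contribute,
#' so IOB jumps by exactly the dose at the instant of administration.
#'
#' @param doses `data.frame` with columns `time` (`POSIXct`), `units`
#'   (numeric) and optionally `kind` (`"bolus"`/`"basal"`, default bolus).
#' @param t evaluation instant(s), `POSIXct`.
#' @param config configuration list (uses `config$kinetics`).
#' @return numeric IOB in units, one value per element of `t`.
#' @export
iob <- function(doses, t, config = default_config()) {
  kp <- config$kinetics
  if (is.null(doses$kind)) doses$kind <- "bolus"
  vapply(as.numeric(t), function(tt) {
    delta <- (tt - as.numeric(doses$time)) / 60
    live <- delta >= 0
    if (!any(live)) return(0)
    frac <- numeric(sum(live))
    kinds <- doses$kind[live]
    for (k in unique(kinds)) {
      p <- kp[[k]]
      sel <- kinds == k
      frac[sel] <- iob_fraction(delta[live][sel], p$dia, p$peak,
                                curve = kp$iob_curve)
    }
    sum(doses$units[live] * frac)
  }, numeric(1))
}

#' Carbohydrates on board
#'
#' Grams of ingested carbohydrate not yet absorbed at time `t`. Each meal
#' is absorbed linearly at `carb_rate` g/hour after a fixed `carb_delay`
#' minutes of digestion, floored at zero; meals are additive.
#'
#' @param meals `data.frame` with columns `time` (`POSIXct`) and `grams`.
#' @param t evaluation instant(s), `POSIXct`.
#' @param config configuration list (uses `config$kinetics`).
#' @return numeric COB in grams, one value per element of `t`.
#' @export
cob <- function(meals, t, config = default_config()) {
  kp <- config$kinetics
  rate_per_min <- kp$carb_rate / 60
  vapply(as.numeric(t), function(tt) {
    delta <- (tt - as.numeric(meals$time)) / 60
    live <- delta >= 0
    if (!any(live)) return(0)
    remaining <- pmax(meals$grams[live] -
                        pmax(0, delta[live] - kp$carb_delay) * rate_per_min, 0)
    sum(remaining)
  }, numeric(1))
}

# IOB/COB evaluated on a regular grid across the dataset period; the
# Combined Data view includes these as calculated (not patient-collected)
# series.
.kinetic_series <- function(dataset, config = default_config(),
                            step_min = 15) {
  rec <- dataset$records
  if (is.null(dataset$period)) {
    return(list(iob = data.frame(time = as.POSIXct(character(), tz = "UTC"),
                                 value = numeric()),
                cob = data.frame(time = as.POSIXct(character(), tz = "UTC"),
                                 value = numeric())))
  }
  grid <- seq(dataset$period[["start"]], dataset$period[["end"]],
              by = step_min * 60)
  ins <- rec[rec$data_type %in% c("insulin_bolus", "insulin_basal"), ]
  doses <- data.frame(time = ins$timestamp, units = ins$value,
                      kind = ifelse(ins$data_type == "insulin_basal",
                                    "basal", "bolus"))
  carbs <- rec[rec$data_type == "carbohydrate", ]
  meals <- data.frame(time = carbs$timestamp, grams = carbs$value)
  list(
    iob = data.frame(time = grid,
                     value = if (nrow(doses)) iob(doses, grid, config)
                             else numeric(length(grid)) * 0),
    cob = data.frame(time = grid,
                     value = if (nrow(meals)) cob(meals, grid, config)
                             else numeric(length(grid)) * 0)
  )
}
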