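# Fanger predicted mean vote (PMV), implemented from the heat-balance
# equation set of ISO 7730 / ASHRAE 55.

#' Fanger predicted mean vote
#'
#' Solves the clothing-surface temperature by damped fixed-point iteration
#' and evaluates the Fanger heat-balance sensation index from the six
#' classic inputs. Values are returned unclipped (they can exceed the
#' nominal -3..+3 scale); comparison metrics in this package use the raw
#' values.
#'
#' Inputs outside the usual validity range of the equations (ta 10-30 degC,
#' vr up to 1 m/s, met 0.8-4, clo up to 2) trigger a warning, not an error.
#'
#' @param ta air temperature, degC.
#' @param tr mean radiant temperature, degC (defaults to `ta`).
#' @param vr relative air speed, m/s.
#' @param rh relative humidity, %.
#' @param met metabolic rate, met (1 met = 58.15 W/m^2).
#' @param clo clothing insulation, clo (1 clo = 0.155 m^2 K/W).
#' @param wme external work, met (normally 0).
#' @param tol convergence tolerance on the clothing-surface temperature,
#'   degC.
#' @param max_iter maximal fixed-point iterations.
#' @return PMV value (vectorised over the inputs). Attribute `iterations`
#'   carries the per-point iteration counts.
#' @export
#' @examples
#' pmv(ta = 25, rh = 50, vr = 0.1, met = 1.0, clo = 0.5)
pmv <- function(ta, tr = ta, vr, rh, met, clo, wme = 0,
                tol = 1e-4, max_iter = 150) {
  args <- data.frame(ta = ta, tr = tr, vr = vr, rh = rh, met = met,
                     clo = clo, wme = wme)
  stopifnot(all(args$met > 0), all(args$clo >= 0), all(args$vr >= 0),
            all(args$rh >= 0 & args$rh <= 100))
  if (any(args$ta < 10 | args$ta > 30 | args$vr > 1 |
          args$met < 0.8 | args$met > 4 | args$clo > 2)) {
    warning("some inputs fall outside the usual PMV validity range")
  }
  out <- numeric(nrow(args))
  iters <- integer(nrow(args))
  for (i in seq_len(nrow(args))) {
    r <- pmv_point(args$ta[i], args$tr[i], args$vr[i], args$rh[i],
                   args$met[i], args$clo[i], args$wme[i], tol, max_iter)
    out[i] <- r$pmv
    iters[i] <- r$iterations
  }
  attr(out, "iterations") <- iters
  out
}

pmv_point <- function(ta, tr, vr, rh, met, clo, wme, tol, max_iter) {
  # water vapour partial pressure, Pa (standard saturation formula)
  pa <- rh * 10 * exp(16.6536 - 4030.183 / (ta + 235))
  icl <- 0.155 * clo
  m <- met * 58.15
  w <- wme * 58.15
  mw <- m - w
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  hcf <- 12.1 * sqrt(vr)
  taa <- ta + 273
  tra <- tr + 273
  # fixed-point iteration on the clothing-surface temperature, damped by
  # averaging consecutive iterates; xn is t_cl in hectokelvin
  tcla <- taa + (35.5 - ta) / (3.5 * icl + 0.1)
  p1 <- icl * fcl
  p2 <- p1 * 3.96
  p3 <- p1 * 100
  p4 <- p1 * taa
  p5 <- 308.7 - 0.028 * mw + p2 * (tra / 100)^4
  xn <- tcla / 100
  xf <- tcla / 50
  eps <- tol / 100 # iterate scale is 100 K
  k <- 0
  hc <- hcf
  while (abs(xn - xf) > eps) {
    xf <- (xf + xn) / 2
    hcn <- 2.38 * abs(100 * xf - taa)^0.25
    hc <- max(hcf, hcn)
    xn <- (p5 + p4 * hc - p2 * xf^4) / (100 + p3 * hc)
    k <- k + 1
    if (k > max_iter) {
      stop(sprintf("PMV iteration did not converge: residual %.3g degC",
                   abs(xn - xf) * 100))
    }
  }
  tcl <- 100 * xn - 273
  # heat-loss components: skin diffusion, sweat, latent and dry respiration,
  # clothing radiation and convection
  hl1 <- 3.05e-3 * (5733 - 6.99 * mw - pa)
  hl2 <- if (mw > 58.15) 0.42 * (mw - 58.15) else 0
  hl3 <- 1.7e-5 * m * (5867 - pa)
  hl4 <- 0.0014 * m * (34 - ta)
  hl5 <- 3.96 * fcl * (xn^4 - (tra / 100)^4)
  hl6 <- fcl * hc * (tcl - ta)
  sens <- 0.303 * exp(-0.036 * m) + 0.028
  list(pmv = sens * (mw - hl1 - hl2 - hl3 - hl4 - hl5 - hl6), iterations = k)
}

#' PMV for a chamber trial
#'
#' Applies the conventions used when benchmarking against physiological TS
#' models: radiant temperature equal to air temperature (uniform room),
#' sedentary metabolic rate 1.0 met and summer clothing 0.5 clo unless
#' overridden.
#'
#' @param env a list, `trial_record` or data frame row carrying `EnvTemp`,
#'   `EnvWind`, `EnvRH` (or `air_temp`, `wind_speed`, `rh`).
#' @param met,clo personal parameters.
#' @param tr_offset radiant-minus-air temperature offset, degC.
#' @return PMV value(s).
#' @export
pmv_for_trial <- function(env, met = 1.0, clo = 0.5, tr_offset = 0) {
  if (inherits(env, "trial_record")) env <- env$setting
  ta <- env$EnvTemp %||% env$air_temp
  vr <- env$EnvWind %||% env$wind_speed
  rh <- env$EnvRH %||% env$rh
  if (is.null(ta) || is.null(vr) || is.null(rh)) {
    stop("environment means EnvTemp/EnvWind/EnvRH are required")
  }
  as.numeric(pmv(ta = ta, tr = ta + tr_offset, vr = vr, rh = rh,
                 met = met, clo = clo))
}
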