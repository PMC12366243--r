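#' Rate constants for the NAD-dependent racemization mechanism
#'
#' Elementary steps of the modeled scheme: the enzyme binds NAD+, then
#' either HAEP enantiomer; the bound substrate is oxidized to an
#' enzyme-retained keto intermediate (OAEP) with transient NADH, which is
#' re-reduced on the opposite face of the carbonyl to release the opposite
#' enantiomer. A first-order leak lets NADH and OAEP escape from the
#' central intermediate; its magnitude is scaled by a user-set multiplier
#' standing in for pH (enzyme-bound NADH is more stable at high pH, so a
#' larger multiplier plays the role of a higher pH). NADH inhibits by
#' competitive binding to the NAD+ site. An alternative two-step leak route
#' (OAEP release first, then NADH) is available and off by default.
#'
#' The default constants are illustrative, not fitted: they are chosen so
#' that the saturating racemization flux per enzyme is about 6.6 s^-1, the
#' *apparent* NAD+ half-saturation under assay-like turnover (1 mM
#' substrate) is about 200 uM, NADH halves the rate at about 60 uM in the
#' presence of 1 mM NAD+, and the leak stays below 10 percent of total NAD
#' over 15 min at the high-pH multiplier. Because the catalytic cycle
#' sequesters the cofactor, the apparent half-saturation is well below the
#' binding dissociation constant (koff_nad / kon_nad = 0.8 mM), consistent
#' with an enzyme that binds its cofactor loosely yet shows
#' cofactor-dependent steady-state rates.
#'
#' The S and R branches are symmetric (equal constants), as they must be
#' for a racemization whose equilibrium constant is 1.
#'
#' @param kon_nad,koff_nad NAD+ binding to free enzyme (M^-1 s^-1, s^-1).
#' @param kon_s,koff_s substrate binding/release, either enantiomer.
#' @param k_ox,k_red bound oxidation/re-reduction rates (s^-1), used for
#'   both faces.
#' @param k_leak first-order NADH+OAEP leak from the central intermediate
#'   (s^-1), scaled by `leak_mult`.
#' @param leak_mult pH proxy multiplier on the leak (0 disables it).
#' @param kon_nadh,koff_nadh competitive NADH binding to the NAD+ site.
#' @param k_oaep_off,k_nadh_off alternative leak route (OAEP release from
#'   the intermediate, then NADH release); both 0 by default.
#' @return list of class `mechanism_params`.
#' @export
mechanism_params <- function(kon_nad = 2.5e7, koff_nad = 2e4,
                             kon_s = 1e6, koff_s = 500,
                             k_ox = 21, k_red = 21,
                             k_leak = 0.05, leak_mult = 1,
                             kon_nadh = 5e7, koff_nadh = 500,
                             k_oaep_off = 0, k_nadh_off = 0) {
  p <- list(kon_nad = kon_nad, koff_nad = koff_nad, kon_s = kon_s,
            koff_s = koff_s, k_ox = k_ox, k_red = k_red, k_leak = k_leak,
            leak_mult = leak_mult, kon_nadh = kon_nadh,
            koff_nadh = koff_nadh, k_oaep_off = k_oaep_off,
            k_nadh_off = k_nadh_off)
  if (any(unlist(p) < 0)) stop("all rate constants must be non-negative")
  class(p) <- "mechanism_params"
  p
}

MECH_SPECIES <- c("S", "R", "OAEP", "NAD", "NADH",
                  "E", "ENAD", "ENADS", "ENADHOA", "ENADR", "ENADH")

#' Initial state for the mechanism simulator
#'
#' @param S,R free S-HAEP and R-HAEP (M).
#' @param OAEP free keto intermediate (M).
#' @param NAD,NADH free cofactor pools (M).
#' @param E total enzyme, all placed in the free form (M).
#' @return named numeric vector over the mechanism species.
#' @export
mechanism_state <- function(S = 3e-3, R = 0, OAEP = 0, NAD = 3e-4,
                            NADH = 0, E = 0.9e-6) {
  x <- c(S = S, R = R, OAEP = OAEP, NAD = NAD, NADH = NADH, E = E,
         ENAD = 0, ENADS = 0, ENADHOA = 0, ENADR = 0, ENADH = 0)
  if (any(x < 0)) stop("concentrations must be non-negative")
  x
}

mechanism_rhs <- function(t, x, p) {
  with(as.list(c(x, p)), {
    v_nad_on <- kon_nad * E * NAD - koff_nad * ENAD
    v_s_on <- kon_s * ENAD * S - koff_s * ENADS
    v_ox <- k_ox * ENADS - k_red * ENADHOA
    v_red <- k_red * ENADHOA - k_ox * ENADR
    v_r_off <- koff_s * ENADR - kon_s * ENAD * R
    v_leak <- k_leak * leak_mult * ENADHOA
    v_oaep_off <- k_oaep_off * ENADHOA
    v_nadh_off <- k_nadh_off * ENADH
    v_nadh_on <- kon_nadh * E * NADH - koff_nadh * ENADH
    list(c(
      S = -v_s_on,
      R = v_r_off,
      OAEP = v_leak + v_oaep_off,
      NAD = -v_nad_on,
      NADH = v_leak + v_nadh_off - v_nadh_on,
      E = -v_nad_on + v_leak - v_nadh_on + v_nadh_off,
      ENAD = v_nad_on - v_s_on + v_r_off,
      ENADS = v_s_on - v_ox,
      ENADHOA = v_ox - v_red - v_leak - v_oaep_off,
      ENADR = v_red - v_r_off,
      ENADH = v_nadh_on + v_oaep_off - v_nadh_off
    ))
  })
}

#' Simulate the racemization mechanism
#'
#' Mass-action integration of the full scheme with a stiff-capable solver.
#' The three conservation laws (total enzyme, total HAEP moiety, total
#' nicotinamide) hold analytically in the rate equations and are monitored
#' numerically at every output step.
#'
#' @param params a [mechanism_params()].
#' @param initial a [mechanism_state()].
#' @param t_end simulation horizon (s).
#' @param n_out number of output times (default 200).
#' @param rtol,atol solver tolerances (defaults 1e-10 and 1e-14 M keep the
#'   conservation drift below 1e-9 relative).
#' @return data.frame of class `mechanism_series`: `time` plus one column
#'   per species.
#' @export
simulate_mechanism <- function(params, initial = mechanism_state(),
                               t_end = 900, n_out = 200,
                               rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(params, "mechanism_params"), t_end > 0)
  if (any(initial < 0)) stop("initial state has a negative concentration")
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::lsoda(y = initial[MECH_SPECIES], times = times,
                        func = mechanism_rhs, parms = unclass(params),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  out <- as.data.frame(sol)
  if (any(out[, MECH_SPECIES] < -1e-9 * max(initial)))
    stop("integration produced a negative concentration beyond tolerance")
  class(out) <- c("mechanism_series", "data.frame")
  out
}

#' Conservation errors of a simulated mechanism series
#'
#' @param series output of [simulate_mechanism()].
#' @return data.frame with the maximum relative drift of each conserved
#'   total: `enzyme`, `haep` (S + R + OAEP + substrate-bound species),
#'   `nicotinamide`.
#' @export
conservation_error <- function(series) {
  enz <- series$E + series$ENAD + series$ENADS + series$ENADHOA +
    series$ENADR + series$ENADH
  haep <- series$S + series$R + series$OAEP + series$ENADS +
    series$ENADHOA + series$ENADR
  nic <- series$NAD + series$NADH + series$ENAD + series$ENADS +
    series$ENADHOA + series$ENADR + series$ENADH
  rel_drift <- function(x) if (x[1] == 0) max(abs(x)) else max(abs(x - x[1]) / x[1])
  data.frame(enzyme = rel_drift(enz), haep = rel_drift(haep),
             nicotinamide = rel_drift(nic))
}

#' Simulate the four-enzyme coupled racemase assay
#'
#' Models the continuous assay in which racemization of S-HAEP is coupled,
#' through a lyase (R-HAEP consumer), a hydrolase (PAA consumer) and an
#' NADP-dependent alcohol dehydrogenase (acetaldehyde + NADPH consumer), to
#' a 340-nm absorbance decrease. The racemase step follows the
#' Michaelis-Menten form; each coupling enzyme is a Michaelis-Menten
#' consumer whose Vmax is `coupling_excess` times the racemase Vmax, so a
#' large excess makes the observed NADPH-consumption rate equal the
#' racemization flux after a short coupling lag. The observed rate is the
#' least-squares slope of the simulated A340 trace over the post-lag
#' window.
#'
#' @param kcat,km racemase parameters (s^-1, M).
#' @param enzyme_total racemase concentration (M).
#' @param s_haep0 initial S-HAEP (M).
#' @param coupling_excess fold Vmax excess of every coupling enzyme over
#'   the racemase Vmax; must be positive.
#' @param nadph0 initial NADPH (M).
#' @param t_end measurement horizon (s).
#' @param km_coupling Michaelis constant of the coupling consumers (M).
#' @param eps340,path_cm absorbance conversion as in [rate_from_trace()].
#' @param lag_fraction initial fraction of the trace discarded before the
#'   slope fit (default 0.25).
#' @return list with `observed_rate` (M s^-1 of NADPH consumption),
#'   `racemase_flux` (mean true racemization flux over the fitted window),
#'   `series` (time courses of S, R, PAA, acetaldehyde, NADPH, A340).
#' @export
simulate_coupled_assay <- function(kcat = 6.6, km = 5.3e-4,
                                   enzyme_total = 35e-9, s_haep0 = 1e-3,
                                   coupling_excess = 100, nadph0 = 2e-4,
                                   t_end = 120, km_coupling = 1e-4,
                                   eps340 = 6220, path_cm = 1,
                                   lag_fraction = 0.25) {
  if (coupling_excess <= 0) stop("coupling_excess must be positive")
  vmax_r <- kcat * enzyme_total
  vmax_c <- coupling_excess * max(vmax_r, kcat * 1e-12)
  rhs <- function(t, x, p) {
    with(as.list(x), {
      v_rac <- vmax_r * S / (km + S)
      v_lyase <- vmax_c * R / (km_coupling + R)
      v_hydro <- vmax_c * PAA / (km_coupling + PAA)
      v_adh <- vmax_c * ALD / (km_coupling + ALD) *
        NADPH / (2e-5 + NADPH)
      list(c(S = -v_rac, R = v_rac - v_lyase, PAA = v_lyase - v_hydro,
             ALD = v_hydro - v_adh, NADPH = -v_adh))
    })
  }
  x0 <- c(S = s_haep0, R = 0, PAA = 0, ALD = 0, NADPH = nadph0)
  times <- seq(0, t_end, length.out = 400)
  sol <- as.data.frame(deSolve::lsoda(x0, times, rhs, parms = NULL,
                                      rtol = 1e-10, atol = 1e-14))
  if (min(sol$NADPH) < 0.05 * nadph0)
    stop("NADPH exhausted before the end of the measurement window")
  sol$A340 <- eps340 * path_cm * sol$NADPH
  fit_win <- sol$time >= lag_fraction * t_end
  obs_slope <- stats::coef(stats::lm(A340 ~ time, data = sol[fit_win, ]))[[2]]
  flux <- vmax_r * sol$S[fit_win] / (km + sol$S[fit_win])
  list(observed_rate = -obs_slope / (eps340 * path_cm),
       racemase_flux = mean(flux),
       series = sol)
}
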