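#' Model parameters for the delayed CSC reaction-diffusion system
#'
#' Constructs and validates the full parameter set of the four-component
#' model (cancer stem cells S, differentiated cancer cells D, Wnt-beta
#' catenin activator a, microRNA m). Defaults are the published reference
#' values with the prostate-cancer dedifferentiation/death pair
#' (`q0 = 87.6`, `d = 87.2`).
#'
#' Units: concentrations in cell/mm^3 (S, D) or molecule/mm^3 (a, m), time
#' in years, space in mm. `alpha` acts as a first-order degradation rate
#' and is treated as year^-1 throughout (its nominal unit listing as
#' mm^3/molecule is inconsistent with its use; see the package vignette).
#'
#' @param eta positive feedback strength of the Wnt-beta activator on the
#'   symmetric-division probability (mm^3/molecule).
#' @param psi negative feedback strength of differentiated cells
#'   (mm^3/cell).
#' @param epsilon mitotic rate of CSCs (year^-1).
#' @param q0 maximum dedifferentiation rate of DCs (year^-1).
#' @param m0 minimal (threshold) microRNA concentration (molecule/mm^3).
#' @param d DC death rate (year^-1).
#' @param alpha degradation rate of proteins/molecules (year^-1).
#' @param beta aggressiveness of Wnt-beta self-renewal
#'   (mm^3/cell/year).
#' @param gamma maximal microRNA production rate (molecule/mm^3/year).
#' @param sigma sensitivity of the dedifferentiation switch
#'   (molecule/mm^3); must be strictly positive.
#' @param S0 minimal CSC concentration scale (cell/mm^3).
#' @param DS,DD,Da,Dm diffusion coefficients of S, D, a, m (mm^2/year).
#' @param tau dedifferentiation time delay (years), `tau >= 0`.
#'
#' @return An object of class `csc_params` (a named list).
#' @seealso [cancer_params()] for the per-cancer presets,
#'   [e2_consistent_m2()] for the self-consistent microRNA level.
#' @examples
#' p <- csc_params(tau = 6.8964)
#' p$q0 / p$d
#' @export
csc_params <- function(eta = 1, psi = 0.5, epsilon = 1, q0 = 87.6,
                       m0 = 0.05, d = 87.2, alpha = 0.3, beta = 1,
                       gamma = 1, sigma = 0.05, S0 = 0.038,
                       DS = 0.031536, DD = 0.031536,
                       Da = 0.365, Dm = 0.365, tau = 0) {
  p <- list(eta = eta, psi = psi, epsilon = epsilon, q0 = q0, m0 = m0,
            d = d, alpha = alpha, beta = beta, gamma = gamma,
            sigma = sigma, S0 = S0, DS = DS, DD = DD, Da = Da, Dm = Dm,
            tau = tau)
  validate_csc_params(p)
  structure(p, class = "csc_params")
}

validate_csc_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  pos <- setdiff(names(p), "tau")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (p$tau < 0) stop("tau must be >= 0", call. = FALSE)
  invisible(p)
}

#' Per-cancer parameter presets
#'
#' The model is specialised to a cancer type through the pair
#' (`q0`, `d`): prostate `q0 = 87.6`, `d = 87.2`; lung `q0 = 109.97`,
#' `d = 80`; breast `q0 = 70.39`, `d = 45` (all year^-1). All other
#' parameters keep the [csc_params()] defaults unless overridden.
#'
#' @param cancer one of `"prostate"`, `"lung"`, `"breast"`.
#' @param ... further overrides passed to [csc_params()].
#' @return A `csc_params` object.
#' @examples
#' cancer_params("lung")$q0
#' @export
cancer_params <- function(cancer = c("prostate", "lung", "breast"), ...) {
  cancer <- match.arg(cancer)
  qd <- switch(cancer,
               prostate = c(87.6, 87.2),
               lung     = c(109.97, 80),
               breast   = c(70.39, 45))
  dots <- list(...)
  if (is.null(dots$q0)) dots$q0 <- qd[1]
  if (is.null(dots$d))  dots$d  <- qd[2]
  do.call(csc_params, dots)
}

#' Self-consistent microRNA level at the CSC-free-activator equilibrium
#'
#' The S and D balance of the non-spatial system holds at the second
#' equilibrium only when the dedifferentiation rate equals the DC death
#' rate, `q(m2) = d`. Inverting the sigmoidal rate gives the unique
#' microRNA level `m2* = m0 + sigma * atanh(2 d / q0 - 1)`, which requires
#' `0 < d < q0`. At any other `m2` the closed-form point is stationary in
#' the a and m components only (see [equilibrium_E2()]).
#'
#' @param params a [csc_params()] object.
#' @return The self-consistent `m2*` (molecule/mm^3).
#' @export
e2_consistent_m2 <- function(params) {
  stopifnot(inherits(params, "csc_params"))
  if (params$d >= params$q0)
    stop("q(m2) = d has no solution unless d < q0", call. = FALSE)
  params$m0 + params$sigma * atanh(2 * params$d / params$q0 - 1)
}

#' Radiobiological parameters for fractionated radiotherapy
#'
#' Linear-quadratic sensitivities, repair kinetics and the fractionation
#' schedule used by the effective-radiation and biologically-effective-dose
#' machinery. Defaults are the published prostate values: `alpha_s = 0.302`
#' Gy^-1, `beta_s = 0.0417` Gy^-2, `delta = 25` year^-1 Gy^-1,
#' `mu = 3195.77` year^-1, with two fractions per day of duration
#' `tau_r = 9e-6` yr (about 5 min) separated by `delta_tau_r = 6.9e-4` yr
#' (about 6.04 h), `theta_late = 3` Gy, `K = 0.2` Gy/day, `T_d = 40` days,
#' `f = 7/5` and a treatment time of `T = 45` days.
#'
#' @param alpha_s single-hit radiosensitivity (Gy^-1).
#' @param beta_s two-hit (repairable) radiosensitivity (Gy^-2).
#' @param delta CSC death rate per unit effective radiation
#'   (year^-1 Gy^-1); couples the radiation term into the S equation.
#' @param mu sublethal-damage repair rate constant (year^-1),
#'   `ln(2) / t_half`.
#' @param dose dose per fraction (Gy).
#' @param n_per_day dose fractions per treatment day.
#' @param tau_r duration of one irradiation fraction (years).
#' @param delta_tau_r interval between fraction starts within a day
#'   (years); must be at least `tau_r`.
#' @param K repopulation dose rate (Gy/day), the daily biologically
#'   effective dose needed to offset tumor repopulation once it has begun.
#' @param T_d repopulation kick-off time after treatment start (days).
#' @param f schedule factor relating treatment time and fraction number
#'   (`T = f * n - 1`); 7/5 for five treatment days per week.
#' @param theta_late alpha/beta ratio of late-responding normal tissue
#'   (Gy).
#' @param theta_can alpha/beta ratio of the tumor (Gy); defaults to
#'   `alpha_s / beta_s`.
#' @param T treatment time (days).
#' @param days_per_week treatment days per week (consecutive, from the
#'   start of each 7-day block).
#' @param gating how the radiation switch resolves time: `"day"` (on
#'   across each treatment day; the effective radiation already aggregates
#'   the day's fractions), `"fraction"` (on only inside the literal
#'   irradiation windows) or `"continuous"` (on throughout the treatment
#'   span). See the vignette for why `"day"` is the default.
#'
#' @return An object of class `radio_params`.
#' @examples
#' rp <- radio_params(dose = 0.05)
#' repair_correction_M(rp)
#' @export
radio_params <- function(alpha_s = 0.302, beta_s = 0.0417, delta = 25,
                         mu = 3195.77, dose = 0.02, n_per_day = 2,
                         tau_r = 9e-6, delta_tau_r = 6.9e-4,
                         K = 0.2, T_d = 40, f = 7 / 5, theta_late = 3,
                         theta_can = alpha_s / beta_s, T = 45,
                         days_per_week = 5,
                         gating = c("day", "fraction", "continuous")) {
  gating <- match.arg(gating)
  p <- list(alpha_s = alpha_s, beta_s = beta_s, delta = delta, mu = mu,
            dose = dose, n_per_day = n_per_day, tau_r = tau_r,
            delta_tau_r = delta_tau_r, K = K, T_d = T_d, f = f,
            theta_late = theta_late, theta_can = theta_can, T = T,
            days_per_week = days_per_week, gating = gating)
  num <- setdiff(names(p), "gating")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("radio parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (any(c(p$alpha_s, p$beta_s, p$mu) <= 0))
    stop("alpha_s, beta_s and mu must be strictly positive", call. = FALSE)
  if (p$dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (p$n_per_day < 1 || p$n_per_day != round(p$n_per_day))
    stop("n_per_day must be a positive integer", call. = FALSE)
  if (p$tau_r <= 0 || p$delta_tau_r < p$tau_r)
    stop("need 0 < tau_r <= delta_tau_r (non-overlapping fractions)",
         call. = FALSE)
  if (p$days_per_week < 1 || p$days_per_week > 7)
    stop("days_per_week must be in 1..7", call. = FALSE)
  structure(p, class = "radio_params")
}

#' @export
print.csc_params <- function(x, ...) {
  cat("<csc_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 8), " = ",
             format(v, digits = 7), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.radio_params <- function(x, ...) {
  cat("<radio_params>  gating =", x$gating, "\n")
  v <- unlist(x[setdiff(names(x), "gating")])
  cat(paste0("  ", format(names(v), width = 12), " = ",
             format(v, digits = 7), collapse = "\n"), "\n")
  invisible(x)
}

#' Number of year units per day (365-day year convention)
#' @noRd
DAYS_PER_YEAR <- 365
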