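# Fractionated radiotherapy: LQ effective radiation with repair
# corrections, biologically effective dose, optimum dose per fraction and
# Poisson tumor control probability.

#' Intra-fraction repair factor g
#'
#' `g(x) = 2 (x - 1 + exp(-x)) / x^2` with `x = mu * tau_r`, the classic
#' Lea-Catcheside correction for sublethal-damage repair during a
#' protracted irradiation; `g(0) = 1` (instantaneous fraction) and
#' `g -> 2/x` for long fractions. A second-order series is used below
#' `x = 1e-4` for numerical stability.
#'
#' @param x dimensionless `mu * tau_r`, `>= 0` (vectorised).
#' @return Values in `(0, 1]`.
#' @examples
#' repair_g(1)  # 2/e
#' @export
repair_g <- function(x) {
  stopifnot(all(x >= 0))
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 12
  xl <- x[!small]
  out[!small] <- 2 * (xl - 1 + exp(-xl)) / xl^2
  out
}

#' Incomplete inter-fraction repair factor h_n
#'
#' `h_n(phi) = 2 (n phi - n phi^2 - phi + phi^(n+1)) / (n (1 - phi)^2)`,
#' where `phi = exp(-mu (tau_r + delta_tau_r))` is the fraction of
#' sublethal damage still unrepaired when the next fraction starts.
#' `h_1 = 0` (a single fraction has no inter-fraction term) and
#' `h_2 = phi` exactly.
#'
#' @param n fractions per day (positive integer).
#' @param phi unrepaired fraction, `0 <= phi < 1` (vectorised).
#' @return Non-negative factor.
#' @export
incomplete_repair_h <- function(n, phi) {
  if (n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  if (any(phi < 0) || any(phi >= 1))
    stop("phi must satisfy 0 <= phi < 1", call. = FALSE)
  out <- numeric(length(phi))
  nz <- phi > 0
  p <- phi[nz]
  out[nz] <- 2 * (n * p - n * p^2 - p + p^(n + 1)) / (n * (1 - p)^2)
  out
}

#' Combined repair correction M
#'
#' `M = g(mu tau_r) + 2 ((cosh(mu tau_r) - 1) / (mu tau_r)^2) h_n(phi)`,
#' correcting the quadratic LQ term for both repair during each
#' irradiation and incomplete repair between the day's fractions.
#' `M >= g` always; `M -> 1` for instantaneous single fractions.
#'
#' @param radio a [radio_params()] object.
#' @return The correction factor (dimensionless).
#' @export
repair_correction_M <- function(radio) {
  stopifnot(inherits(radio, "radio_params"))
  x <- radio$mu * radio$tau_r
  phi <- exp(-radio$mu * (radio$tau_r + radio$delta_tau_r))
  cosh_term <- if (x < 1e-4) 1 + x^2 / 12 else 2 * (cosh(x) - 1) / x^2
  repair_g(x) +
    cosh_term * incomplete_repair_h(radio$n_per_day, phi)
}

#' Effective radiation of one treatment day
#'
#' Linear-quadratic effect aggregated over the `n` fractions of a
#' treatment day:
#' `R_eff = alpha_s n D + beta_s n D^2 M`, with `D` the dose per fraction
#' and `M` the repair correction of [repair_correction_M()].
#'
#' @param radio a [radio_params()] object.
#' @return Dimensionless effect (couples into the S equation as
#'   `-delta R_eff K_R S`).
#' @export
effective_radiation <- function(radio) {
  stopifnot(inherits(radio, "radio_params"))
  n <- radio$n_per_day
  D <- radio$dose
  radio$alpha_s * n * D +
    radio$beta_s * n * D^2 * repair_correction_M(radio)
}

#' Radiation on/off switch K_R(t)
#'
#' Indicator that the radiation term is active at time `t`. Treatment
#' runs on the first `days_per_week` days of each 7-day block within
#' `[t_start, t_start + duration)`. The time granularity is set by the
#' `gating` field of the schedule: `"day"` switches on across whole
#' treatment days (the effective radiation already aggregates a day's
#' fractions), `"fraction"` only inside the literal irradiation windows
#' (fraction `j` of a day occupies
#' `[j delta_tau_r, j delta_tau_r + tau_r)`), and `"continuous"` is on
#' throughout the treatment span.
#'
#' @param t time (years), vectorised.
#' @param radio a [radio_params()] object (schedule and gating).
#' @param t_start treatment start (years).
#' @param duration treatment course length (years); `Inf` for open-ended.
#' @return 0/1 vector.
#' @export
radiation_switch <- function(t, radio, t_start = 0, duration = Inf) {
  stopifnot(inherits(radio, "radio_params"))
  u <- t - t_start
  on <- u >= 0 & u < duration
  if (radio$gating == "continuous" || !any(on))
    return(as.numeric(on))
  day <- floor(u * DAYS_PER_YEAR)
  dow <- day %% 7
  on <- on & dow < radio$days_per_week
  if (radio$gating == "fraction" && any(on)) {
    tod <- u - day / DAYS_PER_YEAR        # time within the day, years
    j <- floor(tod / radio$delta_tau_r)
    inwin <- j < radio$n_per_day &
      (tod - j * radio$delta_tau_r) < radio$tau_r
    on <- on & inwin
  }
  as.numeric(on)
}

#' Biologically effective dose for late-responding normal tissue
#'
#' `BED_late = n D (1 + D / theta_late) M`.
#'
#' @param radio a [radio_params()] object.
#' @param n number of fractions entering the BED (defaults to the
#'   schedule's fractions per day, matching the published worked
#'   configuration).
#' @param dose dose per fraction (Gy); defaults to the schedule's.
#' @return BED in Gy.
#' @export
bed_late <- function(radio, n = radio$n_per_day, dose = radio$dose) {
  stopifnot(inherits(radio, "radio_params"))
  n * dose * (1 + dose / radio$theta_late) * repair_correction_M(radio)
}

#' Biologically effective dose for the tumor, with repopulation
#'
#' `BED_can = n D (1 + D / theta_can) M - K (T - T_d)` where the
#' repopulation subtraction applies only once repopulation has started
#' (`T > T_d`; clamped to zero otherwise). `form = "late-tissue"`
#' evaluates the algebraically equivalent expression written in terms of
#' `BED_late` with the schedule relation `T = f n - 1`; the two forms
#' agree to machine precision when that relation holds.
#'
#' @param radio a [radio_params()] object.
#' @param n fractions entering the BED.
#' @param dose dose per fraction (Gy).
#' @param T treatment time (days); defaults to the schedule's `T`.
#' @param form `"direct"` or `"late-tissue"`.
#' @return BED in Gy.
#' @export
bed_cancer <- function(radio, n = radio$n_per_day, dose = radio$dose,
                       T = radio$T, form = c("direct", "late-tissue")) {
  stopifnot(inherits(radio, "radio_params"))
  form <- match.arg(form)
  M <- repair_correction_M(radio)
  repop <- radio$K * max(T - radio$T_d, 0)
  if (form == "direct")
    return(n * dose * (1 + dose / radio$theta_can) * M - repop)
  BL <- bed_late(radio, n = n, dose = dose)
  (BL / (1 + dose / radio$theta_late)) * (1 + dose / radio$theta_can) -
    radio$K * max(radio$f * BL /
                    (dose * (1 + dose / radio$theta_late) * M) - 1 -
                    radio$T_d, 0)
}

#' Logarithmic tumor cell kill E
#'
#' `E = alpha_s * BED_can`: the natural-log cell kill of the LQ model
#' with repopulation, proportional to the tumor BED (the repopulation
#' subtraction is carried inside the BED so that the proportionality is
#' exact and dimensionally consistent).
#'
#' @inheritParams bed_cancer
#' @return Dimensionless log cell kill.
#' @export
log_cell_kill_E <- function(radio, n = radio$n_per_day,
                            dose = radio$dose, T = radio$T) {
  stopifnot(inherits(radio, "radio_params"))
  radio$alpha_s * bed_cancer(radio, n = n, dose = dose, T = T)
}

#' Optimum dose per fraction
#'
#' Maximising the tumor BED at fixed late-tissue BED over the dose per
#' fraction yields the quadratic
#' `(1 - theta_late/theta_can) M D^2 - 2 K f D - K f theta_late = 0`;
#' the optimum is its positive root. A positive finite optimum requires
#' `theta_late < theta_can`. `form = "as-printed"` evaluates the
#' published closed-form expression, which omits the repair factor under
#' the square root and therefore does not exactly zero the quadratic
#' unless `M = 1`; the default `"exact"` root does (to 1e-10, which is
#' checked).
#'
#' @param radio a [radio_params()] object.
#' @param form `"exact"` or `"as-printed"`.
#' @return Optimum dose per fraction (Gy).
#' @examples
#' optimum_dose(radio_params())
#' @export
optimum_dose <- function(radio, form = c("exact", "as-printed")) {
  stopifnot(inherits(radio, "radio_params"))
  form <- match.arg(form)
  a <- 1 - radio$theta_late / radio$theta_can
  if (a <= 0)
    stop("no finite optimum: need theta_late < theta_can ",
         "(leading coefficient <= 0)", call. = FALSE)
  M <- repair_correction_M(radio)
  Kf <- radio$K * radio$f
  if (form == "as-printed")
    return((Kf + sqrt(Kf^2 + a * Kf * radio$theta_late)) / (a * M))
  D <- (Kf + sqrt(Kf^2 + a * M * Kf * radio$theta_late)) / (a * M)
  resid <- a * M * D^2 - 2 * Kf * D - Kf * radio$theta_late
  stopifnot(abs(resid) < 1e-10 * max(1, a * M * D^2))
  D
}

#' Poisson tumor control probability
#'
#' `TCP = exp(-N S_v)` with `N = density * volume` clonogenic cells and
#' survival probability `S_v = exp(-alpha_s BED_can)`.
#'
#' @param radio a [radio_params()] object.
#' @param density clonogenic CSC density (cell/mm^3).
#' @param volume tumor volume (mm^3).
#' @param n,dose,T fractionation entering [bed_cancer()].
#' @return A list with `tcp`, `survival` (`S_v`), `N` and `bed_can`.
#' @examples
#' tcp(radio_params(dose = 1), density = 0.000805, volume = 80000)$tcp
#' @export
tcp <- function(radio, density = 0.000805, volume = 80000,
                n = radio$n_per_day, dose = radio$dose, T = radio$T) {
  stopifnot(inherits(radio, "radio_params"))
  N <- density * volume
  if (N < 0) stop("N must be >= 0", call. = FALSE)
  bed <- bed_cancer(radio, n = n, dose = dose, T = T)
  Sv <- exp(-radio$alpha_s * bed)
  list(tcp = exp(-N * Sv), survival = Sv, N = N, bed_can = bed)
}

#' TCP dose-response table
#'
#' Evaluates [tcp()] on a grid of doses per fraction for one or more
#' tumor volumes.
#'
#' @param radio a [radio_params()] object.
#' @param doses dose-per-fraction grid (Gy).
#' @param volumes tumor volumes (mm^3).
#' @param density clonogenic CSC density (cell/mm^3).
#' @return Data frame with columns `dose`, `volume`, `tcp`, `survival`,
#'   `bed_can`.
#' @export
tcp_curve <- function(radio, doses = seq(0, 2, by = 0.01),
                      volumes = c(80000, 250000), density = 0.000805) {
  out <- expand.grid(dose = doses, volume = volumes)
  res <- mapply(function(d, v) {
    tc <- tcp(radio, density = density, volume = v, dose = d)
    c(tc$tcp, tc$survival, tc$bed_can)
  }, out$dose, out$volume)
  out$tcp <- res[1, ]
  out$survival <- res[2, ]
  out$bed_can <- res[3, ]
  out
}

#' Sensitivity of the optimum dose and tumor BED to schedule conventions
#'
#' Scans the optimum dose per fraction and the tumor BED at the optimum
#' over fraction durations, inter-fraction intervals, fraction-number
#' conventions and both closed forms of the optimum, holding the
#' radiobiological constants fixed. Useful for assessing how strongly the
#' reported pair depends on scheduling details that the BED formulas do
#' not pin down.
#'
#' @param radio baseline [radio_params()] object.
#' @param tau_r_grid fraction durations to scan (years).
#' @param delta_tau_r_grid inter-fraction intervals to scan (years).
#' @param n_grid fraction numbers entering the BED.
#' @param forms optimum-dose closed forms to scan.
#' @return Data frame with one row per combination: the schedule, `M`,
#'   `D_opt` and `bed_can` at the optimum.
#' @export
bed_sensitivity_scan <- function(radio = radio_params(),
                                 tau_r_grid = c(3e-6, 9e-6, 1.9e-5),
                                 delta_tau_r_grid = c(4.6e-4, 6.9e-4,
                                                      1.37e-3),
                                 n_grid = c(1, 2, 32),
                                 forms = c("exact", "as-printed")) {
  g <- expand.grid(tau_r = tau_r_grid, delta_tau_r = delta_tau_r_grid,
                   n = n_grid, form = forms,
                   stringsAsFactors = FALSE)
  g <- g[g$delta_tau_r >= g$tau_r, ]
  rows <- lapply(seq_len(nrow(g)), function(i) {
    rp <- radio_params(alpha_s = radio$alpha_s, beta_s = radio$beta_s,
                       delta = radio$delta, mu = radio$mu,
                       dose = radio$dose, n_per_day = radio$n_per_day,
                       tau_r = g$tau_r[i],
                       delta_tau_r = g$delta_tau_r[i], K = radio$K,
                       T_d = radio$T_d, f = radio$f,
                       theta_late = radio$theta_late,
                       theta_can = radio$theta_can, T = radio$T)
    D <- optimum_dose(rp, form = g$form[i])
    data.frame(tau_r = g$tau_r[i], delta_tau_r = g$delta_tau_r[i],
               n = g$n[i], form = g$form[i],
               M = repair_correction_M(rp), D_opt = D,
               bed_can = bed_cancer(rp, n = g$n[i], dose = D))
  })
  do.call(rbind, rows)
}
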