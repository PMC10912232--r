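#' Symmetric self-renewal probability p(D, a)
#'
#' Probability that a CSC mitosis yields two CSCs, activated by the
#' Wnt-beta catenin concentration `a` and inhibited by the differentiated
#' cell concentration `D`:
#' `p = eta * a / ((1 + eta * a) * (1 + psi * D))`.
#' The value lies in `[0, 1)`, increases with `a` and decreases with `D`.
#'
#' @param D differentiated cell concentration (cell/mm^3), `>= 0`.
#' @param a activator concentration (molecule/mm^3), `>= 0`.
#' @param params a [csc_params()] object.
#' @return Numeric vector of probabilities (vectorised over `D` and `a`).
#' @examples
#' p <- csc_params()
#' fraction_p(D = 2, a = 1, params = csc_params(eta = 1, psi = 0.5))
#' @export
fraction_p <- function(D, a, params) {
  stopifnot(inherits(params, "csc_params"))
  if (any(D < 0) || any(a < 0))
    stop("fraction_p requires D >= 0 and a >= 0", call. = FALSE)
  params$eta * a / ((1 + params$eta * a) * (1 + params$psi * D))
}

#' Dedifferentiation rate q(m)
#'
#' Sigmoidal rate at which differentiated cells revert to the stem state,
#' driven by the (delayed) microRNA concentration:
#' `q = q0/2 * (1 + tanh((m - m0) / sigma))`, a value in `(0, q0)`.
#'
#' @param m_delayed microRNA concentration (molecule/mm^3), `>= 0`;
#'   in the dynamical system this is `m(t - tau)`.
#' @param params a [csc_params()] object.
#' @return Numeric vector of rates (year^-1), vectorised over `m_delayed`.
#' @examples
#' dediff_rate_q(0.05, csc_params())  # q0 / 2 at the threshold m0
#' @export
dediff_rate_q <- function(m_delayed, params) {
  stopifnot(inherits(params, "csc_params"))
  if (any(m_delayed < 0))
    stop("dediff_rate_q requires m >= 0", call. = FALSE)
  params$q0 / 2 * (1 + tanh((m_delayed - params$m0) / params$sigma))
}

as_cell_state <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) && length(x) == 4L) names(x) <- c("S", "D", "a", "m")
  if (!all(c("S", "D", "a", "m") %in% names(x)))
    stop("cell state needs components S, D, a, m", call. = FALSE)
  x <- x[c("S", "D", "a", "m")]
  if (any(x < 0))
    stop("cell state components must be non-negative", call. = FALSE)
  x
}

#' Non-spatial reaction terms of the delayed CSC system
#'
#' Evaluates the four reaction right-hand sides (no diffusion):
#' \deqn{dS/dt = (2 p(D,a) - 1)\,\varepsilon S + q(m_\tau) D_\tau}
#' \deqn{dD/dt = 2 (1 - p(D,a))\,\varepsilon S - (d + q(m)) D}
#' \deqn{da/dt = a(\beta S a/(1+a) - \alpha)}
#' \deqn{dm/dt = \gamma e^{-S/S_0} - \alpha m}
#' where \eqn{m_\tau, D_\tau} are the delayed values supplied through
#' `delayed` (only its `D` and `m` components are used).
#'
#' @param state current state: named vector/list with `S`, `D`, `a`, `m`.
#' @param delayed state at `t - tau`; defaults to `state` (no delay).
#' @param params a [csc_params()] object.
#' @return Named numeric vector of derivatives `c(S, D, a, m)`.
#' @examples
#' eq <- equilibrium_E2(csc_params(), m2 = e2_consistent_m2(csc_params()))
#' reaction_rhs(eq$state, params = csc_params())  # ~ 0
#' @export
reaction_rhs <- function(state, delayed = state, params) {
  stopifnot(inherits(params, "csc_params"))
  s <- as_cell_state(state)
  sl <- as_cell_state(delayed)
  p <- fraction_p(s[["D"]], s[["a"]], params)
  dS <- (2 * p - 1) * params$epsilon * s[["S"]] +
    dediff_rate_q(sl[["m"]], params) * sl[["D"]]
  dD <- 2 * (1 - p) * params$epsilon * s[["S"]] -
    (params$d + dediff_rate_q(s[["m"]], params)) * s[["D"]]
  da <- s[["a"]] * (params$beta * s[["S"]] * s[["a"]] / (1 + s[["a"]]) -
                      params$alpha)
  dm <- params$gamma * exp(-s[["S"]] / params$S0) - params$alpha * s[["m"]]
  c(S = dS, D = dD, a = da, m = dm)
}

new_equilibrium <- function(label, state, free_parameter, stable, params) {
  res <- reaction_rhs(state, state, params)
  structure(list(label = label, state = state,
                 free_parameter = free_parameter, stable = stable,
                 residual = res),
            class = "csc_equilibrium")
}

#' Equilibria of the non-spatial system
#'
#' The homogeneous system has three families of stationary points:
#' * `E1 = (0, 0, 0, m1)`: tumor-free, inactive activator; `m1` is a free
#'   value (the m-equation is stationary only at `m1 = gamma/alpha`).
#' * `E2 = (S2, D2, 0, m2)` with `S2 = -S0 log(alpha m2 / gamma)` and
#'   `D2 = S2 / d`: active tumor, inactive Wnt-beta activator. The S and D
#'   balance additionally requires the dedifferentiation balance
#'   `q(m2) = d`, i.e. `m2 = ` [e2_consistent_m2()]; for other `m2` the
#'   closed form is stationary in the a and m components only, with
#'   residuals `+(q(m2)-d) D2` in S and `-(q(m2)-d) D2` in D.
#' * `E3 = (S3, D3, a3, m3)`: fully active state with
#'   `S3 = alpha (1 + a3)/(beta a3)`, `D3 = S3/d`,
#'   `m3 = gamma/alpha exp(-S3/S0)` and `a3` the positive root of the
#'   half-activation condition `p(D3, a3) = 1/2` (this closed form
#'   neglects the dedifferentiation influx `q(m3) D3`; the a and m
#'   components are exactly stationary). `E3` is unstable.
#'
#' @param m1,m2 free microRNA value of the respective family; `E2`
#'   requires `0 < m2 < gamma/alpha` so that `S2 > 0`.
#' @param params a [csc_params()] object.
#' @return A `csc_equilibrium` object with elements `label`, `state`,
#'   `free_parameter`, `stable` (`"stable"`, `"unstable"` or
#'   `"conditional"`) and `residual` (the reaction right-hand side at the
#'   point).
#' @examples
#' equilibrium_E2(csc_params(), m2 = 0.08)$state
#' @export
equilibrium_E1 <- function(m1, params) {
  stopifnot(inherits(params, "csc_params"))
  if (m1 < 0) stop("m1 must be >= 0", call. = FALSE)
  st <- c(S = 0, D = 0, a = 0, m = m1)
  new_equilibrium("E1", st, m1, "conditional", params)
}

#' @rdname equilibrium_E1
#' @export
equilibrium_E2 <- function(params, m2 = 0.08) {
  stopifnot(inherits(params, "csc_params"))
  if (m2 <= 0 || m2 >= params$gamma / params$alpha)
    stop("equilibrium leaves the admissible region: need 0 < m2 < ",
         "gamma/alpha = ", format(params$gamma / params$alpha),
         call. = FALSE)
  S2 <- -params$S0 * log(params$alpha * m2 / params$gamma)
  st <- c(S = S2, D = S2 / params$d, a = 0, m = m2)
  stable <- if (e2_stable_at_zero_delay(params, m2)) "conditional"
            else "unstable"
  new_equilibrium("E2", st, m2, stable, params)
}

#' @rdname equilibrium_E1
#' @export
equilibrium_E3 <- function(params) {
  stopifnot(inherits(params, "csc_params"))
  r <- params$psi * params$alpha / (params$d * params$beta)
  if (abs(1 - r) < 1e-12)
    stop("E3 closed form degenerate: psi*alpha/(d*beta) = 1",
         call. = FALSE)
  eta <- params$eta
  pref <- (1 + r * (1 + eta)) / (2 * eta * (1 - r))
  a3 <- pref * (1 + sqrt(1 + 4 * r * eta * (1 - r) /
                           (1 + r * (1 + eta))^2))
  S3 <- params$alpha * (1 + a3) / (params$beta * a3)
  D3 <- S3 / params$d
  m3 <- params$gamma / params$alpha * exp(-S3 / params$S0)
  st <- c(S = S3, D = D3, a = a3, m = m3)
  new_equilibrium("E3", st, NA_real_, "unstable", params)
}

#' Local stability of E2 at zero delay
#'
#' At `tau = 0` the second equilibrium is asymptotically stable exactly
#' when `d < q0` and `m2 < gamma/alpha` (strict inequalities; the
#' boundary cases are classified not stable).
#'
#' @param params a [csc_params()] object.
#' @param m2 free microRNA value of the E2 family.
#' @return `TRUE` or `FALSE`.
#' @export
e2_stable_at_zero_delay <- function(params, m2) {
  stopifnot(inherits(params, "csc_params"))
  params$d < params$q0 && m2 < params$gamma / params$alpha
}

#' @export
print.csc_equilibrium <- function(x, ...) {
  cat("<csc_equilibrium> ", x$label, " (", x$stable, ")\n", sep = "")
  cat("  state:   ", paste(names(x$state),
                           format(x$state, digits = 7), sep = " = ",
                           collapse = ", "), "\n")
  cat("  max |residual|:", format(max(abs(x$residual)), digits = 4), "\n")
  invisible(x)
}
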