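# Linear stability of E2 with delay and diffusion: characteristic
# coefficients, purely imaginary crossings, delay branches, transversality
# and the minimal critical delay.

# -- small dense polynomial helpers (coefficients ascending in lambda) ----

pmul <- function(p, q) {
  r <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p))
    r[i:(i + length(q) - 1L)] <- r[i:(i + length(q) - 1L)] + p[i] * q
  r
}

padd <- function(p, q) {
  n <- max(length(p), length(q))
  c(p, numeric(n - length(p))) + c(q, numeric(n - length(q)))
}

peval <- function(p, x) {
  # Horner; works for complex x
  r <- 0 * x + p[length(p)]
  for (i in rev(seq_len(length(p) - 1L))) r <- r * x + p[i]
  r
}

# determinant of a 3x3 matrix of polynomials (list-matrix, ascending coefs)
pdet3 <- function(P) {
  s <- function(i, j, k) pmul(P[[1, i]], pmul(P[[2, j]], P[[3, k]]))
  Reduce(padd, list(s(1, 2, 3), s(2, 3, 1), s(3, 1, 2),
                    -1 * s(3, 2, 1), -1 * s(1, 3, 2), -1 * s(2, 1, 3)))
}

#' Linearization of the delayed system at E2
#'
#' Builds the instantaneous part `A` and the delayed part `B` of the
#' spatial-mode linearization at the second equilibrium, so that the
#' characteristic matrix is `A + B exp(-lambda tau) - lambda I` for a
#' perturbation with squared wavenumber `ksq`. The entries follow the
#' dedifferentiation-balance substitution `q(m2) = d`, under which the
#' delayed row-1 entries are `B[1,2] = d` and
#' `B[1,4] = (2 d D2 / sigma)(1 - d/q0)`; diffusion enters the diagonal as
#' `-D k^2`.
#'
#' @param params a [csc_params()] object.
#' @param m2 free microRNA value of the E2 family (`0 < m2 < gamma/alpha`).
#' @param ksq squared wavenumber `k^2` (mm^-2) of the spatial mode.
#' @return A list with matrices `A` and `B` (4x4), plus `ksq`, `m2` and
#'   the equilibrium components `S2`, `D2`.
#' @examples
#' J <- jacobian_at_E2(cancer_params("prostate"), m2 = 0.08, ksq = 0)
#' eigen(J$A + J$B)$values  # spectrum at tau = 0
#' @export
jacobian_at_E2 <- function(params, m2 = 0.08, ksq = 0) {
  stopifnot(inherits(params, "csc_params"), ksq >= 0)
  if (m2 <= 0 || m2 >= params$gamma / params$alpha)
    stop("invalid E2: need 0 < m2 < gamma/alpha", call. = FALSE)
  S2 <- -params$S0 * log(params$alpha * m2 / params$gamma)
  D2 <- S2 / params$d
  w <- (2 * params$d * D2 / params$sigma) * (1 - params$d / params$q0)
  A <- matrix(0, 4, 4)
  B <- matrix(0, 4, 4)
  A[1, 1] <- -params$epsilon - params$DS * ksq
  A[1, 3] <- 2 * S2 * params$eta / (1 + params$psi * D2)
  B[1, 2] <- params$d
  B[1, 4] <- w
  A[2, 1] <- 2 * params$epsilon
  A[2, 2] <- -2 * params$d - params$DD * ksq
  A[2, 3] <- -A[1, 3]
  A[2, 4] <- -w
  A[3, 3] <- -params$alpha - params$Da * ksq
  A[4, 1] <- -(params$alpha / params$S0) * m2
  A[4, 4] <- -params$alpha - params$Dm * ksq
  list(A = A, B = B, ksq = ksq, m2 = m2, S2 = S2, D2 = D2)
}

#' Characteristic-equation coefficients from the linearization matrices
#'
#' Expands `det(A + B e^{-lambda tau} - lambda I)` exactly into
#' `lambda^4 + C11 lambda^3 + C22 lambda^2 + C33 lambda + C44 +
#' (E11 lambda^2 + E22 lambda + E33) e^{-lambda tau}`. The delayed part
#' `B` must be confined to row 1 (as it is for this model), so that no
#' `e^{-2 lambda tau}` terms arise.
#'
#' @param A,B instantaneous and delayed 4x4 matrices, e.g. from
#'   [jacobian_at_E2()].
#' @param ksq squared wavenumber recorded on the result.
#' @return A `char_coeffs` object with elements `C11`, `C22`, `C33`,
#'   `C44`, `E11`, `E22`, `E33`, `ksq`, and the full ascending coefficient
#'   vectors `C_poly` (degree 4, monic) and `E_poly` (degree 2).
#' @export
char_from_matrices <- function(A, B, ksq = 0) {
  stopifnot(is.matrix(A), all(dim(A) == c(4, 4)),
            is.matrix(B), all(dim(B) == c(4, 4)))
  if (any(B[-1, ] != 0))
    stop("delayed part must be confined to row 1", call. = FALSE)
  # entries of A - lambda I as linear polynomials
  P <- matrix(vector("list", 16), 4, 4)
  for (i in 1:4) for (j in 1:4)
    P[[i, j]] <- c(A[i, j], if (i == j) -1 else 0)
  # instantaneous quartic: det(A - lambda I); make it monic (+lambda^4)
  minor <- function(M, i, j) M[-i, -j, drop = FALSE]
  det4 <- function(M) {
    acc <- 0
    for (j in 1:4) {
      term <- pmul(M[[1, j]], pdet3(minor(M, 1, j)))
      acc <- padd(acc, (-1)^(1 + j) * term)
    }
    acc
  }
  C_poly <- det4(P)                       # already monic: (-lambda)^4
  # delayed part: row 1 replaced by B's (constant) row 1
  E_poly <- 0
  for (j in 1:4) {
    if (B[1, j] == 0) next
    term <- B[1, j] * (-1)^(1 + j) * pdet3(minor(P, 1, j))
    E_poly <- padd(E_poly, term)
  }
  E_poly <- c(E_poly, numeric(4 - length(E_poly)))[1:4]
  if (abs(E_poly[4]) > 1e-10 * max(1, max(abs(E_poly))))
    stop("delayed part has unexpected cubic term", call. = FALSE)
  structure(list(C11 = C_poly[4], C22 = C_poly[3], C33 = C_poly[2],
                 C44 = C_poly[1], E11 = E_poly[3], E22 = E_poly[2],
                 E33 = E_poly[1], ksq = ksq,
                 C_poly = C_poly, E_poly = E_poly[1:3]),
            class = "char_coeffs")
}

#' @rdname char_from_matrices
#' @param params a [csc_params()] object.
#' @param m2 free microRNA value of the E2 family.
#' @examples
#' cf <- char_coefficients(cancer_params("breast"), m2 = 0.08, ksq = 0)
#' cf$C44^2 - cf$E33^2  # sign controls existence of a low-frequency crossing
#' @export
char_coefficients <- function(params, m2 = 0.08, ksq = 0) {
  J <- jacobian_at_E2(params, m2, ksq)
  char_from_matrices(J$A, J$B, ksq = ksq)
}

#' Evaluate the transcendental characteristic function
#'
#' @param coeffs a `char_coeffs` object.
#' @param lambda complex (or real) argument.
#' @param tau delay (years).
#' @return Complex value of
#'   `lambda^4 + C11 lambda^3 + ... + C44 + (E11 lambda^2 + E22 lambda +
#'   E33) e^{-lambda tau}`.
#' @export
char_poly <- function(coeffs, lambda, tau) {
  stopifnot(inherits(coeffs, "char_coeffs"))
  peval(coeffs$C_poly, lambda) +
    peval(coeffs$E_poly, lambda) * exp(-lambda * tau)
}

#' Positive frequencies of purely imaginary characteristic roots
#'
#' A purely imaginary root `i omega` exists for some delay exactly when
#' `omega^2` is a positive real root of the quartic
#' `z^4 + (C11^2 - 2 C22) z^3 + (C22^2 + 2 C44 - 2 C11 C33 - E11^2) z^2 +
#' (C33^2 + 2 E11 E33 - 2 C22 C44 - E22^2) z + (C44^2 - E33^2) = 0`,
#' solved here through the eigenvalues of its companion matrix. An empty
#' result means no Hopf crossing exists at this spatial mode for any
#' delay.
#'
#' @param coeffs a `char_coeffs` object.
#' @param tol_im relative tolerance on the imaginary part for accepting a
#'   root of the z-quartic as real.
#' @param tol_pos absolute threshold below which a real root is treated
#'   as zero (rejected).
#' @return Sorted numeric vector of positive `omega` (year^-1); possibly
#'   empty.
#' @export
omega_roots <- function(coeffs, tol_im = 1e-9, tol_pos = 1e-12) {
  stopifnot(inherits(coeffs, "char_coeffs"))
  zc <- omega_poly(coeffs)
  # companion matrix of the monic quartic in z
  n <- length(zc) - 1L
  Cm <- matrix(0, n, n)
  if (n > 1) Cm[cbind(2:n, 1:(n - 1))] <- 1
  Cm[, n] <- -zc[1:n]
  z <- eigen(Cm, only.values = TRUE)$values
  keep <- abs(Im(z)) < tol_im * pmax(1, Mod(z)) & Re(z) > tol_pos
  sort(sqrt(Re(z[keep])))
}

# ascending coefficients of the quartic in z = omega^2 (monic)
omega_poly <- function(cf) {
  c(cf$C44^2 - cf$E33^2,
    cf$C33^2 + 2 * cf$E11 * cf$E33 - 2 * cf$C22 * cf$C44 - cf$E22^2,
    cf$C22^2 + 2 * cf$C44 - 2 * cf$C11 * cf$C33 - cf$E11^2,
    cf$C11^2 - 2 * cf$C22,
    1)
}

# numerators Z11 (sin) and Z22 (cos) and their common denominator.
# With A = E33 - E11 w^2, B = E22 w, R1 = C22 w^2 - C44 - w^4 and
# R2 = C11 w^3 - C33 w, the crossing conditions A cos + B sin = R1,
# B cos - A sin = R2 solve to cos = (A R1 + B R2) / (A^2 + B^2) and
# sin = (B R1 - A R2) / (A^2 + B^2). (Some published statements of the
# sin numerator carry "+ A R2", which does not satisfy the crossing
# conditions; the back-substitution tests pin the sign down.)
crossing_trig <- function(cf, omega) {
  om <- omega
  A <- cf$E33 - cf$E11 * om^2
  B <- cf$E22 * om
  R1 <- cf$C22 * om^2 - cf$C44 - om^4
  R2 <- cf$C11 * om^3 - cf$C33 * om
  den <- A^2 + B^2
  list(Z11 = B * R1 - A * R2, Z22 = A * R1 + B * R2, den = den,
       cos = (A * R1 + B * R2) / den, sin = (B * R1 - A * R2) / den)
}

#' Delay branches of a purely imaginary crossing
#'
#' For a frequency `omega` returned by [omega_roots()], the delays at
#' which `i omega` is a characteristic root are
#' `tau_j = theta / omega + 2 pi j / omega`, where `theta` is the unique
#' angle in `[0, 2 pi)` with `cos(theta)` and `sin(theta)` given by the
#' crossing conditions. The angle is resolved with a two-argument
#' arctangent, which agrees with the three printed quadrant cases of the
#' branch formula and covers the fourth quadrant consistently.
#'
#' @param coeffs a `char_coeffs` object.
#' @param omega positive crossing frequency (year^-1).
#' @param j_max highest branch index `j` (branches `0..j_max`).
#' @return Numeric vector of delays (years), one per branch.
#' @export
critical_delays <- function(coeffs, omega, j_max = 0) {
  stopifnot(inherits(coeffs, "char_coeffs"), omega > 0)
  tr <- crossing_trig(coeffs, omega)
  if (tr$den == 0)
    stop("degenerate coefficients: zero crossing denominator",
         call. = FALSE)
  theta <- atan2(tr$Z11, tr$Z22) %% (2 * pi)
  theta / omega + 2 * pi * (0:j_max) / omega
}

#' Transversality of a crossing
#'
#' Sign of `d Re(lambda)/d tau` at a purely imaginary crossing
#' `(i omega, tau)`, computed from the closed-form real/imaginary parts
#' of the derivative of the characteristic function. `+1` means the root
#' pair genuinely crosses into the right half-plane (destabilisation).
#'
#' @param coeffs a `char_coeffs` object.
#' @param omega crossing frequency (year^-1).
#' @param tau_c crossing delay (years).
#' @return `+1` or `-1`.
#' @export
transversality <- function(coeffs, omega, tau_c) {
  stopifnot(inherits(coeffs, "char_coeffs"), omega > 0, tau_c >= 0)
  ct <- cos(omega * tau_c)
  st <- sin(omega * tau_c)
  BR <- -coeffs$E22 * omega^2 * ct +
    (-coeffs$E11 * omega^3 + coeffs$E33 * omega) * st
  BI <- (coeffs$E33 * omega - coeffs$E11 * omega^3) * ct +
    coeffs$E22 * omega^2 * st
  AR <- coeffs$E22 * ct - 3 * coeffs$C11 * omega^2 +
    2 * coeffs$E11 * omega * st + coeffs$C33
  AI <- -4 * omega^3 + 2 * coeffs$E11 * omega * ct +
    2 * coeffs$C22 * omega - coeffs$E22 * st
  if (BR == 0 && BI == 0)
    stop("degenerate crossing: B-tilde vanishes", call. = FALSE)
  s <- sign(AR * BR + AI * BI)
  if (s == 0) stop("transversality is zero (tangent crossing)",
                   call. = FALSE)
  s
}

#' Newton refinement of a characteristic root
#'
#' Refines a characteristic root of the delayed equation near a starting
#' guess, used to continue the rightmost root in the delay.
#'
#' @param coeffs a `char_coeffs` object.
#' @param tau delay (years).
#' @param lambda0 complex starting guess.
#' @param tol convergence tolerance on `|char_poly|`.
#' @param max_iter Newton iteration cap.
#' @return Complex root.
#' @export
char_root_near <- function(coeffs, tau, lambda0, tol = 1e-12,
                           max_iter = 100) {
  l <- as.complex(lambda0)
  dC <- coeffs$C_poly[-1] * seq_len(4)
  dE <- coeffs$E_poly[-1] * seq_len(2)
  for (i in seq_len(max_iter)) {
    e <- exp(-l * tau)
    f <- peval(coeffs$C_poly, l) + peval(coeffs$E_poly, l) * e
    if (Mod(f) < tol) break
    fp <- peval(dC, l) +
      (peval(dE, l) - tau * peval(coeffs$E_poly, l)) * e
    l <- l - f / fp
  }
  l
}

#' Zero-flux spatial modes of a square domain
#'
#' Squared wavenumbers `k^2 = (pi nx / L)^2 + (pi ny / L)^2` admissible
#' under zero-flux boundary conditions on an `L x L` domain, including
#' the homogeneous mode `k = 0`, sorted ascending.
#'
#' @param L domain side (mm).
#' @param n_modes number of distinct nonzero `k^2` values to include.
#' @return Numeric vector of `k^2` values (mm^-2), starting at 0.
#' @export
zero_flux_modes <- function(L = 100, n_modes = 10) {
  n <- ceiling(sqrt(n_modes)) + 2
  g <- expand.grid(nx = 0:n, ny = 0:n)
  ks <- sort(unique((pi * g$nx / L)^2 + (pi * g$ny / L)^2))
  c(0, ks[ks > 0][seq_len(n_modes)])
}

#' Minimal critical delay over spatial modes
#'
#' For each squared wavenumber in `ksq_modes`, computes all purely
#' imaginary crossings (frequencies from [omega_roots()], first-branch
#' delays from [critical_delays()]) and keeps those with positive
#' transversality. The critical delay `tau_c` is the minimum admissible
#' delay over all modes; at `tau = tau_c` the equilibrium loses stability
#' through a Hopf bifurcation. When no mode admits a crossing the
#' equilibrium is stable for every delay and `tau_c` is `NA` (reported in
#' the `message` element).
#'
#' @param params a [csc_params()] object.
#' @param m2 free microRNA value of the E2 family.
#' @param ksq_modes squared wavenumbers to scan; defaults to the
#'   homogeneous mode plus the ten lowest zero-flux modes of a
#'   100 mm x 100 mm domain.
#' @param j_max highest delay-branch index to record per frequency.
#' @return A `hopf_result` object: data frame `crossings` (columns `ksq`,
#'   `omega`, `tau0`, `sign`), list columns of all `tau_branches`, the
#'   minimal admissible delay `tau_c`, `omega_at_min`, `ksq_at_min` and a
#'   `message`.
#' @examples
#' critical_delay(cancer_params("prostate"), m2 = 0.08)
#' @export
critical_delay <- function(params, m2 = 0.08,
                           ksq_modes = zero_flux_modes(), j_max = 0) {
  stopifnot(inherits(params, "csc_params"))
  if (!e2_stable_at_zero_delay(params, m2))
    stop("E2 is not stable at tau = 0 for this parameter set",
         call. = FALSE)
  rows <- list()
  branches <- list()
  for (ksq in ksq_modes) {
    cf <- char_coefficients(params, m2, ksq)
    for (om in omega_roots(cf)) {
      taus <- critical_delays(cf, om, j_max = j_max)
      sg <- transversality(cf, om, taus[1])
      rows[[length(rows) + 1L]] <-
        data.frame(ksq = ksq, omega = om, tau0 = taus[1], sign = sg)
      branches[[length(branches) + 1L]] <- taus
    }
  }
  crossings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ksq = numeric(), omega = numeric(), tau0 = numeric(),
               sign = numeric())
  adm <- crossings[crossings$sign > 0, , drop = FALSE]
  if (nrow(adm)) {
    i <- which.min(adm$tau0)
    tau_c <- adm$tau0[i]
    res <- list(crossings = crossings, tau_branches = branches,
                tau_c = tau_c, omega_at_min = adm$omega[i],
                ksq_at_min = adm$ksq[i],
                message = sprintf(
                  "Hopf bifurcation at tau_c = %.4f yr (omega = %.4f, k^2 = %.4g)",
                  tau_c, adm$omega[i], adm$ksq[i]))
  } else {
    res <- list(crossings = crossings, tau_branches = branches,
                tau_c = NA_real_, omega_at_min = NA_real_,
                ksq_at_min = NA_real_,
                message = paste(
                  "no Hopf bifurcation for this parameter set:",
                  "no admissible purely imaginary crossing at any",
                  "scanned mode (delay-independent stability)"))
  }
  structure(res, class = "hopf_result")
}

#' @export
print.hopf_result <- function(x, ...) {
  cat("<hopf_result>\n  ", x$message, "\n", sep = "")
  if (nrow(x$crossings)) {
    cat("  crossings:\n")
    print(x$crossings, row.names = FALSE)
  }
  invisible(x)
}
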