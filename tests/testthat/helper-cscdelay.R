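# shared fixtures and small independent oracles

prostate <- function(...) cancer_params("prostate", ...)
lung <- function(...) cancer_params("lung", ...)
breast <- function(...) cancer_params("breast", ...)

# determinant of a complex matrix via LU with partial pivoting
# (base det() does not handle complex input); independent oracle for the
# characteristic-polynomial tests
cdet <- function(M) {
  n <- nrow(M)
  d <- 1 + 0i
  for (k in seq_len(n)) {
    p <- which.max(Mod(M[k:n, k])) + k - 1L
    if (p != k) {
      M[c(k, p), ] <- M[c(p, k), ]
      d <- -d
    }
    d <- d * M[k, k]
    if (k < n)
      for (i in (k + 1L):n)
        M[i, ] <- M[i, ] - M[i, k] / M[k, k] * M[k, ]
  }
  d
}

# polynomial division remainder: p (ascending) divided by (x + r)
lin_div_remainder <- function(p, r) {
  # synthetic division by root -r
  acc <- 0
  for (c in rev(p)) acc <- acc * (-r) + c
  acc
}

# smallest admissible crossing delay at one mode, found independently of
# omega_roots()/critical_delays(): dense grid + uniroot on the modulus
# condition |P0(i w)|^2 - |P1(i w)|^2, then the angle of -P0/P1
modulus_tau0 <- function(cf, omega_max = 50, n_grid = 20000) {
  pev <- function(p, x) {
    r <- 0 * x + p[length(p)]
    for (i in rev(seq_len(length(p) - 1L))) r <- r * x + p[i]
    r
  }
  F <- function(om) Mod(pev(cf$C_poly, 1i * om))^2 -
    Mod(pev(cf$E_poly, 1i * om))^2
  oms <- seq(1e-4, omega_max, length.out = n_grid)
  Fv <- vapply(oms, F, numeric(1))
  idx <- which(Fv[-1] * Fv[-length(Fv)] < 0)
  best <- Inf
  for (i in idx) {
    om <- uniroot(F, c(oms[i], oms[i + 1]), tol = 1e-13)$root
    R <- -pev(cf$C_poly, 1i * om) / pev(cf$E_poly, 1i * om)
    tau <- (-Arg(R)) %% (2 * pi) / om
    if (tau < best) best <- tau
  }
  best
}
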