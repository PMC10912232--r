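# Method-of-lines integration of the delayed reaction-diffusion system:
# 5-point zero-flux Laplacian, classical RK4 with cubic Hermite history
# interpolation, probe series and pattern snapshots.

#' Simulation grid
#'
#' Cell-centred square grid on the domain `(0, L) x (0, L)` with zero-flux
#' (Neumann) boundaries. Either the space step `dx` or the number of cells
#' per side `nx` can be given.
#'
#' @param L domain side (mm).
#' @param dx space step (mm); ignored when `nx` is given.
#' @param nx,ny number of cells per side (optional; `ny` defaults to
#'   `nx`).
#' @return A `sim_grid` object with `L`, `dx`, `dy`, `nx`, `ny`, the cell
#'   centre coordinates `x`, `y`, and `boundary = "zero-flux"`.
#' @examples
#' g <- sim_grid(L = 100, dx = 0.2)   # the full published grid
#' g64 <- sim_grid(L = 100, nx = 64)  # reduced grid for quick runs
#' @export
sim_grid <- function(L = 100, dx = 0.2, nx = NULL, ny = nx) {
  stopifnot(L > 0)
  if (is.null(nx)) {
    nx <- round(L / dx)
    ny <- nx
  }
  stopifnot(nx >= 1, ny >= 1)
  dx <- L / nx
  dy <- L / ny
  structure(list(L = L, dx = dx, dy = dy, nx = as.integer(nx),
                 ny = as.integer(ny),
                 x = (seq_len(nx) - 0.5) * dx,
                 y = (seq_len(ny) - 0.5) * dy,
                 boundary = "zero-flux"),
            class = "sim_grid")
}

#' Discrete Laplacian with zero-flux boundaries
#'
#' Second-order 5-point stencil; the no-flux condition is imposed by
#' ghost-cell reflection (the ghost cell mirrors the boundary cell), which
#' makes the operator exactly conservative: the sum of the Laplacian over
#' all cells is zero for any field.
#'
#' @param field numeric matrix (`nx` x `ny`).
#' @param grid a [sim_grid()] object matching `field`.
#' @return Matrix of the same shape.
#' @export
laplacian <- function(field, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  if (!is.matrix(field) || nrow(field) != grid$nx ||
      ncol(field) != grid$ny)
    stop("field shape does not match grid", call. = FALSE)
  nx <- grid$nx
  ny <- grid$ny
  xm <- field[c(1L, seq_len(nx - 1L)), , drop = FALSE]
  xp <- field[c(seq_len(nx)[-1L], nx), , drop = FALSE]
  ym <- field[, c(1L, seq_len(ny - 1L)), drop = FALSE]
  yp <- field[, c(seq_len(ny)[-1L], ny), drop = FALSE]
  (xm + xp - 2 * field) / grid$dx^2 + (ym + yp - 2 * field) / grid$dy^2
}

#' Initial perturbation fields around the E2 equilibrium
#'
#' Evaluates the published trigonometric perturbation formulas at
#' arbitrary coordinates, anchored at an equilibrium tuple
#' `(S2, D2, a2, m2)`:
#' \deqn{S = S_2 - 0.1\cos((x^2+y^2)\pi - 0.01\sin((x^2+y^2)\pi))}
#' \deqn{D = D_2 - 0.0002\cos(\sqrt{x^2+y^2}\,\pi +
#'   0.0003\sin(\sqrt{x^2+y^2}\,\pi))}
#' \deqn{a = a_2 + 0.002\cos^2(x+2) + 0.001\sin^2(y+4)}
#' \deqn{m = m_2 + 0.001\cos^2(x-2) + 0.001\sin^2(y-4)}
#' (the nesting of the S and D formulas follows the printed expressions
#' literally). Negative values are clamped to zero for admissibility.
#'
#' @param x,y coordinates (mm); recycled against each other.
#' @param anchor named numeric `c(S, D, a, m)` equilibrium tuple.
#' @return A list of numeric vectors `S`, `D`, `a`, `m`.
#' @export
ic_fields <- function(x, y, anchor) {
  anchor <- as_cell_state(anchor)
  r2 <- x^2 + y^2
  list(
    S = pmax(anchor[["S"]] -
               0.1 * cos(r2 * pi - 0.01 * sin(r2 * pi)), 0),
    D = pmax(anchor[["D"]] -
               2e-4 * cos(sqrt(r2) * pi + 3e-4 * sin(sqrt(r2) * pi)), 0),
    a = pmax(anchor[["a"]] +
               0.002 * cos(x + 2)^2 + 0.001 * sin(y + 4)^2, 0),
    m = pmax(anchor[["m"]] +
               0.001 * cos(x - 2)^2 + 0.001 * sin(y - 4)^2, 0))
}

#' Initial condition on a grid
#'
#' Evaluates [ic_fields()] on the grid's cell centres, anchored by default
#' at the closed-form E2 equilibrium for the given `m2`.
#'
#' @param grid a [sim_grid()] object.
#' @param params a [csc_params()] object.
#' @param m2 free microRNA value of the E2 family.
#' @param anchor optional explicit `c(S, D, a, m)` anchor tuple.
#' @return A `field_state` object: matrices `S`, `D`, `a`, `m` plus `t`
#'   and the grid.
#' @export
initial_condition <- function(grid, params, m2 = 0.08, anchor = NULL) {
  stopifnot(inherits(grid, "sim_grid"))
  if (is.null(anchor)) anchor <- equilibrium_E2(params, m2)$state
  X <- matrix(grid$x, grid$nx, grid$ny)
  Y <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  f <- ic_fields(as.vector(X), as.vector(Y), anchor)
  field_state(lapply(f, matrix, nrow = grid$nx, ncol = grid$ny),
              t = 0, grid = grid)
}

field_state <- function(fields, t, grid) {
  structure(list(S = fields$S, D = fields$D, a = fields$a, m = fields$m,
                 t = t, grid = grid),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat("<field_state> t =", format(x$t), " grid",
      x$grid$nx, "x", x$grid$ny, "\n")
  for (f in c("S", "D", "a", "m"))
    cat(sprintf("  %s: min %.4g  mean %.4g  max %.4g\n", f,
                min(x[[f]]), mean(x[[f]]), max(x[[f]])))
  invisible(x)
}

#' Fixed-step RK4 integrator for delay differential equations
#'
#' Classical fourth-order Runge-Kutta on a (possibly large) state vector,
#' with the delayed values obtained by cubic Hermite interpolation on the
#' stored solution history (values plus stage-consistent derivatives).
#' The history is initialised constant at `y0` for `t <= 0`. Only the
#' components listed in `lag_idx` are stored and interpolated, which
#' keeps the memory of the delay horizon small.
#'
#' @param rhs function `rhs(t, y, ylag)` returning the full derivative
#'   vector; `ylag` holds `y[lag_idx]` evaluated at `t - tau`.
#' @param y0 initial state vector.
#' @param tau delay (years); either 0 or at least `dt`.
#' @param dt time step.
#' @param t_end final time (integrated over `round(t_end/dt)` steps).
#' @param lag_idx indices of the components whose history is needed.
#' @param observer optional `observer(step, t, y)` called at `t = 0` and
#'   after every accepted step (for probes/snapshots).
#' @param check_every finiteness check interval (steps); a non-finite
#'   state aborts with a diagnostic.
#' @return The final state vector (invisibly also delivered through the
#'   observer).
#' @export
dde_rk4 <- function(rhs, y0, tau, dt, t_end,
                    lag_idx = seq_along(y0), observer = NULL,
                    check_every = 50L) {
  stopifnot(dt > 0, t_end >= 0)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (tau > 0 && tau < dt)
    stop("0 < tau < dt is not supported; decrease dt", call. = FALSE)
  nsteps <- round(t_end / dt)
  y <- y0
  nlag <- length(lag_idx)
  y0lag <- y0[lag_idx]

  cap <- if (tau > 0) ceiling(tau / dt) + 3L else 1L
  V <- matrix(0, nlag, cap)   # history values at nodes
  W <- matrix(0, nlag, cap)   # history derivatives at nodes
  slot <- function(j) (j %% cap) + 1L

  lag_at <- function(s) {
    # solution value at node-time s (in units of dt), s <= current node;
    # the prehistory (s <= 0) is constant at y0
    if (s <= 1e-9) return(y0lag)
    i <- floor(s + 1e-9)
    th <- s - i
    if (th < 1e-9) return(V[, slot(i)])
    v0 <- V[, slot(i)]
    w0 <- W[, slot(i)]
    v1 <- V[, slot(i + 1L)]
    w1 <- W[, slot(i + 1L)]
    h00 <- (1 + 2 * th) * (1 - th)^2
    h10 <- th * (1 - th)^2
    h01 <- th^2 * (3 - 2 * th)
    h11 <- th^2 * (th - 1)
    h00 * v0 + h10 * dt * w0 + h01 * v1 + h11 * dt * w1
  }

  if (!is.null(observer)) observer(0L, 0, y)
  soff <- tau / dt
  for (n in seq_len(nsteps)) {
    t <- (n - 1) * dt
    l0 <- if (tau > 0) lag_at(n - 1 - soff) else NULL
    k1 <- rhs(t, y, if (tau > 0) l0 else y[lag_idx])
    if (tau > 0) {
      V[, slot(n - 1L)] <- y[lag_idx]
      W[, slot(n - 1L)] <- k1[lag_idx]
    }
    if (tau > 0) {
      lh <- lag_at(n - 0.5 - soff)
      l1 <- lag_at(n - soff)
    }
    y2 <- y + dt / 2 * k1
    k2 <- rhs(t + dt / 2, y2, if (tau > 0) lh else y2[lag_idx])
    y3 <- y + dt / 2 * k2
    k3 <- rhs(t + dt / 2, y3, if (tau > 0) lh else y3[lag_idx])
    y4 <- y + dt * k3
    k4 <- rhs(t + dt, y4, if (tau > 0) l1 else y4[lag_idx])
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (n %% check_every == 0L && any(!is.finite(y)))
      stop(sprintf(
        "non-finite state at t = %.4f (blow-up or dt too large)",
        n * dt), call. = FALSE)
    if (!is.null(observer)) observer(n, n * dt, y)
  }
  if (any(!is.finite(y)))
    stop("non-finite state at the final time", call. = FALSE)
  y
}

#' Simulate the delayed CSC reaction-diffusion system
#'
#' Method-of-lines integration of the four-field system on a zero-flux
#' grid, optionally coupled to a fractionated-radiotherapy kill term
#' `-delta R_eff K_R(t) S` in the S equation. Spatially uniform (0-D)
#' dynamics are obtained with a 1x1 grid. The run is fully deterministic.
#'
#' @param params a [csc_params()] object (its `tau` is the delay used).
#' @param grid a [sim_grid()] object; defaults to a 64x64 reduction of
#'   the 100 mm domain.
#' @param m2 microRNA level anchoring the initial condition.
#' @param t_end final time (years).
#' @param dt time step (years); must respect the explicit diffusion
#'   stability bound `dt <= dx^2 / (4 max(D))`.
#' @param init optional `field_state` initial condition; defaults to
#'   [initial_condition()].
#' @param record_times times (years) at which full field snapshots are
#'   kept.
#' @param probe cell index `c(i, j)` for the probe time series; defaults
#'   to the central cell.
#' @param radio optional [radio_params()] object switching radiotherapy
#'   on.
#' @param rt_start radiotherapy start time (years).
#' @param rt_duration length of the treatment course (years); `Inf`
#'   treats until `t_end`.
#' @param reaction,diffusion logical switches for the reaction and
#'   diffusion terms (diagnostics / conservation tests).
#' @return A `csc_sim` object: `series` (data frame with probe values and
#'   spatial means per step), `snapshots` (list of `field_state`),
#'   `final` state, `diagnostics` (per-field minima and totals), and the
#'   resolved configuration.
#' @examples
#' p <- cancer_params("prostate", tau = 0)
#' s <- simulate_csc(p, grid = sim_grid(L = 100, nx = 1), t_end = 1)
#' tail(s$series, 3)
#' @export
simulate_csc <- function(params, grid = sim_grid(L = 100, nx = 64),
                         m2 = 0.08, t_end = 16, dt = 0.01, init = NULL,
                         record_times = numeric(),
                         probe = NULL, radio = NULL, rt_start = 0,
                         rt_duration = Inf,
                         reaction = TRUE, diffusion = TRUE) {
  stopifnot(inherits(params, "csc_params"), inherits(grid, "sim_grid"))
  dmax <- max(params$DS, params$DD, params$Da, params$Dm)
  if (diffusion && grid$nx > 1 &&
      dt > min(grid$dx, grid$dy)^2 / (4 * dmax))
    stop(sprintf(
      "dt = %g violates the diffusion stability bound dx^2/(4 Dmax) = %g",
      dt, min(grid$dx, grid$dy)^2 / (4 * dmax)), call. = FALSE)
  if (is.null(init)) init <- initial_condition(grid, params, m2)
  if (is.null(probe)) probe <- c(max(1L, grid$nx %/% 2L),
                                 max(1L, grid$ny %/% 2L))
  nn <- grid$nx * grid$ny
  iS <- seq_len(nn)
  iD <- nn + iS
  ia <- 2L * nn + iS
  im <- 3L * nn + iS
  y0 <- c(init$S, init$D, init$a, init$m)
  ip <- (probe[2] - 1L) * grid$nx + probe[1]

  reff <- if (!is.null(radio)) effective_radiation(radio) else 0
  use_rt <- !is.null(radio) && radio$delta > 0 && reff > 0

  p <- params
  rhs <- function(t, y, ylag) {
    S <- y[iS]; D <- y[iD]; a <- y[ia]; m <- y[im]
    Dl <- ylag[seq_len(nn)]
    ml <- ylag[nn + seq_len(nn)]
    if (reaction) {
      pv <- p$eta * a / ((1 + p$eta * a) * (1 + p$psi * D))
      ql <- p$q0 / 2 * (1 + tanh((ml - p$m0) / p$sigma))
      qv <- p$q0 / 2 * (1 + tanh((m - p$m0) / p$sigma))
      dS <- (2 * pv - 1) * p$epsilon * S + ql * Dl
      dD <- 2 * (1 - pv) * p$epsilon * S - (p$d + qv) * D
      da <- a * (p$beta * S * a / (1 + a) - p$alpha)
      dm <- p$gamma * exp(-S / p$S0) - p$alpha * m
    } else {
      dS <- dD <- da <- dm <- numeric(nn)
    }
    if (use_rt)
      dS <- dS - radio$delta * reff *
        radiation_switch(t, radio, t_start = rt_start,
                         duration = rt_duration) * S
    if (diffusion && grid$nx * grid$ny > 1L) {
      dS <- dS + p$DS * laplacian(matrix(S, grid$nx), grid)
      dD <- dD + p$DD * laplacian(matrix(D, grid$nx), grid)
      da <- da + p$Da * laplacian(matrix(a, grid$nx), grid)
      dm <- dm + p$Dm * laplacian(matrix(m, grid$nx), grid)
    }
    c(dS, dD, da, dm)
  }

  nsteps <- round(t_end / dt)
  ser <- matrix(NA_real_, nsteps + 1L, 9L)
  colnames(ser) <- c("t", "S", "D", "a", "m",
                     "S_mean", "D_mean", "a_mean", "m_mean")
  snaps <- vector("list", length(record_times))
  rec_steps <- round(record_times / dt)
  minv <- c(S = Inf, D = Inf, a = Inf, m = Inf)

  observer <- function(n, t, y) {
    ser[n + 1L, ] <<- c(t, y[iS][ip], y[iD][ip], y[ia][ip], y[im][ip],
                        mean(y[iS]), mean(y[iD]), mean(y[ia]),
                        mean(y[im]))
    minv <<- pmin(minv, c(min(y[iS]), min(y[iD]), min(y[ia]),
                          min(y[im])))
    hit <- which(rec_steps == n)
    for (k in hit)
      snaps[[k]] <<- field_state(list(S = matrix(y[iS], grid$nx),
                                      D = matrix(y[iD], grid$nx),
                                      a = matrix(y[ia], grid$nx),
                                      m = matrix(y[im], grid$nx)),
                                 t = t, grid = grid)
  }

  yT <- dde_rk4(rhs, y0, tau = params$tau, dt = dt, t_end = t_end,
                lag_idx = c(iD, im), observer = observer)

  final <- field_state(list(S = matrix(yT[iS], grid$nx),
                            D = matrix(yT[iD], grid$nx),
                            a = matrix(yT[ia], grid$nx),
                            m = matrix(yT[im], grid$nx)),
                       t = nsteps * dt, grid = grid)
  scale <- vapply(c("S", "D", "a", "m"),
                  function(f) max(abs(final[[f]]), 1e-300), numeric(1))
  neg_flag <- any(minv < -1e-8 * scale)
  structure(list(series = as.data.frame(ser), snapshots = snaps,
                 final = final,
                 diagnostics = list(min_values = minv,
                                    negative_flag = neg_flag,
                                    totals0 = c(sum(init$S), sum(init$D),
                                                sum(init$a), sum(init$m)),
                                    totalsT = c(sum(final$S), sum(final$D),
                                                sum(final$a),
                                                sum(final$m))),
                 params = params, radio = radio, grid = grid, dt = dt,
                 m2 = m2, rt_start = rt_start,
                 rt_duration = rt_duration),
            class = "csc_sim")
}

#' @export
print.csc_sim <- function(x, ...) {
  cat("<csc_sim> ", nrow(x$series) - 1L, " steps of dt = ", x$dt,
      " on ", x$grid$nx, "x", x$grid$ny, " grid, tau = ",
      x$params$tau, "\n", sep = "")
  if (!is.null(x$radio))
    cat("  radiotherapy: dose", x$radio$dose, "Gy x",
        x$radio$n_per_day, "/day from t =", x$rt_start, "\n")
  cat("  final means:",
      paste(c("S", "D", "a", "m"),
            format(unlist(x$series[nrow(x$series),
                                   c("S_mean", "D_mean", "a_mean",
                                     "m_mean")]), digits = 4),
            sep = " = ", collapse = ", "), "\n")
  if (isTRUE(x$diagnostics$negative_flag))
    cat("  WARNING: fields dipped significantly below zero",
        "(numerical misconfiguration?)\n")
  invisible(x)
}

#' Spatial summary metrics of a pattern snapshot
#'
#' Quantifies a field snapshot: extrema and mean, centre of mass, a
#' radial profile about the domain centre, the fraction of field variance
#' explained by radius (close to 1 for circularly symmetric patterns) and
#' the localisation radius, defined as the smallest radius around the
#' domain centre containing 90 percent of the field's deviation energy
#' (squared deviation from the spatial mean). A uniform field has zero
#' deviation energy and localisation radius 0 by convention.
#'
#' @param field numeric matrix, or a `field_state` (use `component` to
#'   pick the field).
#' @param grid a [sim_grid()]; taken from the `field_state` if omitted.
#' @param component one of `"S"`, `"D"`, `"a"`, `"m"` when `field` is a
#'   `field_state`.
#' @param energy_fraction quantile of deviation energy defining the
#'   localisation radius.
#' @param n_bins number of radial bins for the profile.
#' @return A list with `min`, `max`, `mean`, `center_of_mass`,
#'   `radial_profile` (data frame `r`, `mean`), `radial_fraction` and
#'   `loc_radius`.
#' @export
pattern_metrics <- function(field, grid = NULL, component = "S",
                            energy_fraction = 0.9, n_bins = 32) {
  if (inherits(field, "field_state")) {
    grid <- field$grid
    field <- field[[component]]
  }
  stopifnot(is.matrix(field), inherits(grid, "sim_grid"))
  X <- matrix(grid$x, grid$nx, grid$ny)
  Y <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  mu <- mean(field)
  w <- abs(field)
  com <- if (sum(w) > 0) c(x = sum(X * w) / sum(w),
                           y = sum(Y * w) / sum(w))
         else c(x = grid$L / 2, y = grid$L / 2)
  r <- sqrt((X - grid$L / 2)^2 + (Y - grid$L / 2)^2)
  dev2 <- (field - mu)^2
  tot <- sum(dev2)
  if (tot < 1e-30) {
    loc <- 0
    radial_fraction <- 0
    prof <- data.frame(r = numeric(), mean = numeric())
  } else {
    o <- order(r)
    cum <- cumsum(dev2[o])
    loc <- r[o][which(cum >= energy_fraction * tot)[1]]
    bins <- cut(r, breaks = n_bins)
    bm <- tapply(field, bins, mean)
    bn <- tapply(field, bins, length)
    ok <- !is.na(bm)
    between <- sum(bn[ok] * (bm[ok] - mu)^2)
    radial_fraction <- between / tot
    br <- tapply(r, bins, mean)
    prof <- data.frame(r = as.numeric(br[ok]), mean = as.numeric(bm[ok]))
  }
  list(min = min(field), max = max(field), mean = mu,
       center_of_mass = com, radial_profile = prof,
       radial_fraction = radial_fraction, loc_radius = loc)
}
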