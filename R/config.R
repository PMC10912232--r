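# Configuration, scenario presets and structured output writers tying
# the model, Hopf analysis, simulator and radiotherapy modules together.

#' Run configuration
#'
#' Bundles a model parameter set, an optional radiotherapy parameter set,
#' a grid and the numerical settings of one run. All fields are
#' validated; omitted keys take the published defaults.
#'
#' @param model a [csc_params()] object or a named list of overrides.
#' @param radio `NULL`, or a [radio_params()] object / named list of
#'   overrides.
#' @param grid a [sim_grid()] object or a named list (`L`, `dx`, `nx`,
#'   `ny`).
#' @param numerics named list: `dt`, `t_end`, `m2`, `record_times`,
#'   `rt_start`, `rt_duration`.
#' @param label free-text scenario label.
#' @return A `run_config` object.
#' @export
run_config <- function(model = list(), radio = NULL, grid = list(),
                       numerics = list(), label = "run") {
  if (!inherits(model, "csc_params")) {
    check_keys(model, names(formals(csc_params)), "model")
    model <- do.call(csc_params, model)
  }
  if (!is.null(radio) && !inherits(radio, "radio_params")) {
    check_keys(radio, names(formals(radio_params)), "radio")
    radio <- do.call(radio_params, radio)
  }
  if (!inherits(grid, "sim_grid")) {
    check_keys(grid, c("L", "dx", "nx", "ny"), "grid")
    grid <- do.call(sim_grid, grid)
  }
  check_keys(numerics, c("dt", "t_end", "m2", "record_times",
                         "rt_start", "rt_duration"), "numerics")
  defaults <- list(dt = 0.01, t_end = 16, m2 = 0.08,
                   record_times = numeric(), rt_start = 0,
                   rt_duration = Inf)
  numerics <- utils::modifyList(defaults, as.list(numerics))
  structure(list(label = label, model = model, radio = radio,
                 grid = grid, numerics = numerics),
            class = "run_config")
}

check_keys <- function(x, allowed, where) {
  x <- as.list(x)
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' The YAML file may contain the sections `label`, `model`, `radio`,
#' `grid` and `numerics`, each holding the keys of the corresponding
#' constructor; omitted keys take the published defaults and unknown
#' keys are rejected with a key-level message. Writing and re-reading a
#' configuration preserves all values.
#'
#' @param path file path.
#' @return `load_config()` returns a validated `run_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, c("label", "model", "radio", "grid", "numerics"),
             "config")
  run_config(model = raw$model %||% list(),
             radio = raw$radio,
             grid = raw$grid %||% list(),
             numerics = raw$numerics %||% list(),
             label = raw$label %||% "run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config a `run_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(label = config$label,
            model = unclass(config$model),
            grid = list(L = config$grid$L, nx = config$grid$nx,
                        ny = config$grid$ny),
            numerics = config$numerics)
  if (!is.null(config$radio)) x$radio <- unclass(config$radio)
  # Inf is not portable YAML; encode open-ended courses as -1
  if (is.infinite(x$numerics$rt_duration)) x$numerics$rt_duration <- -1
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' Built-in scenario presets
#'
#' Named configurations reproducing the published figure and table
#' setups: `table2_prostate`, `table2_lung`, `table2_breast` (critical
#' delay per cancer), `fig3a`/`fig3b` (pattern localisation under small /
#' 10x larger diffusion at `tau = 11.8964`), `fig4` (`tau = 6.8964`),
#' `fig5` (`tau = 14.8964`), `fig7`-`fig9` (radiotherapy time series at
#' doses 0.02, 0.05 and 1.323 Gy per fraction), `fig10`/`fig11`
#' (radiotherapy patterns at 0.02 / 0.05 Gy), and `fig6_tcp` (TCP versus
#' dose for two tumor volumes).
#'
#' @param grid optional [sim_grid()] overriding the preset grids (the
#'   presets default to the full 0.2 mm grid; pass a coarser grid for
#'   quick runs).
#' @return Named list of `run_config` objects.
#' @export
builtin_scenarios <- function(grid = NULL) {
  g <- function() grid %||% sim_grid(L = 100, dx = 0.2)
  slow <- list(DS = 0.0031536, DD = 0.0031536, Da = 0.0365, Dm = 0.0365)
  rt <- function(dose) list(dose = dose, n_per_day = 2, tau_r = 9e-6,
                            delta_tau_r = 6.9e-4)
  sc <- list(
    table2_prostate = run_config(model = list(q0 = 87.6, d = 87.2),
                                 grid = list(nx = 1),
                                 label = "table2_prostate"),
    table2_lung = run_config(model = list(q0 = 109.97, d = 80),
                             grid = list(nx = 1),
                             label = "table2_lung"),
    table2_breast = run_config(model = list(q0 = 70.39, d = 45),
                               grid = list(nx = 1),
                               label = "table2_breast"),
    fig3a = run_config(model = c(list(tau = 11.8964), slow), grid = g(),
                       numerics = list(t_end = 16,
                                       record_times = 16),
                       label = "fig3a"),
    fig3b = run_config(model = list(tau = 11.8964), grid = g(),
                       numerics = list(t_end = 16, record_times = 16),
                       label = "fig3b"),
    fig4 = run_config(model = c(list(tau = 6.8964), slow), grid = g(),
                      numerics = list(t_end = 16, record_times = 16),
                      label = "fig4"),
    fig5 = run_config(model = c(list(tau = 14.8964), slow), grid = g(),
                      numerics = list(t_end = 16, record_times = 16),
                      label = "fig5"),
    fig6_tcp = run_config(model = list(), grid = list(nx = 1),
                          radio = list(n_per_day = 2, T = 45),
                          label = "fig6_tcp"),
    fig7 = run_config(model = c(list(tau = 6.8964), slow), grid = g(),
                      radio = rt(0.02),
                      numerics = list(t_end = 16, rt_start = 6.8964),
                      label = "fig7"),
    fig8 = run_config(model = c(list(tau = 6.8964), slow), grid = g(),
                      radio = rt(0.05),
                      numerics = list(t_end = 16, rt_start = 6.8964),
                      label = "fig8"),
    fig9 = run_config(model = c(list(tau = 6.8964), slow), grid = g(),
                      radio = rt(1.323),
                      numerics = list(t_end = 16, rt_start = 6.8964),
                      label = "fig9"),
    fig10 = run_config(model = c(list(tau = 6.8964), slow), grid = g(),
                       radio = rt(0.02),
                       numerics = list(t_end = 16, rt_start = 6.8964,
                                       record_times = 16),
                       label = "fig10"),
    fig11 = run_config(model = c(list(tau = 6.8964), slow), grid = g(),
                       radio = rt(0.05),
                       numerics = list(t_end = 16, rt_start = 6.8964,
                                       record_times = 16),
                       label = "fig11"))
  sc
}

#' Run a configuration
#'
#' Dispatches a `run_config` to the appropriate computation: the
#' `table2_*` presets run [critical_delay()], `fig6_tcp` runs
#' [tcp_curve()], and every other configuration runs [simulate_csc()].
#'
#' @param config a `run_config` or the name of a built-in scenario.
#' @param grid optional grid override (passed to [builtin_scenarios()]
#'   when `config` is a name, or replacing `config$grid`).
#' @return The result object of the dispatched computation.
#' @export
run_scenario <- function(config, grid = NULL) {
  if (is.character(config)) {
    sc <- builtin_scenarios(grid = grid)
    if (!config %in% names(sc))
      stop("unknown scenario '", config, "'; available: ",
           paste(names(sc), collapse = ", "), call. = FALSE)
    config <- sc[[config]]
  }
  stopifnot(inherits(config, "run_config"))
  if (!is.null(grid)) config$grid <- grid
  if (grepl("^table2_", config$label))
    return(critical_delay(config$model, m2 = config$numerics$m2))
  if (identical(config$label, "fig6_tcp"))
    return(tcp_curve(config$radio))
  nm <- config$numerics
  dur <- nm$rt_duration
  if (!is.null(dur) && dur < 0) dur <- Inf
  simulate_csc(config$model, grid = config$grid, m2 = nm$m2,
               t_end = nm$t_end, dt = nm$dt,
               record_times = nm$record_times, radio = config$radio,
               rt_start = nm$rt_start, rt_duration = dur)
}

#' Critical-delay table for the built-in cancer parameter sets
#'
#' Runs [critical_delay()] for the prostate, lung and breast presets and
#' tabulates the outcome. When a parameter set admits no Hopf crossing
#' the delay column is `NA` (delay-independent stability).
#'
#' @param m2 microRNA level of the E2 family used for the linearisation.
#' @param cancers subset of the built-in cancer names.
#' @return Data frame with columns `cancer`, `q0`, `d`, `tau_c`,
#'   `omega`, `ksq`.
#' @export
tau_c_table <- function(m2 = 0.08,
                        cancers = c("prostate", "lung", "breast")) {
  rows <- lapply(cancers, function(cc) {
    p <- cancer_params(cc)
    h <- critical_delay(p, m2 = m2)
    data.frame(cancer = cc, q0 = p$q0, d = p$d, tau_c = h$tau_c,
               omega = h$omega_at_min, ksq = h$ksq_at_min)
  })
  do.call(rbind, rows)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write structured outputs of a run
#'
#' Writes deterministic delimited-text outputs plus a JSON metadata
#' sidecar (resolved configuration and package version) to a directory.
#' Supported inputs: a `csc_sim` (probe series, snapshot grids per
#' field), a `hopf_result` (crossing table and summary), a data frame
#' (e.g. a TCP curve), or the [tau_c_table()] output. Identical inputs
#' produce byte-identical files.
#'
#' @param x result object.
#' @param dir output directory (created if needed).
#' @param name base name for the files.
#' @return Character vector of the files written (invisibly).
#' @export
write_outputs <- function(x, dir, name = "run") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  meta <- list(package = "cscdelay",
               version = as.character(utils::packageVersion("cscdelay")),
               name = name)
  if (inherits(x, "csc_sim")) {
    f <- file.path(dir, paste0(name, "_series.tsv"))
    write_tsv(x$series, f)
    files <- c(files, f)
    for (sn in x$snapshots) {
      if (is.null(sn)) next
      for (fld in c("S", "D", "a", "m")) {
        f <- file.path(dir, sprintf("%s_snapshot_t%s_%s.tsv", name,
                                    fmt_num(sn$t), fld))
        utils::write.table(matrix(fmt_num(sn[[fld]]), nrow(sn[[fld]])),
                           f, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        files <- c(files, f)
      }
    }
    meta$model <- unclass(x$params)
    meta$radio <- if (!is.null(x$radio)) unclass(x$radio)
    meta$grid <- list(L = x$grid$L, nx = x$grid$nx, ny = x$grid$ny)
    meta$numerics <- list(dt = x$dt, m2 = x$m2, rt_start = x$rt_start,
                          rt_duration =
                            if (is.finite(x$rt_duration))
                              x$rt_duration else -1)
  } else if (inherits(x, "hopf_result")) {
    f <- file.path(dir, paste0(name, "_crossings.tsv"))
    write_tsv(x$crossings, f)
    files <- c(files, f)
    meta$tau_c <- x$tau_c
    meta$message <- x$message
  } else if (is.data.frame(x)) {
    f <- file.path(dir, paste0(name, ".tsv"))
    write_tsv(x, f)
    files <- c(files, f)
  } else {
    stop("unsupported result type: ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  fm <- file.path(dir, paste0(name, "_metadata.json"))
  jsonlite::write_json(meta, fm, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, fm)
  invisible(files)
}
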