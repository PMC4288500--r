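#' Read and write the package's tidy CSV schemas
#'
#' Sweep sets, dose-response tables, traces and fit results are exchanged as
#' plain CSV/JSON so every stage can be run from files.
#'
#' @param x object to write.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return the object.
#' @name io
NULL

#' @rdname io
#' @export
write_sweeps <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  proto <- attr(x, "protocol")
  jsonlite::write_json(unclass(proto), sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_sweeps <- function(path) {
  d <- read.csv(path)
  side <- sub("\\.csv$", ".json", path)
  if (file.exists(side)) {
    pj <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(d, "protocol") <- do.call(step_protocol, pj)
  }
  class(d) <- c("sweep_set", "data.frame")
  d
}

#' @rdname io
#' @export
write_fit <- function(x, path) {
  jsonlite::write_json(
    lapply(unclass(x), function(v) if (is.numeric(v)) unname(v) else v),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run a declarative analysis scenario
#'
#' A scenario bundles seeded generator stages, curve fits, burst-model runs
#' and fast-slow comparisons into one reproducible unit: the same scenario
#' and seed give identical outputs.  Scenarios are plain lists, read from
#' YAML with [read_scenario()].
#'
#' Supported stage types and their fields:
#' \describe{
#'   \item{dose_response}{`concentrations`, `e_max`, `ec50`, `n_h`,
#'     `n_cells`, `noise_sd`, `cell_cv`; generates a table and fits the Hill
#'     equation.}
#'   \item{boltzmann}{`v_half`, `q`, `g_max`, `steps`; generates noiseless
#'     relative-conductance points and refits them.}
#'   \item{simulate}{`g_m_scale`, `g_kca_scale`, `duration`, `dt`,
#'     `label`; runs the burst model and computes burst metrics.}
#'   \item{fold_change}{`a`, `b` (labels of simulate stages), `current`.}
#'   \item{nullcline_shift}{`a`, `b` (labels), `o_grid` resolution.}
#' }
#'
#' @param scenario scenario list with fields `name`, `seed`, `stages`
#'   (named list of stage specs), or a path to a YAML file.
#' @param out_dir output directory for per-stage artifacts; `NULL` writes
#'   nothing.
#' @return report list (one entry per stage) with the scenario name and
#'   seed; written as `report.json` when `out_dir` is given.
#' @export
run_scenario <- function(scenario, out_dir = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(is.list(scenario))
  seed <- if (is.null(scenario$seed)) 1L else as.integer(scenario$seed)
  stages <- scenario$stages
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(name = scenario$name, seed = seed, stages = list())
  sims <- list()

  for (nm in names(stages)) {
    st <- stages[[nm]]
    res <- switch(
      st$type,
      dose_response = {
        ns <- noise_spec(trace_noise_sd = st$noise_sd %||% 5,
                         cell_cv = st$cell_cv %||% 0.12, seed = seed)
        tab <- gen_dose_response(unlist(st$concentrations),
                                 e_max = st$e_max %||% 100,
                                 ec50 = st$ec50 %||% 9.8,
                                 n_h = st$n_h %||% 1,
                                 noise = ns, n_cells = st$n_cells %||% 10)
        if (!is.null(out_dir))
          write.csv(tab, file.path(out_dir, paste0(nm, ".csv")),
                    row.names = FALSE)
        fit <- fit_hill(tab)
        list(ec50 = unname(fit$estimate["ec50"]),
             e_max = unname(fit$estimate["e_max"]),
             n_h = unname(fit$estimate["n_h"]),
             converged = fit$convergence$converged)
      },
      boltzmann = {
        v <- unlist(st$steps %||% seq(-50, 10, by = 10))
        g <- (st$g_max %||% 1) * eval_boltzmann(v, st$v_half, st$q)
        fit <- fit_boltzmann(data.frame(v_mV = v, g = g))
        list(v_half = unname(fit$estimate["v_half"]),
             q = unname(fit$estimate["q"]),
             converged = fit$convergence$converged)
      },
      simulate = {
        cfg <- sim_config(dt = st$dt %||% 0.001,
                          duration = st$duration %||% 3000)
        tr <- simulate_neuron(model_params(), cfg,
                              modulation = list(g_m_scale = st$g_m_scale %||% 1,
                                                g_kca_scale = st$g_kca_scale %||% 1))
        sims[[nm]] <- tr
        bm <- burst_metrics(tr, discard_ms = 300)
        if (!is.null(out_dir)) {
          keep <- tr[seq(1, nrow(tr), by = 10),
                     c("time_ms", "V", "ca", "I_M", "I_KCa")]
          write.csv(keep, file.path(out_dir, paste0(nm, ".csv")),
                    row.names = FALSE)
        }
        list(n_bursts = nrow(bm$bursts),
             spikes_per_burst = bm$spikes_per_burst,
             intraburst_rate_Hz = bm$intraburst_rate_Hz,
             interburst_interval_ms = bm$interburst_interval_ms,
             ahp_min_mV = bm$ahp_min_mV)
      },
      fold_change = {
        list(current = st$current,
             fold = fold_change(sims[[st$a]], sims[[st$b]], st$current))
      },
      nullcline_shift = {
        og <- seq(0.1, 0.9, length.out = st$n_points %||% 9)
        pa <- scaled_params(st$a_scales)
        pb <- scaled_params(st$b_scales)
        ca <- cycle_average_ca(model_params())
        na <- compute_nullcline(pa, og, ca = ca)
        nb <- compute_nullcline(pb, og, ca = ca)
        list(mean_shift = nullcline_shift(na, nb))
      },
      stop("unknown stage type: ", st$type)
    )
    report$stages[[nm]] <- res
  }
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  report
}

scaled_params <- function(scales) {
  gm <- if (is.null(scales$g_m_scale)) 1 else scales$g_m_scale
  gk <- if (is.null(scales$g_kca_scale)) 1 else scales$g_kca_scale
  p <- model_params()
  p[["g_m"]] <- p[["g_m"]] * gm
  p[["g_kca"]] <- p[["g_kca"]] * gk
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param path YAML scenario file.
#' @rdname run_scenario
#' @export
read_scenario <- function(path) {
  yaml::read_yaml(path)
}
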