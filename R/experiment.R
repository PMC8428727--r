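#' Packaged experiment configurations
#'
#' Named parameter sets shipped with the package (YAML files under
#' \code{inst/extdata/configs}), keyed by the canonical model setups used
#' throughout: the adaptive QIF with colored noise (\code{"fig2_qif"}),
#' adaptive LIF combinations (\code{"fig3a_lif"}, \code{"fig3b_lif"},
#' \code{"fig4a_lif"}, \code{"fig4b_lif"}), adaptive and non-adaptive GIF
#' resonators (\code{"fig5a_gif"} ... \code{"fig5c_gif"}, \code{"fig6b_gif"},
#' \code{"fig9_gif"}), the shared-channel LIF (\code{"fig7a_lif"},
#' \code{"fig7b_lif"}), green-noise LIF (\code{"fig8c_lif"},
#' \code{"fig8d_lif"}) and the Traub-Miles model
#' (\code{"table1_traub_miles"}).
#'
#' @param key configuration name; call with no arguments to list keys.
#' @return a validated experiment configuration (list), or the key vector.
#' @export
figure_config <- function(key = NULL) {
  dir <- system.file("extdata", "configs", package = "isicorr")
  keys <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (is.null(key)) return(keys)
  if (!key %in% keys)
    stop_cfg("unknown configuration '%s'; available: %s", key,
             paste(keys, collapse = ", "))
  cfg <- yaml::read_yaml(file.path(dir, paste0(key, ".yaml")))
  cfg$name <- key
  validate_config(cfg)
}

config_defaults <- list(
  model = list(kind = "lif", mu = 5, gamma = 1, beta_w = 0, tau_w = 1,
               v_threshold = 1, v_reset = 0, w_reset = 0),
  adaptation = list(tau_a = 1, delta = 0),
  noise = list(d_white = 0, sigma2 = 0, tau_eta = 1, mode = "independent"),
  sim = list(dt = 1e-4, n_spikes = 10000, seed = 1),
  analysis = list(k_max = 8, statistics = list("theory"))
)

#' Validate an experiment configuration
#'
#' Fills defaults and checks every field; schema violations are reported
#' field by field.
#'
#' @param cfg a nested list with blocks \code{model}, \code{adaptation},
#'   \code{noise}, \code{sim}, \code{analysis}.
#' @return the completed configuration (invisibly classed
#'   \code{"experiment_config"}).
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  for (blk in names(config_defaults)) {
    cfg[[blk]] <- modifyList(config_defaults[[blk]], cfg[[blk]] %||% list())
    extra <- setdiff(names(cfg[[blk]]), names(config_defaults[[blk]]))
    if (length(extra))
      errs <- c(errs, sprintf("%s: unknown field(s) %s", blk,
                              paste(extra, collapse = ", ")))
  }
  if (!cfg$model$kind %in% c("lif", "qif", "gif", "traub_miles"))
    errs <- c(errs, sprintf("model.kind: unknown kind '%s'", cfg$model$kind))
  for (fld in c("tau_a")) if (cfg$adaptation[[fld]] <= 0)
    errs <- c(errs, sprintf("adaptation.%s: must be > 0", fld))
  if (cfg$adaptation$delta < 0) errs <- c(errs, "adaptation.delta: must be >= 0")
  if (cfg$noise$d_white < 0) errs <- c(errs, "noise.d_white: must be >= 0")
  if (cfg$noise$sigma2 < 0) errs <- c(errs, "noise.sigma2: must be >= 0")
  if (!cfg$noise$mode %in% c("independent", "green", "shared_channel"))
    errs <- c(errs, sprintf("noise.mode: unknown mode '%s'", cfg$noise$mode))
  if (cfg$sim$dt <= 0) errs <- c(errs, "sim.dt: must be > 0")
  if (cfg$sim$n_spikes < 2) errs <- c(errs, "sim.n_spikes: must be >= 2")
  if (length(errs))
    stop_cfg("invalid configuration:\n  %s", paste(errs, collapse = "\n  "))
  class(cfg) <- "experiment_config"
  cfg
}

config_objects <- function(cfg) {
  m <- cfg$model
  list(model = model_spec(m$kind, mu = m$mu, gamma = m$gamma,
                          beta_w = m$beta_w, tau_w = m$tau_w,
                          v_threshold = m$v_threshold, v_reset = m$v_reset,
                          w_reset = m$w_reset),
       adaptation = adaptation_spec(cfg$adaptation$tau_a, cfg$adaptation$delta),
       noise = noise_spec(cfg$noise$d_white, cfg$noise$sigma2,
                          cfg$noise$tau_eta, cfg$noise$mode))
}

#' Run a configured experiment
#'
#' Executes the pipeline limit cycle -> PRC -> theory and/or stochastic
#' simulation with estimators, as requested by
#' \code{analysis.statistics} (any of \code{"theory"},
#' \code{"simulation"}). Degenerate deterministic configurations (no
#' adaptation, no noise) yield a clean summary flagged
#' \code{renewal_undefined} instead of an error. Identical configuration and
#' seed reproduce identical outputs.
#'
#' @param cfg an experiment configuration (see [figure_config()],
#'   [validate_config()]).
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV together with a JSON provenance record (configuration hash,
#'   seed, package version).
#' @return list with \code{summary} (data frame), \code{theory} and/or
#'   \code{simulation} tables.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  cfg <- validate_config(unclass(cfg))
  stats <- unlist(cfg$analysis$statistics)
  k_max <- cfg$analysis$k_max
  stage <- "setup"
  res <- tryCatch({
    if (cfg$model$kind == "traub_miles") {
      stage <- "limit cycle"
      params <- tm_params(d_white = cfg$noise$d_white,
                          sigma2 = cfg$noise$sigma2,
                          tau_eta = cfg$noise$tau_eta)
      cycle <- tm_limit_cycle(params)
      stage <- "theory"
      ctx <- tm_theory_adapter(params, cycle = cycle)
      out <- list(summary = data.frame(
        period = cycle$period, a_star = cycle$a_star, alpha = ctx$alpha,
        beta = ctx$beta, nu = ctx$nu, cv_theory = cv_theory(ctx)))
      if ("theory" %in% stats) out$theory <- scc_general(ctx, seq_len(k_max))
      if ("simulation" %in% stats) {
        stage <- "simulation"
        train <- tm_simulate(params, n_spikes = cfg$sim$n_spikes,
                             dt = min(cfg$sim$dt, 0.005), seed = cfg$sim$seed,
                             cycle = cycle)
        out$simulation <- estimate_scc(train, k_max)
        cvh <- estimate_cv(train)
        out$summary$cv_hat <- cvh$cv
      }
      out
    } else {
      obj <- config_objects(cfg)
      degenerate <- cfg$adaptation$delta == 0 && cfg$noise$sigma2 == 0 &&
        cfg$noise$d_white == 0
      stage <- "limit cycle"
      cycle <- find_limit_cycle(obj$model, obj$adaptation)
      if (degenerate) {
        list(summary = data.frame(
          period = cycle$period, a_star = cycle$a_star,
          renewal_undefined = TRUE),
          note = "deterministic model: renewal statistics undefined")
      } else {
        stage <- "theory"
        ctx <- build_context(obj$model, obj$adaptation, obj$noise, cycle = cycle)
        out <- list(summary = data.frame(
          period = cycle$period, a_star = cycle$a_star, alpha = ctx$alpha,
          beta = ctx$beta, nu = ctx$nu,
          cv_theory = if (cfg$noise$sigma2 > 0 || cfg$noise$d_white > 0)
            cv_theory(ctx) else NA_real_))
        if ("theory" %in% stats) out$theory <- scc_general(ctx, seq_len(k_max))
        if ("simulation" %in% stats) {
          stage <- "simulation"
          train <- simulate_train(obj$model, obj$adaptation, obj$noise,
                                  sim_config(dt = cfg$sim$dt,
                                             n_spikes = cfg$sim$n_spikes,
                                             seed = cfg$sim$seed),
                                  cycle = cycle)
          out$simulation <- estimate_scc(train, k_max)
          cvh <- estimate_cv(train)
          out$summary$cv_hat <- cvh$cv
        }
        out
      }
    }
  }, error = function(e) {
    stop_cfg("experiment failed at stage '%s': %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir)) write_experiment(cfg, res, out_dir)
  res
}

write_experiment <- function(cfg, res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in intersect(c("summary", "theory", "simulation"), names(res)))
    write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  prov <- list(config = unclass(cfg),
               config_md5 = unname(tools::md5sum(tmp)),
               seed = cfg$sim$seed,
               package_version = as.character(utils::packageVersion("isicorr")))
  unlink(tmp)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Sweep one scalar configuration field
#'
#' Re-runs the theory (and optionally the simulation) of an experiment for a
#' sequence of values of one scalar field, e.g. \code{"noise.tau_eta"} or
#' \code{"noise.d_white"}; for shared-channel configurations sweeping
#' \code{"noise.tau_eta"} moves \code{adaptation.tau_a} along with it.
#'
#' @param cfg an experiment configuration.
#' @param parameter dotted path to a scalar field.
#' @param values numeric vector of values (empty gives an empty table).
#' @param statistics character vector, subset of
#'   \code{c("theory", "simulation")}.
#' @return long-format data frame with one row per (value, lag).
#' @export
sweep_parameter <- function(cfg, parameter, values,
                            statistics = "theory") {
  cfg <- validate_config(unclass(cfg))
  path <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  if (length(path) != 2 || is.null(cfg[[path[1]]][[path[2]]]) ||
      !is.numeric(cfg[[path[1]]][[path[2]]]))
    stop_cfg("'%s' is not a scalar numeric configuration field", parameter)
  out <- vector("list", length(values))
  for (i in seq_along(values)) {
    ci <- unclass(cfg)
    ci[[path[1]]][[path[2]]] <- values[i]
    if (ci$noise$mode == "shared_channel" && parameter == "noise.tau_eta")
      ci$adaptation$tau_a <- values[i]
    ci$analysis$statistics <- as.list(statistics)
    r <- run_experiment(ci)
    tab <- r$theory
    df <- data.frame(value = values[i], lag = tab$lag, rho_theory = tab$rho)
    if ("simulation" %in% statistics) {
      sim <- r$simulation[r$simulation$lag >= 1, ]
      df$rho_sim <- sim$rho_hat[match(df$lag, sim$lag)]
      df$rho_sim_se <- sim$se[match(df$lag, sim$lag)]
    }
    out[[i]] <- df
  }
  if (!length(out)) return(data.frame(value = numeric(0), lag = integer(0),
                                      rho_theory = numeric(0)))
  do.call(rbind, out)
}
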