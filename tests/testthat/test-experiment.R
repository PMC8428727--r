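# configuration schema, experiment runner, sweeps

test_that("packaged configurations load and validate", {
  keys <- figure_config()
  expect_true(all(c("fig2_qif", "fig5c_gif", "table1_traub_miles") %in% keys))
  cfg <- figure_config("fig2_qif")
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$model$kind, "qif")
  expect_equal(cfg$adaptation$delta, 18)
  expect_error(figure_config("fig99"), "unknown configuration")
})

test_that("schema violations are reported field by field", {
  bad <- list(model = list(kind = "hodgkin"), sim = list(dt = -1),
              noise = list(sigma2 = -2))
  err <- tryCatch(validate_config(bad), error = conditionMessage)
  expect_match(err, "model.kind")
  expect_match(err, "sim.dt")
  expect_match(err, "noise.sigma2")
  expect_error(validate_config(list(model = list(kindd = "lif"))), "unknown field")
})

test_that("runner executes theory+simulation and is reproducible on disk", {
  cfg <- unclass(figure_config("fig3a_lif"))
  cfg$sim$n_spikes <- 1500
  cfg$analysis$k_max <- 4
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  r1 <- run_experiment(cfg, out_dir = d1)
  r2 <- run_experiment(cfg, out_dir = d2)
  expect_true(all(c("summary", "theory", "simulation") %in% names(r1)))
  expect_equal(nrow(r1$theory), 4)
  for (f in c("summary.csv", "theory.csv", "simulation.csv", "provenance.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  prov <- jsonlite::read_json(file.path(d1, "provenance.json"))
  expect_equal(prov$seed, cfg$sim$seed)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("degenerate deterministic configuration yields a clean report", {
  cfg <- list(model = list(kind = "lif", mu = 5),
              adaptation = list(tau_a = 2, delta = 0),
              noise = list(d_white = 0, sigma2 = 0))
  r <- run_experiment(cfg)
  expect_true(r$summary$renewal_undefined)
  expect_match(r$note, "renewal statistics undefined")
})

test_that("errors carry the failing stage", {
  cfg <- list(model = list(kind = "lif", mu = 0.2),  # below threshold drive
              adaptation = list(tau_a = 2, delta = 0),
              noise = list(d_white = 0.01))
  err <- tryCatch(run_experiment(cfg), error = conditionMessage)
  expect_match(err, "stage 'limit cycle'")
  expect_match(err, "not tonically firing")
})

test_that("sweeps produce long tables with the documented shapes", {
  expect_identical(nrow(sweep_parameter(figure_config("fig6b_gif"),
                                        "noise.tau_eta", numeric(0))), 0L)
  expect_error(sweep_parameter(figure_config("fig6b_gif"),
                               "analysis.statistics", 1:3), "scalar")

  # rho_1(tau_eta) of the non-adaptive resonator has one interior minimum
  cfg <- unclass(figure_config("fig6b_gif"))
  cfg$analysis$k_max <- 1
  tes <- 10^seq(-2, 1.2, length.out = 10) * 1.76
  tab <- sweep_parameter(cfg, "noise.tau_eta", tes)
  expect_equal(nrow(tab), 10)
  r1 <- tab$rho_theory
  expect_true(which.min(r1) > 1 && which.min(r1) < length(r1))
  expect_equal(sum(diff(sign(diff(r1))) != 0), 1)  # single turning point

  # shared-channel sweep moves tau_a along with tau_c and shows a minimum
  cfg7 <- unclass(figure_config("fig7a_lif"))
  cfg7$analysis$k_max <- 1
  tcs <- 10^seq(-1.3, 1.3, length.out = 9)
  tab7 <- sweep_parameter(cfg7, "noise.tau_eta", tcs)
  expect_true(which.min(tab7$rho_theory) > 1 &&
              which.min(tab7$rho_theory) < nrow(tab7))
})
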