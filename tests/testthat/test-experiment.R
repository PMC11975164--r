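test_that("presets populate the canonical treatment lists", {
  short <- experiment_config("short_term", seed = 3)
  expect_identical(names(short$policies),
                   c("batch", "fixed_60_3", "perfect", "ensemble"))
  expect_identical(short$policies$fixed_60_3$rate, 0.6)
  expect_identical(short$policies$fixed_60_3$period_days, 3)
  expect_identical(short$n_days, 8L)

  long <- experiment_config("long_term", seed = 3)
  expect_identical(names(long$policies),
                   c("fixed_60_3", "fixed_20_1", "perfect", "ensemble"))
  expect_identical(long$policies$fixed_20_1$rate, 0.2)
  expect_identical(long$policies$fixed_20_1$period_days, 1)
  expect_identical(long$n_days, 92L)
  expect_identical(long$policies$perfect$source, "perfect")
  expect_identical(long$policies$ensemble$source, "ensemble")

  expect_error(experiment_config("custom"), class = "pondcast_error_config")
})

test_that("YAML configurations round-trip and unknown keys are rejected", {
  cfg <- experiment_config("short_term", seed = 9,
                           pond = list(concentration = 0.3),
                           optics = list(n_layers = 60))
  f <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, f)
  back <- load_config(f)
  expect_identical(back$preset, cfg$preset)
  expect_identical(back$n_days, cfg$n_days)
  expect_identical(back$seed, cfg$seed)
  expect_equal(back$pond$concentration, 0.3)
  expect_equal(back$optics$n_layers, 60L)
  expect_identical(names(back$policies), names(cfg$policies))
  expect_identical(back$policies$fixed_60_3$rate, cfg$policies$fixed_60_3$rate)
  expect_equal(unclass(back$weather), unclass(cfg$weather))
  expect_equal(unclass(back$forecast), unclass(cfg$forecast))

  writeLines("preset: short_term\nmystery_knob: 1", f)
  expect_error(load_config(f), class = "pondcast_error_config")
  writeLines("preset: short_term\npolicies:\n  a:\n    kind: fixed\n    frequency: 2", f)
  expect_error(load_config(f), class = "pondcast_error_config")
})

test_that("a small custom experiment produces the documented outputs", {
  cfg <- experiment_config(
    "custom", start_date = "2013-07-01", n_days = 6, seed = 5,
    policies = list(batch = policy_batch(),
                    fixed = policy_fixed(0.5, 2),
                    perfect = policy_forecast("perfect")),
    forecast = list(n_members = 3)
  )
  ex <- run_experiment(cfg)
  expect_s3_class(ex, "fipo_experiment")
  expect_identical(ex$comparison$treatment, c("batch", "fixed", "perfect"))
  expect_true(all(ex$comparison$total_g > 0))
  expect_true(is.na(ex$comparison$rel_diff_1[1]))
  expect_equal(ex$comparison$rel_diff_1[2],
               100 * (ex$comparison$total_g[2] / ex$comparison$total_g[1] - 1),
               tolerance = 1e-12)
  # totals equal their ledgers
  for (nm in names(ex$runs)) {
    expect_equal(ex$comparison$total_g[ex$comparison$treatment == nm],
                 ledger_total(ex$runs[[nm]]$ledger))
  }
  # decisions recorded only for the forecast-informed treatment
  expect_identical(length(ex$runs$batch$decisions), 0L)
  expect_identical(length(ex$runs$perfect$decisions), 6L)

  # tidiers
  expect_identical(tidy(ex), ex$comparison)
  g <- glance(ex)
  expect_identical(g$n_treatments, 3L)
  expect_identical(g$best_treatment,
                   ex$comparison$treatment[which.max(ex$comparison$total_g)])
  expect_s3_class(tidy(ex$runs$perfect), "tbl_df")
  expect_identical(glance(ex$runs$perfect)$total_g, ex$runs$perfect$total_g)
  dec <- ex$runs$perfect$decisions[[1]]
  expect_identical(glance(dec)$chosen_rate, dec$chosen_rate)

  # plots build without error
  expect_s3_class(ggplot2::autoplot(ex), "ggplot")
  expect_s3_class(ggplot2::autoplot(ex$runs$fixed), "ggplot")
  expect_s3_class(ggplot2::autoplot(dec), "ggplot")
  expect_s3_class(plot_meteo(ex$truth[1:48, ]), "ggplot")
})

test_that("experiments are reproducible from the master seed and write outputs", {
  cfg <- function(dir = NULL) experiment_config(
    "custom", start_date = "2013-07-10", n_days = 4, seed = 21,
    policies = list(fixed = policy_fixed(0.4, 2),
                    ensemble = policy_forecast("ensemble")),
    forecast = list(n_members = 3), out_dir = dir
  )
  a <- run_experiment(cfg())
  b <- run_experiment(cfg())
  expect_identical(a$comparison, b$comparison)
  expect_identical(a$runs$ensemble$ledger, b$runs$ensemble$ledger)

  dir <- withr::local_tempdir()
  run_experiment(cfg(dir))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "comparison.csv")))
  expect_true(file.exists(file.path(dir, "ledger_fixed.csv")))
  expect_true(file.exists(file.path(dir, "decisions_ensemble.csv")))
  dec <- readr::read_csv(file.path(dir, "decisions_ensemble.csv"),
                         show_col_types = FALSE)
  expect_identical(nrow(dec), 4L)
  expect_true(all(c("chosen_rate", "rate_00", "rate_99") %in% names(dec)))
  # the resolved config reproduces the experiment
  again <- run_experiment(load_config(file.path(dir, "config.yaml")))
  expect_equal(again$comparison$total_g,
               readr::read_csv(file.path(dir, "comparison.csv"),
                               show_col_types = FALSE)$total_g,
               tolerance = 1e-9)
})
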