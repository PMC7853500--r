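test_that("datasets round-trip losslessly through the on-disk dialect", {
  co <- generate_cohort(3, seed = 9, dt = 0.5, t_grid = seq(0, 150))
  p <- withr::local_tempdir()
  write_dataset(co, p)
  back <- read_dataset(p)
  expect_s3_class(back, "tc_cohort")
  expect_identical(back$dataset$waves, co$dataset$waves)
  expect_identical(back$dataset$subjects, co$dataset$subjects)
  expect_equal(back$dataset$t, co$dataset$t)
  expect_equal(back$truth$theta, co$truth$theta)
  expect_equal(back$truth$beta, co$truth$beta, ignore_attr = TRUE)

  # a bare dataset (no truth) reads back as a dataset
  p2 <- withr::local_tempdir()
  write_dataset(co$dataset, p2)
  expect_s3_class(read_dataset(p2), "tc_dataset")
})

test_that("schema violations are reported with a pointer to the offending field", {
  co <- generate_cohort(2, seed = 9, dt = 0.5, t_grid = seq(0, 120))
  p <- withr::local_tempdir()
  write_dataset(co$dataset, p)

  # truncate one subject's samples: grids no longer match
  w <- readr::read_csv(file.path(p, "waveforms.csv"),
                       show_col_types = FALSE)
  w <- w[!(w$subject == "sub-02" & w$t > 100), ]
  readr::write_csv(w, file.path(p, "waveforms.csv"))
  expect_error(read_dataset(p), "sub-02")

  # missing metadata field
  meta <- jsonlite::read_json(file.path(p, "meta.json"))
  meta$sampling_rate <- NULL
  jsonlite::write_json(meta, file.path(p, "meta.json"), auto_unbox = TRUE)
  expect_error(read_dataset(p), "/sampling_rate")

  expect_error(read_dataset(withr::local_tempdir()), "meta.json")
})

test_that("per-condition CSV import reconstructs the sampling arithmetic", {
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(pre = c(0.5, 1), early_post = c(0, 2),
                              late_post = c(1, 3)), p)
  ds <- read_subject_csv(p, sampling_rate = 500)
  expect_equal(length(ds$t), 2)          # duration x rate
  expect_equal(ds$t, c(0, 2))            # 500 Hz -> 2 ms spacing
  expect_equal(ds$waves[[1]][, "late_post"], c(1, 3))

  readr::write_csv(data.frame(pre = 1, x = 2), p)
  expect_error(read_subject_csv(p), "early_post")
})

test_that("model specifications round-trip through the YAML schema", {
  spec <- tc_model(V_R = -42, delay_tc = 2.5)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(spec, f)
  back <- read_model_yaml(f)
  expect_equal(back$gains, spec$gains)
  expect_equal(back$kinetics$kappa, spec$kinetics$kappa)
  expect_equal(back$V_R, -42)
  expect_equal(back$delay_tc, 2.5)
  expect_equal(back$free_mask, spec$free_mask)
  # the deserialised model simulates identically
  des <- condition_design("linear")
  Y1 <- simulate_erp(spec, parameter_vector(spec, des), tc_obs_default,
                     des, t_grid = seq(0, 120), dt = 0.5)
  Y2 <- simulate_erp(back, parameter_vector(back, des), tc_obs_default,
                     des, t_grid = seq(0, 120), dt = 0.5)
  expect_equal(Y1, Y2, tolerance = 1e-12)
})

test_that("fit results round-trip through the JSON container", {
  des <- condition_design("linear")
  Y <- sim_subject("b_sssp", des, beta = c("ss->sp" = 0.25))
  fit <- invert_evoked(Y, tc_spec, tc_obs_default, des,
                       settings = list(max_iter = 2, dt = 0.5))
  f <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, f)
  back <- read_fit(f, tc_spec)
  expect_equal(back$F, fit$F)
  expect_equal(back$mean, fit$mean, tolerance = 1e-12)
  expect_equal(unname(back$cov), unname(fit$cov), tolerance = 1e-12)
  expect_equal(back$F_trace, fit$F_trace)
  expect_equal(back$explained_variance, fit$explained_variance)
  expect_equal(back$design, "linear")
})

test_that("the pipeline validates its configuration before fitting", {
  expect_error(run_pipeline(list(designs = "linear")), "2 designs")
  expect_error(run_pipeline(list(designs = c("linear", "nonlinear"))),
               "synth block or a dataset")
  expect_error(run_pipeline(list(designs = c("linear", "nonlinear"),
                                 model = "banana",
                                 synth = list(n_subjects = 1))),
               "banana")
})

test_that("the pipeline produces a complete, reproducible report", {
  cfg <- list(synth = list(n_subjects = 2, design = "linear",
                           effects = list(c("rl->ss" = 0.3, "ss->sp" = 0.3)),
                           snr = 8, seed = 2),
              designs = c("linear", "nonlinear"),
              settings = list(max_iter = 2, dt = 0.5),
              seed = 1,
              out_dir = withr::local_tempdir())
  rep1 <- run_pipeline(cfg)
  expect_true(all(c("bms", "stats", "explained_variance", "config") %in%
                    names(rep1)))
  expect_equal(dim(rep1$bms$evidence), c(2, 2))
  expect_length(rep1$explained_variance, 2)
  expect_true(file.exists(file.path(cfg$out_dir, "report.json")))
  expect_true(file.exists(file.path(cfg$out_dir, "parameter_stats.csv")))
  expect_match(rep1$config$hash, "^[a-f0-9]{32}$")

  rep2 <- run_pipeline(cfg)
  expect_identical(rep1$bms$evidence, rep2$bms$evidence)
  expect_identical(rep1$bms$rfx$pxp, rep2$bms$rfx$pxp)
})
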