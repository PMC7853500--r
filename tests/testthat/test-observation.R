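test_that("contrast designs match the three-condition study layout", {
  expect_equal(unname(condition_design("nonlinear")$X), matrix(c(-1, 1, 0), 1))
  expect_equal(unname(condition_design("linear")$X), matrix(c(-1, 0, 1), 1))
  expect_equal(unname(condition_design("combination")$X),
               matrix(c(-1, 1, 0, -1, 0, 1), 2, byrow = TRUE))
  expect_equal(colnames(condition_design("linear")$X),
               c("pre", "early_post", "late_post"))
  expect_length(condition_design("linear")$effect_targets, 14)
})

test_that("condition scaling is multiplicative in log space", {
  spec <- tc_model()
  des <- condition_design("linear")
  b <- 0.3
  pv <- parameter_vector(spec, des, beta = c("rl->ss" = b))
  g0 <- spec$gains$AMPA["ss", "rl"]
  got <- vapply(1:3, function(cc)
    condition_model(spec, pv, des, cc)$gains$AMPA["ss", "rl"], numeric(1))
  expect_equal(got, g0 * exp(c(-b, 0, b)))
  # NMDA gain of the same edge is co-scaled
  expect_equal(condition_model(spec, pv, des, 3)$gains$NMDA["ss", "rl"],
               spec$gains$NMDA["ss", "rl"] * exp(b))
  # fixed edges untouched
  expect_equal(condition_model(spec, pv, des, 3)$gains$AMPA["rt", "rl"],
               spec$gains$AMPA["rt", "rl"])
  # input spec not modified in place
  expect_equal(spec$gains$AMPA["ss", "rl"], g0)
})

test_that("combination design applies its rows to the right conditions", {
  spec <- tc_model()
  des <- condition_design("combination")
  pv <- parameter_vector(spec, des,
                         beta = matrix(c(0.4, 0.1), 2, 1,
                                       dimnames = list(NULL, "ss->sp")))
  g0 <- spec$gains$AMPA["sp", "ss"]
  sc <- vapply(1:3, function(cc)
    condition_model(spec, pv, des, cc)$gains$AMPA["sp", "ss"] / g0,
    numeric(1))
  # condition 2: row 1 weight +1, row 2 weight 0; condition 3: 0 and +1
  expect_equal(sc, exp(c(-0.4 - 0.1, 0.4, 0.1)))
})

test_that("beta on a non-free or off-target quantity is rejected", {
  spec <- tc_model()
  des <- condition_design("linear")
  expect_error(parameter_vector(spec, des, beta = c("rl->sp" = 0.1)),
               "non-free")
  des2 <- condition_design("linear", effect_targets = c("rl->ss"))
  expect_error(parameter_vector(spec, des2, beta = c("ss->sp" = 0.1)),
               "effect targets")
  expect_error(condition_model(spec, parameter_vector(spec, des), des, 7),
               "condition index")
})

test_that("exp-scaling keeps modulated gains positive and is negation-symmetric", {
  spec <- tc_model()
  des <- condition_design("linear")
  set.seed(42)
  for (i in 1:10) {
    beta <- setNames(rnorm(14, 0, 2), free_quantities(spec))
    pv <- parameter_vector(spec, des, beta = beta)
    for (cc in 1:3) {
      cm <- condition_model(spec, pv, des, cc)
      expect_true(all(vapply(cm$gains, function(m) all(m >= 0), logical(1))))
      expect_true(all(cm$kinetics$kappa > 0))
    }
    # negating beta and the contrast row leaves every condition unchanged
    des_neg <- des
    des_neg$X <- -des$X
    pv_neg <- parameter_vector(spec, des, beta = -beta)
    for (cc in 1:3)
      expect_equal(condition_model(spec, pv_neg, des_neg, cc)$gains,
                   condition_model(spec, pv, des, cc)$gains)
  }
})

test_that("exogenous input is the stated Gaussian bump", {
  obs <- observation_params(input_onset = 60, input_width = 12,
                            input_amplitude = 30)
  expect_equal(exogenous_input(obs, 60), 30)
  expect_equal(exogenous_input(obs, 60 + 12), 30 * exp(-0.5))
  expect_equal(exogenous_input(obs, 60 - 12), 30 * exp(-0.5))
  expect_lt(exogenous_input(obs, 60 + 6 * 12 + 1), 30 * 1e-7)
  expect_error(observation_params(input_width = 0), "width")
})

test_that("observation parameter invariants hold", {
  expect_error(observation_params(lead_weights = c(sp = 0.2, dp = 0.5)),
               "sp")
  expect_error(observation_params(lead_weights = c(sp = -1)), "non-negative")
  expect_error(observation_params(gain = 0), "gain")
})

test_that("simulated responses are flat without input and identical without effects", {
  spec <- tc_model()
  des <- condition_design("linear")
  obs0 <- observation_params(input_amplitude = 0, baseline_offset = 1.5)
  Y <- simulate_erp(spec, parameter_vector(spec, des), obs0, des,
                    t_grid = seq(0, 150), dt = 0.5)
  expect_equal(max(abs(Y - 1.5)), 0, tolerance = 1e-7)

  Y2 <- sim_subject("beta0", des)
  expect_identical(Y2[, 1], Y2[, 2])
  expect_identical(Y2[, 1], Y2[, 3])

  # determinism: a repeated call is bit-identical
  des2 <- condition_design("linear")
  pv <- parameter_vector(spec, des2, beta = c("ss->sp" = 0.1))
  Ya <- simulate_erp(spec, pv, tc_obs_default, des2, dt = 0.5)
  Yb <- simulate_erp(spec, pv, tc_obs_default, des2, dt = 0.5)
  expect_identical(Ya, Yb)
})

test_that("potentiating the input pathway amplifies the late response", {
  spec <- tc_model()
  des <- condition_design("linear")
  pv <- parameter_vector(spec, des, beta = c("rl->ss" = 0.3))
  Y <- simulate_erp(spec, pv, tc_obs_default, des, dt = 0.5)
  expect_gt(max(abs(Y[, "late_post"])), max(abs(Y[, "pre"])))
})

test_that("cortex-only variant removes the thalamus and reroutes the input", {
  spec <- tc_model()
  cx <- cortex_only_variant(spec)
  expect_length(cx$populations, 6)
  expect_false(any(c("rl", "rt") %in% cx$populations))
  lost <- setdiff(free_quantities(spec), free_quantities(cx))
  expect_setequal(lost, c("rl->ss", "tp->rl"))
  expect_equal(cx$input_target, "ss")

  des <- condition_design("linear", effect_targets = free_quantities(cx))
  Y <- simulate_erp(cx, parameter_vector(cx, des), tc_obs_default, des,
                    dt = 0.5)
  expect_true(all(is.finite(Y)))
  expect_gt(max(abs(Y)), 1)  # the rerouted drive produces a response
  expect_error(cortex_only_variant(cx), "thalamocortical")
})
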