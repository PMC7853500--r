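test_that("default model carries the printed constants and free-parameter partition", {
  spec <- tc_model()
  expect_equal(spec$delay_tc, 3)
  expect_equal(spec$delay_ct, 8)
  expect_equal(spec$V_R, -40)
  expect_equal(nrow(free_connections(spec)), 12)
  expect_setequal(
    paste(free_connections(spec)$source, free_connections(spec)$target,
          sep = "->"),
    c("rl->ss", "ss->ss", "ss->sp", "ss->si", "si->sp", "si->si",
      "sp->sp", "sp->si", "si->ss", "sp->dp", "dp->tp", "tp->rl"))
  expect_equal(spec$free_decay, c("AMPA", "NMDA"))
  expect_length(free_quantities(spec), 14)
  expect_equal(length(spec$populations), 8)
})

test_that("overrides pass through and unknown keys are rejected", {
  spec <- tc_model(V_R = -45)
  expect_equal(spec$V_R, -45)
  expect_equal(spec$delay_tc, 3)  # untouched
  expect_error(tc_model(nonsense = 1), "nonsense")
  expect_error(tc_model(5), "named")
})

test_that("structural invariants reject invalid architectures", {
  # M/H channels outside tp/rl
  base <- tc_model()
  for (i in 1:5) {
    set.seed(i)
    bad_pop <- sample(setdiff(base$populations, c("tp", "rl")), 1)
    gM <- base$gM; gM[bad_pop] <- runif(1, 0.1, 2)
    expect_error(tc_model(gM = gM), "M/H")
  }
  # inhibitory source with excitatory coupling
  g <- base$gains
  g$AMPA["sp", "si"] <- 0.5
  expect_error(tc_model(gains = g), "si")
  # excitatory source with GABA coupling
  g <- base$gains
  g$GABA_A["sp", "ss"] <- 0.5
  expect_error(tc_model(gains = g), "ss")
  # non-positive dispersion and delays
  expect_error(tc_model(Sigma = 0), "Sigma")
  expect_error(tc_model(delay_tc = 0), "delay")
})

test_that("firing sigmoid is the Gaussian CDF around threshold", {
  expect_equal(firing_rate(-40, -40, 3), 0.5)
  expect_equal(firing_rate(-40, -40, 12), 0.5)
  # one dispersion above threshold: standard normal CDF at 1 (frozen from
  # an independent erf evaluation)
  expect_equal(firing_rate(-40 + 6, -40, 6), 0.8413447, tolerance = 1e-6)
  expect_equal(firing_rate(-1e4, -40, 8), 0)
  expect_equal(firing_rate(1e4, -40, 8), 1)
  v <- firing_rate(seq(-90, 10, length.out = 400), -40, 8)
  expect_true(all(diff(v) > 0))
  expect_error(firing_rate(-40, -40, 0), "Sigma")
  expect_error(firing_rate(-40, -40, -2), "Sigma")
})

test_that("magnesium block follows the stated gating function", {
  expect_equal(mg_block(0, 0.06), 1 / 1.2)
  # hand evaluation of 1/(1 + 0.2 exp(3.6))
  expect_equal(mg_block(-60, 0.06), 0.120197409, tolerance = 1e-7)
  expect_equal(mg_block(1e5, 0.06), 1)
  v <- mg_block(seq(-100, 60, length.out = 1000), 0.06)
  expect_true(all(v > 0 & v < 1))
  expect_true(all(diff(v) > 0))
  expect_error(mg_block(0, 0), "alpha")
})

test_that("state derivative respects leak equilibrium and driving-force signs", {
  spec <- tc_model()
  # decoupled leak: zero derivative at V_L with no gains, no intrinsic
  g0 <- lapply(spec$gains, function(m) m * 0)
  spec0 <- tc_model(gains = g0, gM = spec$gM * 0, gH = spec$gH * 0)
  st <- tc_state(spec0)  # V = V_L, g = 0
  d <- state_derivative(spec0, st)
  expect_equal(max(abs(d$V)), 0)
  expect_equal(max(abs(d$g)), 0)

  # a fixed AMPA conductance below reversal depolarises
  st2 <- tc_state(spec0)
  st2$g["sp", "AMPA"] <- 0.5
  d2 <- state_derivative(spec0, st2)
  expect_gt(d2$V["sp"], 0)

  # NMDA current is larger in magnitude at depolarised potentials (same g)
  stA <- tc_state(spec0, V = c(sp = -70)); stA$g["sp", "NMDA"] <- 0.5
  stB <- tc_state(spec0, V = c(sp = -30)); stB$g["sp", "NMDA"] <- 0.5
  iA <- 0.5 * mg_block(-70) * (spec0$kinetics$V_rev["NMDA"] - (-70))
  iB <- 0.5 * mg_block(-30) * (spec0$kinetics$V_rev["NMDA"] - (-30))
  expect_gt(iB, iA)  # direct evaluations of the gated current
})

test_that("R reference derivative matches the compiled dynamics", {
  spec <- tc_model()
  ss <- find_steady_state(spec)
  # at the fixed point the R derivative must vanish too
  d <- state_derivative(spec, ss)
  expect_lt(max(abs(d$V)), 1e-9)
  expect_lt(max(abs(d$g)), 1e-9)

  # away from the fixed point: compare R derivative against a small
  # compiled step (finite difference of the integrator)
  set.seed(1)
  st <- tc_state(spec, V = ss$V + rnorm(8, 0, 3),
                 g = ss$g * matrix(runif(48, 0.5, 1.5), 8, 6))
  dR <- state_derivative(spec, st)
  h <- 1e-4
  tr <- tc_integrate(spec, u = NULL, t_span = 8, dt = h, init = st,
                     out_dt = h)
  dV_num <- (tr$V[2, ] - tr$V[1, ]) / h
  expect_equal(unname(dV_num), unname(dR$V), tolerance = 1e-3)
})

test_that("missing delay history is rejected with the required horizon", {
  spec <- tc_model()
  st <- find_steady_state(spec)
  bad_history <- function(tq) if (tq < -5) NULL else st$V
  expect_error(state_derivative(spec, st, t = 0, history = bad_history),
               "history")
})

test_that("steady state: decoupled exact solution and perturbation robustness", {
  spec <- tc_model()
  g0 <- lapply(spec$gains, function(m) m * 0)
  spec0 <- tc_model(gains = g0, gM = spec$gM * 0, gH = spec$gH * 0)
  ss0 <- find_steady_state(spec0)
  expect_equal(unname(ss0$V), rep(-70, 8))
  expect_equal(max(abs(ss0$g)), 0)

  # default spec: residual tiny, and relaxation integration agrees
  ss <- find_steady_state(spec)
  expect_lt(attr(ss, "residual"), 1e-9)
  # relaxation horizon must cover the slowest channel (GABA-B, 200 ms)
  relax <- tc_integrate(spec, u = NULL, t_span = 4000, dt = 0.5,
                        init = tc_state(spec), out_dt = 4000)
  expect_lt(max(abs(relax$V[nrow(relax$V), ] - ss$V)), 1e-6)

  # constant drive shifts the fixed point
  ssu <- find_steady_state(spec, u0 = c(rl = 5))
  expect_gt(ssu$V["rl"], ss$V["rl"])
})

test_that("integration from the fixed point is stationary", {
  spec <- tc_model()
  ss <- find_steady_state(spec)
  tr <- tc_integrate(spec, u = NULL, t_span = 100, dt = 0.25, init = ss)
  dev <- abs(sweep(tr$V, 2, ss$V))
  expect_lt(max(dev), 1e-6)
})

test_that("impulse responses respect the conduction delays", {
  spec <- tc_model()
  ss <- find_steady_state(spec)
  imp <- function(pop, t0) function(t) {
    U <- matrix(0, length(t), 8)
    U[, which(spec$populations == pop)] <- ifelse(t >= t0 & t < t0 + 1, 50, 0)
    U
  }
  for (delays in list(c(3, 8), c(2, 5), c(4.5, 6.5))) {
    sp2 <- tc_model(delay_tc = delays[1], delay_ct = delays[2])
    ss2 <- find_steady_state(sp2)
    tr <- tc_integrate(sp2, u = imp("rl", 30), t_span = 80, dt = 0.25,
                       init = ss2, out_dt = 0.25)
    lag_ts <- tr$t[which(abs(tr$V[, "ss"] - ss2$V["ss"]) > 1e-9)[1]] - 30
    expect_lt(abs(lag_ts - delays[1]), 0.25 + 1e-9)
    tr <- tc_integrate(sp2, u = imp("tp", 30), t_span = 80, dt = 0.25,
                       init = ss2, out_dt = 0.25)
    lag_ct <- tr$t[which(abs(tr$V[, "rl"] - ss2$V["rl"]) > 1e-9)[1]] - 30
    expect_lt(abs(lag_ct - delays[2]), 0.25 + 1e-9)
  }
})

test_that("step halving converges and degenerate integration inputs are rejected", {
  spec <- tc_model()
  uf <- function(t) {
    U <- matrix(0, length(t), 8)
    U[, 7] <- exogenous_input(tc_obs_default, t)
    U
  }
  o1 <- tc_integrate(spec, u = uf, t_span = 300, dt = 0.5)
  o2 <- tc_integrate(spec, u = uf, t_span = 300, dt = 0.25)
  o3 <- tc_integrate(spec, u = uf, t_span = 300, dt = 0.125)
  d12 <- max(abs(o1$V - o2$V))
  d23 <- max(abs(o2$V - o3$V))
  expect_lt(d23, d12)           # error shrinks with the step
  expect_lt(max(abs(o2$V[nrow(o2$V), ] - o3$V[nrow(o3$V), ])), 1e-3)

  expect_error(tc_integrate(spec, t_span = 0), "t_span")
  expect_error(tc_integrate(spec, t_span = 100, dt = -0.1), "dt")
  expect_error(tc_integrate(spec, t_span = 100, dt = 0.7), "dt")
  expect_error(tc_integrate(spec, t_span = 4), "delay")
})
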