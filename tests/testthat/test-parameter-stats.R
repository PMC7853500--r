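test_that("condition parameter values follow the design scaling", {
  des <- condition_design("linear")
  Y <- sim_subject("b_sssp", des, beta = c("ss->sp" = 0.25))
  fit <- invert_evoked(Y, tc_spec, tc_obs_default, des,
                       settings = list(max_iter = 1, dt = 0.5))
  # overwrite the posterior with exact values to check the mapping alone
  fit$mean[] <- 0
  fit$mean["th:ss->sp"] <- 0.1
  fit$mean["b1:ss->sp"] <- 0.3
  cp <- condition_parameters(fit, des, tc_spec)
  base <- tc_spec$gains$AMPA["sp", "ss"]
  expect_equal(unname(cp[, "ss->sp"]),
               base * exp(0.1 + 0.3 * c(-1, 0, 1)))
  # all other connections at baseline in every condition
  expect_equal(unname(cp[, "rl->ss"]), rep(tc_spec$gains$AMPA["ss", "rl"], 3))
  # decay rates are reported as time constants: positive rate scaling
  # shortens the time constant
  fit$mean[] <- 0
  fit$mean["th:kappa_AMPA"] <- 0.5
  cp2 <- condition_parameters(fit, des, tc_spec)
  expect_equal(unname(cp2[, "kappa_AMPA"]),
               rep(4 * exp(-0.5), 3))  # tau_AMPA default 4 ms
  # design mismatch is rejected
  expect_error(condition_parameters(fit, condition_design("nonlinear"),
                                    tc_spec), "design")
})

test_that("Wilks' lambda matches the determinant-ratio brute force", {
  set.seed(31)
  n <- 12
  tab <- array(rnorm(n * 3 * 2), c(n, 3, 2),
               dimnames = list(NULL, c("pre", "early_post", "late_post"),
                               c("a", "b")))
  tab[, 2, 1] <- tab[, 2, 1] + 0.8  # real condition effect on parameter a
  m <- rm_manova(tab)

  # independent oracle: explicit E and H and a determinant ratio
  D <- cbind(tab[, 2, 1] - tab[, 1, 1], tab[, 3, 1] - tab[, 1, 1],
             tab[, 2, 2] - tab[, 1, 2], tab[, 3, 2] - tab[, 1, 2])
  Dc <- sweep(D, 2, colMeans(D))
  E <- t(Dc) %*% Dc
  H <- n * colMeans(D) %*% t(colMeans(D))
  expect_equal(m$lambda, det(E) / det(E + H), tolerance = 1e-10)
  expect_true(m$p > 0 && m$p < 1)
  expect_equal(m$n_dv, 4)

  # scale invariance
  m10 <- rm_manova(tab * 10)
  expect_equal(m10$lambda, m$lambda, tolerance = 1e-12)

  # exact null: zero mean difference scores give lambda 1, p 1
  tab0 <- array(NA_real_, c(8, 3, 2))
  set.seed(5)
  for (p in 1:2) {
    b <- rnorm(8)
    d1 <- rnorm(8); d1 <- d1 - mean(d1)
    d2 <- rnorm(8); d2 <- d2 - mean(d2)
    tab0[, 1, p] <- b; tab0[, 2, p] <- b + d1; tab0[, 3, p] <- b + d2
  }
  m0 <- rm_manova(tab0)
  expect_equal(m0$lambda, 1)
  expect_equal(m0$F, 0)
  expect_equal(m0$p, 1)
})

test_that("MANOVA preconditions are enforced", {
  set.seed(32)
  # too few subjects for the dependent variables
  tab <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  expect_error(rm_manova(tab), "subsetting")
  # collinear parameters
  tab2 <- array(rnorm(10 * 3 * 2), c(10, 3, 2),
                dimnames = list(NULL, NULL, c("a", "b")))
  tab2[, , 2] <- 2 * tab2[, , 1]
  expect_error(rm_manova(tab2), "singular")
})

test_that("single-parameter MANOVA equals the multivariate univariate follow-up", {
  set.seed(33)
  tab <- array(rnorm(14 * 3), c(14, 3, 1), dimnames = list(NULL, NULL, "a"))
  tab[, 2, 1] <- tab[, 2, 1] + 0.5
  m <- rm_manova(tab)
  u <- univariate_followups(tab)
  expect_equal(m$p, u$p_mv[1], tolerance = 1e-8)
})

test_that("univariate repeated-measures F matches the aov error-stratum oracle", {
  set.seed(34)
  n <- 9
  Y <- matrix(rnorm(n * 3), n, 3)
  Y[, 3] <- Y[, 3] + 1
  tab <- array(Y, c(n, 3, 1), dimnames = list(NULL, NULL, "a"))
  u <- univariate_followups(tab)

  d <- data.frame(y = as.numeric(Y),
                  cond = factor(rep(1:3, each = n)),
                  subj = factor(rep(seq_len(n), 3)))
  a <- summary(stats::aov(y ~ cond + Error(subj / cond), data = d))
  Ftab <- a[["Error: subj:cond"]][[1]]
  expect_equal(u$F[1], Ftab["cond", "F value"], tolerance = 1e-10)
  expect_equal(u$p[1], Ftab["cond", "Pr(>F)"], tolerance = 1e-10)
})

test_that("FDR correction reproduces hand-computed rejection sets", {
  # construct per-parameter data whose uncorrected p-values are then
  # BH-adjusted; the rejection set must match the hand step-up rule
  set.seed(35)
  n <- 12
  effs <- c(1.6, 0.9, 0.7, 0.0)
  tab <- array(rnorm(n * 3 * 4, sd = 0.8), c(n, 3, 4),
               dimnames = list(NULL, NULL, paste0("p", 1:4)))
  for (k in 1:3) tab[, 2:3, k] <- tab[, 2:3, k] + effs[k]
  u <- univariate_followups(tab, q = 0.05)

  hand_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- max(c(0, which(p[o] <= seq_len(m) * q / m)))
    rej <- rep(FALSE, m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  expect_equal(u$significant, hand_bh(u$p_gg, 0.05))

  # monotonicity of adjusted p-values in raw-p order, and nesting of
  # rejection sets across FDR levels
  o <- order(u$p_gg)
  expect_true(all(diff(u$p_fdr[o]) >= -1e-12))
  u01 <- univariate_followups(tab, q = 0.01)
  expect_true(all(which(u01$significant) %in% which(u$significant)))

  # direction reflects the post-minus-pre change
  expect_equal(u$direction[1], 1)
})

test_that("zero-variance parameters are flagged and excluded from the correction", {
  set.seed(36)
  tab <- array(rnorm(10 * 3 * 3), c(10, 3, 3),
               dimnames = list(NULL, NULL, c("a", "flat", "c")))
  tab[, , 2] <- 1
  u <- univariate_followups(tab)
  expect_true(u$excluded[2])
  expect_true(is.na(u$p_fdr[2]))
  expect_false(any(u$excluded[c(1, 3)]))
})
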