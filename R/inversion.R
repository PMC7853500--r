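# Variational Laplace (Gauss-Newton) inversion of the generative model.
#
# One subject's three-condition waveforms are fitted simultaneously under a
# condition-contrast design.  Parameters are log-scalings with Gaussian
# priors; observation noise is i.i.d. Gaussian with a single precision per
# subject, estimated between parameter updates.  The free energy
# F = accuracy - complexity is the Laplace approximation to the log model
# evidence and is the quantity entering Bayesian model selection.

#' Priors for model inversion
#'
#' Gaussian shrinkage priors, mean zero, over all estimable log-scaling
#' quantities: subject-level `theta` for the 12 free connections and 2 free
#' decay rates, per-effect-row `beta` for the design's effect targets, and
#' the log observation gain.  A zero prior variance fixes a quantity.
#'
#' @param spec a `tc_model`
#' @param design a `tc_design`
#' @param theta_var prior variance of connection/decay log-scalings
#' @param beta_var prior variance of condition-effect sizes
#' @param gain_var prior variance of the log observation gain (0 fixes it)
#' @param noise list with `shape` and `scale` of the Gamma hyperprior on
#'   the observation precision, and optionally `fixed` (a precision value
#'   that disables estimation)
#' @return object of class `tc_priors` with `mean` and `var` vectors over
#'   the full parameter layout
#' @export
default_priors <- function(spec, design,
                           theta_var = 1 / 16, beta_var = 1 / 8,
                           gain_var = 1 / 16,
                           noise = list(shape = 1, scale = 1e6,
                                        fixed = NULL)) {
  lay <- .par_layout(spec, design, estimate_gain = gain_var > 0)
  v <- numeric(length(lay$names))
  v[lay$kind == "theta"] <- theta_var
  v[lay$kind == "beta"] <- beta_var
  v[lay$kind == "obs"] <- gain_var
  structure(list(mean = setNames(numeric(length(v)), lay$names),
                 var = setNames(v, lay$names),
                 noise = modifyList(list(shape = 1, scale = 1e6,
                                         fixed = NULL), noise),
                 layout = lay),
            class = "tc_priors")
}

# full parameter layout: theta block, beta block (effect targets only),
# optional observation gain
.par_layout <- function(spec, design, estimate_gain = TRUE) {
  qn <- free_quantities(spec)
  targets <- intersect(design$effect_targets, qn)
  nr <- nrow(design$X)
  nm <- paste0("th:", qn)
  kind <- rep("theta", length(qn))
  quant <- qn
  row <- rep(NA_integer_, length(qn))
  for (k in seq_len(nr)) {
    nm <- c(nm, paste0("b", k, ":", targets))
    kind <- c(kind, rep("beta", length(targets)))
    quant <- c(quant, targets)
    row <- c(row, rep(k, length(targets)))
  }
  if (estimate_gain) {
    nm <- c(nm, "obs:log_gain")
    kind <- c(kind, "obs")
    quant <- c(quant, "log_gain")
    row <- c(row, NA_integer_)
  }
  list(names = nm, kind = kind, quantity = quant, row = row,
       n_free = length(qn), free_names = qn, targets = targets, n_rows = nr)
}

# parameter vector -> (tc_params, scaled obs)
.unpack_pars <- function(p, lay, spec, design, obs) {
  th <- setNames(p[lay$kind == "theta"], lay$free_names)
  B <- matrix(0, lay$n_rows, lay$n_free,
              dimnames = list(rownames(design$X), lay$free_names))
  for (k in seq_len(lay$n_rows)) {
    sel <- lay$kind == "beta" & lay$row == k
    B[k, lay$quantity[sel]] <- p[sel]
  }
  pars <- structure(list(theta = th, beta = B), class = "tc_params")
  if (any(lay$kind == "obs")) {
    obs$gain <- obs$gain * exp(p[lay$kind == "obs"])
  }
  list(params = pars, obs = obs)
}

# conditions whose predicted waveform depends on parameter i
.affected_conditions <- function(lay, design) {
  nC <- ncol(design$X)
  lapply(seq_along(lay$names), function(i) {
    if (lay$kind[i] == "beta") which(design$X[lay$row[i], ] != 0)
    else seq_len(nC)
  })
}

#' Free energy of a posterior candidate
#'
#' The Laplace free energy `F = accuracy - complexity`: expected Gaussian
#' log-likelihood of the residuals under the estimated noise precision
#' (including the sensitivity-weighted posterior-uncertainty term when
#' `sensitivities` are supplied) minus the KL divergence from the Gaussian
#' posterior candidate to the prior.  For a linear-Gaussian model with the
#' exact posterior this equals the log model evidence.
#'
#' @param residuals data minus prediction, concatenated over conditions
#' @param posterior list with `mean` and `cov`
#' @param priors a `tc_priors`, or list with `mean` and `var` (or `cov`)
#' @param lambda log observation precision
#' @param sensitivities optional Jacobian of the prediction at the
#'   posterior mean (residual x parameter)
#' @return list with `F`, `accuracy`, `complexity` (nats)
#' @export
free_energy <- function(residuals, posterior, priors, lambda,
                        sensitivities = NULL) {
  if (any(!is.finite(residuals))) stop("residuals must be finite")
  N <- length(residuals)
  tau <- exp(lambda)
  Sq <- posterior$cov
  ch <- tryCatch(chol(Sq), error = function(e)
    stop("posterior covariance candidate is not positive definite"))
  ess <- sum(residuals^2)
  if (!is.null(sensitivities))
    ess <- ess + sum((sensitivities %*% Sq) * sensitivities)
  accuracy <- -N / 2 * log(2 * pi) + N / 2 * lambda - tau / 2 * ess

  m0 <- priors$mean
  S0 <- if (!is.null(priors$cov)) priors$cov else diag(priors$var,
                                                       length(priors$var))
  dm <- posterior$mean - m0
  S0i <- solve(S0)
  p <- length(m0)
  complexity <- 0.5 * (sum(S0i * Sq) + as.numeric(t(dm) %*% S0i %*% dm) -
                         p + determinant(S0)$modulus -
                         2 * sum(log(diag(ch))))
  list(F = as.numeric(accuracy - complexity),
       accuracy = as.numeric(accuracy),
       complexity = as.numeric(complexity))
}

# noise precision update (Gamma hyperprior, point estimate at the mode)
.update_tau <- function(ess, N, noise) {
  if (!is.null(noise$fixed)) return(noise$fixed)
  (noise$shape - 1 + N / 2) / (1 / noise$scale + ess / 2)
}

#' Invert the model for one subject
#'
#' Fits the generative model to a subject's per-condition waveforms by
#' variational Laplace: Gauss-Newton updates of the posterior mean using
#' central finite-difference sensitivities of the concatenated predicted
#' waveform, a closed-form Laplace posterior covariance, and a noise
#' precision updated between parameter steps.  A step is accepted only if
#' the free energy does not decrease (the step is halved otherwise), so
#' the recorded free-energy trace is non-decreasing.  Deterministic: no
#' randomness is used.
#'
#' @param data time x 3 condition matrix of observed waveforms on the grid
#'   `t_grid`
#' @param spec a `tc_model`
#' @param obs a `tc_obs`
#' @param design a `tc_design`
#' @param priors a `tc_priors`; defaults to [default_priors()]
#' @param settings list; recognised entries `max_iter` (64), `tol` (0.01
#'   nats), `patience` (3), `fd_step` (1e-3), `dt` (0.25 ms),
#'   `estimate_gain` (TRUE), `inner_steps` (2; cheap refinement steps that
#'   reuse the current sensitivities between full evaluations), `t_grid`
#'   (0..300 ms), `init` (optional named start vector, e.g. a nested
#'   model's posterior mapped onto this layout; default is the prior
#'   mean), `verbose` (FALSE)
#' @return object of class `tc_posterior`: posterior `mean` and `cov`,
#'   log-precision `lambda`, free energy `F` with `F_trace`, per-condition
#'   `fitted` waveforms, `explained_variance`, and accuracy/complexity
#'   decomposition
#' @export
invert_evoked <- function(data, spec, obs = observation_params(),
                          design = condition_design("linear"),
                          priors = NULL, settings = list()) {
  s <- modifyList(list(max_iter = 64, tol = 0.01, patience = 3,
                       fd_step = 1e-3, dt = 0.25, estimate_gain = TRUE,
                       inner_steps = 2, t_grid = NULL, init = NULL,
                       verbose = FALSE),
                  settings)
  t_grid <- if (is.null(s$t_grid)) seq(0, nrow(data) - 1) else s$t_grid
  stopifnot(nrow(data) == length(t_grid), ncol(data) == ncol(design$X))
  if (is.null(priors))
    priors <- default_priors(spec, design,
                             gain_var = if (s$estimate_gain) 1 / 16 else 0)
  lay <- priors$layout
  if (is.null(lay)) stop("priors must carry a parameter layout; use default_priors()")
  nC <- ncol(design$X)
  nt <- length(t_grid)
  y <- as.numeric(data)
  N <- length(y)

  predict_some <- function(p, conds) {
    up <- .unpack_pars(p, lay, spec, design, obs)
    simulate_erp(spec, up$params, up$obs, design, t_grid, dt = s$dt,
                 conditions = conds)
  }
  # candidate points can leave the feasible regime (no reachable steady
  # state); the line search treats those as rejected steps
  predict_try <- function(p) {
    tryCatch(predict_some(p, seq_len(nC)), error = function(e) NULL)
  }
  predict_all <- function(p) predict_some(p, seq_len(nC))

  affected <- .affected_conditions(lay, design)
  jacobian <- function(p, Ybase) {
    J <- matrix(0, N, length(p))
    h <- s$fd_step
    for (i in seq_along(p)) {
      if (fixed[i]) next
      conds <- affected[[i]]
      pp <- p; pp[i] <- p[i] + h
      Yp <- predict_some(pp, conds)
      pm <- p; pm[i] <- p[i] - h
      Ym <- predict_some(pm, conds)
      d <- (Yp - Ym) / (2 * h)
      d[is.na(d)] <- 0  # unsimulated conditions are unaffected
      J[, i] <- as.numeric(d)
    }
    J
  }

  m0 <- priors$mean
  fixed <- priors$var <= 0
  act <- !fixed
  p_all <- length(m0)
  S0a <- diag(priors$var[act], sum(act))
  S0ia <- diag(1 / priors$var[act], sum(act))

  # consistent evaluation of a parameter point: prediction, Jacobian,
  # precision update, Laplace covariance, free energy
  evaluate <- function(mu) {
    Yhat <- predict_all(mu)
    if (any(!is.finite(Yhat)))
      stop("prediction non-finite at the evaluated parameters; check priors")
    e <- y - as.numeric(Yhat)
    J <- jacobian(mu, Yhat)
    Ja <- J[, act, drop = FALSE]
    tau <- .update_tau(sum(e^2), N, priors$noise)
    Sqa <- NULL
    for (rep in 1:2) {
      H <- tau * crossprod(Ja) + S0ia
      ch <- tryCatch(chol(H), error = function(err) NULL)
      if (is.null(ch)) {
        # near-singular curvature: regularise and report the conditioning
        ridge <- 1e-6 * max(diag(H))
        ch <- chol(H + diag(ridge, nrow(H)))
        warning("singular curvature regularised (ridge = ",
                format(ridge), ")")
      }
      Sqa <- chol2inv(ch)
      ess <- sum(e^2) + sum((Ja %*% Sqa) * Ja)
      tau <- .update_tau(ess, N, priors$noise)
    }
    fe <- free_energy(e, list(mean = mu[act], cov = Sqa),
                      list(mean = m0[act], cov = S0a), log(tau),
                      sensitivities = Ja)
    list(mu = mu, Yhat = Yhat, e = e, J = J, Ja = Ja, tau = tau, Sqa = Sqa,
         F = fe$F, accuracy = fe$accuracy, complexity = fe$complexity)
  }

  cur <- NULL
  if (!is.null(s$init)) {
    start <- m0
    common <- intersect(names(s$init), lay$names)
    start[common] <- s$init[common]
    start[fixed] <- m0[fixed]
    cur <- tryCatch(evaluate(start), error = function(e) NULL)
  }
  if (is.null(cur)) cur <- evaluate(m0)
  trace <- cur$F
  still <- 0L
  screen_F <- function(mu, e) {
    free_energy(e, list(mean = mu[act], cov = cur$Sqa),
                list(mean = m0[act], cov = S0a),
                log(cur$tau), sensitivities = cur$Ja)$F
  }
  for (it in seq_len(s$max_iter)) {
    # one Gauss-Newton step, then cheap refinement steps that reuse the
    # current sensitivities (lagged Jacobian) before the next full
    # evaluation; each candidate is screened on its own prediction
    mu_w <- cur$mu
    e_w <- cur$e
    F_w <- screen_F(mu_w, e_w)
    n_sub <- 0L
    for (sub in seq_len(1L + s$inner_steps)) {
      g <- cur$tau * crossprod(cur$Ja, e_w) - S0ia %*% (mu_w[act] - m0[act])
      dmu <- numeric(p_all)
      dmu[act] <- as.numeric(cur$Sqa %*% g)
      moved <- FALSE
      alpha <- 1
      for (half in 0:6) {
        muc <- mu_w + alpha * dmu
        Yc <- predict_try(muc)
        if (is.null(Yc) || any(!is.finite(Yc))) { alpha <- alpha / 2; next }
        ec <- y - as.numeric(Yc)
        Fc <- screen_F(muc, ec)
        if (Fc >= F_w - 1e-9) {
          mu_w <- muc; e_w <- ec; F_w <- Fc
          moved <- TRUE
          n_sub <- n_sub + 1L
          break
        }
        alpha <- alpha / 2
      }
      if (!moved) break
    }
    accepted <- NULL
    if (n_sub > 0L) {
      cand <- tryCatch(evaluate(mu_w), error = function(e) NULL)
      if (!is.null(cand) && cand$F >= cur$F - 1e-9) accepted <- cand
    }
    if (is.null(accepted) && n_sub > 1L) {
      # lagged-Jacobian refinement overshot: retry the plain single step
      g <- cur$tau * crossprod(cur$Ja, cur$e) - S0ia %*% (cur$mu[act] - m0[act])
      dmu <- numeric(p_all)
      dmu[act] <- as.numeric(cur$Sqa %*% g)
      alpha <- 1
      for (half in 0:6) {
        muc <- cur$mu + alpha * dmu
        Yc <- predict_try(muc)
        if (is.null(Yc) || any(!is.finite(Yc))) { alpha <- alpha / 2; next }
        ec <- y - as.numeric(Yc)
        if (screen_F(muc, ec) < cur$F - 1e-9) { alpha <- alpha / 2; next }
        cand <- tryCatch(evaluate(muc), error = function(e) NULL)
        if (is.null(cand)) { alpha <- alpha / 2; next }
        if (cand$F >= cur$F - 1e-9) { accepted <- cand; break }
        alpha <- alpha / 2
      }
    }
    if (is.null(accepted)) break
    dF <- accepted$F - cur$F
    cur <- accepted
    trace <- c(trace, cur$F)
    if (s$verbose)
      message(sprintf("iter %d: F = %.4f (dF = %.4f)", it, cur$F, dF))
    still <- if (dF < s$tol) still + 1L else 0L
    if (still >= s$patience) break
  }

  fitted <- cur$Yhat
  colnames(fitted) <- colnames(design$X)
  sst <- sum((y - mean(y))^2)
  Sq <- matrix(0, p_all, p_all, dimnames = list(lay$names, lay$names))
  Sq[act, act] <- cur$Sqa
  structure(list(
    mean = setNames(cur$mu, lay$names),
    cov = Sq,
    lambda = log(cur$tau),
    F = cur$F, F_trace = trace,
    accuracy = cur$accuracy, complexity = cur$complexity,
    fitted = fitted,
    explained_variance = 1 - sum(cur$e^2) / sst,
    design = design$name,
    layout = lay,
    t_grid = t_grid,
    iterations = length(trace) - 1L), class = "tc_posterior")
}

#' Posterior effect sizes as a matrix
#'
#' @param posterior a `tc_posterior`
#' @return effect-row x quantity matrix of posterior-mean betas
#' @export
posterior_betas <- function(posterior) {
  lay <- posterior$layout
  nr <- lay$n_rows
  B <- matrix(0, nr, length(lay$targets),
              dimnames = list(NULL, lay$targets))
  for (k in seq_len(nr)) {
    sel <- lay$kind == "beta" & lay$row == k
    B[k, lay$quantity[sel]] <- posterior$mean[sel]
  }
  B
}

#' @export
print.tc_posterior <- function(x, ...) {
  cat("tc_posterior (design:", x$design, ")\n")
  cat("  F =", round(x$F, 2), "nats after", x$iterations, "iterations\n")
  cat("  explained variance =", round(x$explained_variance, 4), "\n")
  invisible(x)
}
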