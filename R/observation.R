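# Observation model and condition-contrast designs.
#
# The measured evoked response is a single source-level channel: a fixed
# non-negative lead field over population depolarisations, dominated by the
# superficial pyramidal population, times an estimable scalar gain.
# Condition-specific effects enter through a between-condition general
# linear model: each free quantity q is scaled by
# exp(theta_q + sum_k beta_kq * X[k, condition]).

#' Observation parameters
#'
#' @param lead_weights named non-negative contribution weight per
#'   population; the superficial pyramidal (sp) weight must be largest.
#'   Populations not named get weight zero.
#' @param gain output scale (> 0); the only observation quantity estimated
#'   by default (on the log scale)
#' @param input_onset,input_width centre and width (ms) of the Gaussian
#'   exogenous drive; width must be positive
#' @param input_amplitude peak drive amplitude
#' @param baseline_offset additive signal offset
#' @return object of class `tc_obs`
#' @export
observation_params <- function(lead_weights = c(sp = 0.8, dp = 0.1, tp = 0.1),
                               gain = 1,
                               input_onset = 64, input_width = 8,
                               input_amplitude = 25,
                               baseline_offset = 0) {
  if (any(lead_weights < 0)) stop("lead weights must be non-negative")
  if (!("sp" %in% names(lead_weights)) ||
      lead_weights["sp"] < max(lead_weights))
    stop("the superficial pyramidal (sp) lead weight must be the largest")
  if (gain <= 0) stop("gain must be positive")
  if (input_width <= 0) stop("input width must be positive")
  structure(list(lead_weights = lead_weights, gain = gain,
                 input_onset = input_onset, input_width = input_width,
                 input_amplitude = input_amplitude,
                 baseline_offset = baseline_offset),
            class = "tc_obs")
}

#' Condition-contrast design
#'
#' The three between-condition designs over (pre, early post, late post):
#' `nonlinear` `[-1 1 0]` (early-peaking change), `linear` `[-1 0 1]`
#' (monotone change largest late), and `combination`
#' `[-1 1 0; -1 0 1]` carrying both effect rows.
#'
#' @param name one of `"nonlinear"`, `"linear"`, `"combination"`
#' @param effect_targets free quantities the effect rows modulate; default
#'   all 12 free connections plus the AMPA and NMDA decay rates
#' @return object of class `tc_design` with contrast matrix `X`
#'   (effects x 3 conditions)
#' @export
condition_design <- function(name = c("nonlinear", "linear", "combination"),
                             effect_targets = NULL) {
  name <- match.arg(name)
  X <- switch(name,
    nonlinear = matrix(c(-1, 1, 0), 1, 3, byrow = TRUE),
    linear = matrix(c(-1, 0, 1), 1, 3, byrow = TRUE),
    combination = matrix(c(-1, 1, 0, -1, 0, 1), 2, 3, byrow = TRUE)
  )
  rownames(X) <- switch(name,
    nonlinear = "nonlinear", linear = "linear",
    combination = c("nonlinear", "linear"))
  colnames(X) <- .cond_labels
  if (is.null(effect_targets)) effect_targets <- free_quantities(tc_model())
  structure(list(name = name, X = X, effect_targets = effect_targets),
            class = "tc_design")
}

#' Subject-level parameter vector
#'
#' Log-scaling parameters for one subject: `theta` (one entry per free
#' quantity, subject-level deviation) and `beta` (effect sizes, one row per
#' design effect, columns over free quantities).  All zeros reproduces the
#' default model in every condition.
#'
#' @param spec a `tc_model`
#' @param design a `tc_design` (determines the number of effect rows);
#'   `NULL` for zero rows
#' @param theta named numeric; unnamed scalar recycled
#' @param beta matrix (effects x free quantities) or a named numeric
#'   applied to the single effect row
#' @return object of class `tc_params`
#' @export
parameter_vector <- function(spec = tc_model(), design = NULL,
                             theta = 0, beta = NULL) {
  qn <- free_quantities(spec)
  th <- setNames(rep_len(0, length(qn)), qn)
  if (!is.null(names(theta))) {
    bad <- setdiff(names(theta), qn)
    if (length(bad)) stop("theta names not free quantities: ",
                          paste(bad, collapse = ", "))
    th[names(theta)] <- theta
  } else th[] <- rep_len(theta, length(qn))

  nr <- if (is.null(design)) 0L else nrow(design$X)
  B <- matrix(0, nr, length(qn),
              dimnames = list(rownames(design$X), qn))
  if (!is.null(beta) && nr > 0) {
    if (is.matrix(beta)) {
      stopifnot(nrow(beta) == nr)
      bad <- setdiff(colnames(beta), qn)
      if (length(bad)) stop("beta refers to non-free quantities: ",
                            paste(bad, collapse = ", "))
      B[, colnames(beta)] <- beta
    } else {
      bad <- setdiff(names(beta), qn)
      if (length(bad)) stop("beta refers to non-free quantities: ",
                            paste(bad, collapse = ", "))
      B[1, names(beta)] <- beta
    }
  }
  if (!is.null(design)) {
    off_target <- setdiff(colnames(B)[colSums(B != 0) > 0],
                          design$effect_targets)
    if (length(off_target))
      stop("beta on quantities outside the design's effect targets: ",
           paste(off_target, collapse = ", "))
  }
  structure(list(theta = th, beta = B), class = "tc_params")
}

#' Apply condition-specific scaling to a model
#'
#' Returns a new `tc_model` in which every free quantity q is scaled by
#' `exp(theta_q + sum_k beta_kq X[k, condition])`; fixed parameters are
#' untouched and the input spec is not modified.  Free connection scalings
#' multiply both channel gains of the edge (AMPA+NMDA for excitatory
#' sources, GABA-A+GABA-B for inhibitory); free decay scalings multiply the
#' channel rate constant.
#'
#' @param spec a `tc_model`
#' @param params a `tc_params`
#' @param design a `tc_design`
#' @param condition condition index, 1..3 (pre, early post, late post)
#' @return a new `tc_model`
#' @export
condition_model <- function(spec, params, design, condition) {
  if (!(condition %in% seq_len(ncol(design$X))))
    stop("condition index must be in 1..", ncol(design$X))
  qn <- free_quantities(spec)
  th <- setNames(rep_len(0, length(qn)), qn)
  th[names(params$theta)] <- params$theta
  s <- th
  if (nrow(params$beta) > 0) {
    if (nrow(params$beta) != nrow(design$X))
      stop("beta rows do not match the design's effect rows")
    s <- s + as.numeric(t(params$beta[, qn, drop = FALSE]) %*%
                          design$X[, condition])
  }
  out <- spec
  fm <- spec$free_mask
  for (r in seq_len(nrow(fm))) {
    nm <- paste0(fm$source[r], "->", fm$target[r])
    mult <- exp(s[nm])
    kinds <- if (fm$source[r] %in% spec$inhibitory)
      c("GABA_A", "GABA_B") else c("AMPA", "NMDA")
    for (kk in kinds)
      out$gains[[kk]][fm$target[r], fm$source[r]] <-
        spec$gains[[kk]][fm$target[r], fm$source[r]] * mult
  }
  for (dk in spec$free_decay)
    out$kinetics$kappa[dk] <- spec$kinetics$kappa[dk] * exp(s[paste0("kappa_", dk)])
  out
}

#' Gaussian exogenous drive
#'
#' `amplitude * exp(-(t - onset)^2 / (2 width^2))`; in the thalamocortical
#' model the drive enters the thalamic relay population, in the cortex-only
#' variant the spiny stellate population.
#'
#' @param obs a `tc_obs`
#' @param t time (ms), vectorised
#' @return drive value(s)
#' @export
exogenous_input <- function(obs, t) {
  if (obs$input_width <= 0) stop("input width must be positive")
  obs$input_amplitude *
    exp(-(t - obs$input_onset)^2 / (2 * obs$input_width^2))
}

#' Simulate the per-condition evoked response
#'
#' For each condition: builds the condition-scaled model, finds its steady
#' state, integrates under the Gaussian drive, and projects the
#' depolarisations (relative to steady state) through the lead field:
#' `gain * sum_p w_p (V_p(t) - V_p(steady)) + baseline_offset`.
#'
#' @param spec a `tc_model`
#' @param params a `tc_params`
#' @param obs a `tc_obs`
#' @param design a `tc_design`
#' @param t_grid uniform output time grid (ms) starting at 0
#' @param dt integration step (ms)
#' @param conditions condition indices to simulate (default all three);
#'   unsimulated columns are returned as NA
#' @return time x condition waveform matrix (columns pre, early_post,
#'   late_post), with per-condition steady states in attribute `"steady"`
#' @export
simulate_erp <- function(spec, params = parameter_vector(spec, design),
                         obs = observation_params(),
                         design = condition_design("linear"),
                         t_grid = seq(0, 300), dt = 0.25,
                         conditions = NULL) {
  stopifnot(length(t_grid) > 1)
  out_dt <- t_grid[2] - t_grid[1]
  if (max(abs(diff(t_grid) - out_dt)) > 1e-8) stop("t_grid must be uniform")
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  if (max(t_grid) < obs$input_onset)
    stop("t_grid must cover the input onset")

  pops <- spec$populations
  np <- length(pops)
  w <- setNames(rep_len(0, np), pops)
  keep <- intersect(names(obs$lead_weights), pops)
  w[keep] <- obs$lead_weights[keep]
  target <- spec$input_target

  ufun <- function(t) {
    U <- matrix(0, length(t), np, dimnames = list(NULL, pops))
    U[, target] <- exogenous_input(obs, t)
    U
  }

  nC <- ncol(design$X)
  if (is.null(conditions)) conditions <- seq_len(nC)
  Y <- matrix(NA_real_, length(t_grid), nC,
              dimnames = list(NULL, colnames(design$X)))
  steadies <- vector("list", nC)
  for (cc in conditions) {
    cspec <- condition_model(spec, params, design, cc)
    ss <- find_steady_state(cspec)
    traj <- tc_integrate(cspec, u = ufun, t_span = max(t_grid), dt = dt,
                         init = ss, out_dt = out_dt)
    Y[, cc] <- obs$gain * as.numeric((traj$V - matrix(ss$V, nrow(traj$V),
                                                      np, byrow = TRUE)) %*% w) +
      obs$baseline_offset
    steadies[[cc]] <- ss
  }
  attr(Y, "steady") <- steadies
  attr(Y, "t") <- t_grid
  Y
}

#' Cortex-only comparison model
#'
#' Removes the thalamic relay and reticular populations and every edge
#' touching them; the exogenous Gaussian drive is rerouted into the layer
#' IV spiny stellate population.  The free-connection mask loses exactly
#' the thalamic edges (rl->ss and tp->rl).
#'
#' @param spec the thalamocortical `tc_model`
#' @return a 6-population `tc_model`
#' @export
cortex_only_variant <- function(spec) {
  if (!all(.pops_thalamic %in% spec$populations))
    stop("spec is not the thalamocortical model")
  keep <- setdiff(spec$populations, .pops_thalamic)
  out <- spec
  out$populations <- keep
  out$inhibitory <- intersect(spec$inhibitory, keep)
  out$gains <- lapply(spec$gains, function(m) m[keep, keep, drop = FALSE])
  out$gM <- spec$gM[keep]
  out$gH <- spec$gH[keep]
  out$C <- rep_len(spec$C, length(spec$populations))[
    spec$populations %in% keep]
  out$Sigma <- spec$Sigma[keep]
  fm <- spec$free_mask
  out$free_mask <- fm[fm$source %in% keep & fm$target %in% keep, ,
                      drop = FALSE]
  rownames(out$free_mask) <- NULL
  out$input_target <- "ss"
  class(out) <- "tc_model"
  validate_model(out)
  out
}
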