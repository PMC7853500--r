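# Model core: the 8-population thalamocortical conductance neural-mass model.
#
# Populations (Fig.-2-style single column): layer IV spiny stellate (ss),
# layer II/III superficial pyramidal (sp) and inhibitory interneurons (si),
# layer V deep pyramidal (dp) and deep inhibitory interneurons (di), layer VI
# thalamic-projection pyramidal (tp), thalamic relay (rl) and reticular (rt).
# Dynamics per population: C dV/dt = g_L (V_L - V) + sum_n g_n (V_n - V)
# (NMDA gated by the magnesium-block sigmoid) + u, and first-order channel
# kinetics dg_n/dt = kappa_n (sigma_n - g_n), where sigma_n is the coupled
# presynaptic firing.  Thalamo-cortical edges are delayed by delay_tc and
# cortico-thalamic edges by delay_ct.

# canonical free-connection list (source -> target), fixed by the model family
.free_edges <- data.frame(
  source = c("rl", "ss", "ss", "ss", "si", "si", "sp", "sp", "si", "sp", "dp", "tp"),
  target = c("ss", "ss", "sp", "si", "sp", "si", "sp", "si", "ss", "dp", "tp", "rl"),
  stringsAsFactors = FALSE
)

# full default edge table: source, target, base coupling strength, free flag.
# Solid (fixed) edges complete a canonical microcircuit plus the
# thalamo-cortical loop; dotted (free) edges are the 12 estimable connections.
.default_edges <- function() {
  e <- rbind(
    data.frame(source = "rl", target = "ss", strength = 1.2, free = TRUE),
    data.frame(source = "rl", target = "rt", strength = 0.3, free = FALSE),
    data.frame(source = "ss", target = "ss", strength = 0.3, free = TRUE),
    data.frame(source = "ss", target = "sp", strength = 1.2, free = TRUE),
    data.frame(source = "ss", target = "si", strength = 0.6, free = TRUE),
    data.frame(source = "ss", target = "dp", strength = 0.6, free = FALSE),
    data.frame(source = "sp", target = "sp", strength = 0.3, free = TRUE),
    data.frame(source = "sp", target = "si", strength = 0.6, free = TRUE),
    data.frame(source = "sp", target = "dp", strength = 0.6, free = TRUE),
    data.frame(source = "sp", target = "di", strength = 0.3, free = FALSE),
    data.frame(source = "dp", target = "tp", strength = 0.6, free = TRUE),
    data.frame(source = "dp", target = "di", strength = 0.3, free = FALSE),
    data.frame(source = "tp", target = "rl", strength = 0.5, free = TRUE),
    data.frame(source = "tp", target = "rt", strength = 0.3, free = FALSE),
    data.frame(source = "si", target = "sp", strength = 2.0, free = TRUE),
    data.frame(source = "si", target = "si", strength = 1.0, free = TRUE),
    data.frame(source = "si", target = "ss", strength = 1.0, free = TRUE),
    data.frame(source = "di", target = "dp", strength = 2.0, free = FALSE),
    data.frame(source = "di", target = "di", strength = 1.0, free = FALSE),
    data.frame(source = "di", target = "tp", strength = 1.0, free = FALSE),
    data.frame(source = "rt", target = "rl", strength = 1.0, free = FALSE),
    data.frame(source = "rt", target = "rt", strength = 0.5, free = FALSE)
  )
  rownames(e) <- NULL
  e
}

.default_kinetics <- function() {
  list(
    # decay time constants (ms): AMPA 4, GABA_A 16, NMDA 100, GABA_B 200,
    # M 160, H 100; kappa = 1/tau
    kappa = c(AMPA = 1 / 4, NMDA = 1 / 100, GABA_A = 1 / 16,
              GABA_B = 1 / 200, M = 1 / 160, H = 1 / 100)[.kinds],
    V_rev = c(AMPA = 60, NMDA = 10, GABA_A = -90, GABA_B = -100,
              M = -70, H = -30)[.kinds],
    alpha_NMDA = 0.06
  )
}

# fraction of an edge's strength carried by the slow channel of its pair
.nmda_ratio <- 0.25
.gabab_ratio <- 0.1

.edge_gain_matrices <- function(edges, populations, inhibitory) {
  np <- length(populations)
  gains <- lapply(.syn_kinds, function(k) {
    m <- matrix(0, np, np, dimnames = list(populations, populations))
    m
  })
  names(gains) <- .syn_kinds
  for (r in seq_len(nrow(edges))) {
    src <- edges$source[r]; tgt <- edges$target[r]; s <- edges$strength[r]
    if (src %in% inhibitory) {
      gains$GABA_A[tgt, src] <- gains$GABA_A[tgt, src] + s
      gains$GABA_B[tgt, src] <- gains$GABA_B[tgt, src] + s * .gabab_ratio
    } else {
      gains$AMPA[tgt, src] <- gains$AMPA[tgt, src] + s
      gains$NMDA[tgt, src] <- gains$NMDA[tgt, src] + s * .nmda_ratio
    }
  }
  gains
}

#' Build the thalamocortical conductance model specification
#'
#' Constructs the default eight-population model of one visual-cortical
#' column plus thalamus: six cortical populations (ss, sp, si, dp, di, tp)
#' and two thalamic populations (rl relay, rt reticular).  Excitatory
#' sources couple through AMPA and NMDA conductances, inhibitory sources
#' through GABA-A and GABA-B; M- and H-currents are intrinsic to the
#' cortico-thalamic projection cells (tp) and thalamic relay cells (rl)
#' only.  Twelve connections (`free_connections(spec)`) plus the AMPA and
#' NMDA decay rates are estimable; everything else is fixed.
#'
#' Defaults: firing threshold `V_R = -40` mV, leak reversal `V_L = -70` mV,
#' thalamo-cortical conduction delay 3 ms and cortico-thalamic delay 8 ms,
#' membrane capacitance `C = 8` (so the leak time constant is 8 ms with
#' `g_L = 1`), firing dispersion `Sigma = 8` mV (one standard
#' deviation of the firing CDF spans 8 mV about threshold).
#'
#' @param ... named overrides of model fields.  Valid names: `kinetics`
#'   (list with any of `kappa`, `V_rev`, `alpha_NMDA`), `gains` (list of
#'   four target-by-source matrices named AMPA/NMDA/GABA_A/GABA_B), `gM`,
#'   `gH`, `C`, `V_R`, `Sigma`, `V_L`, `g_L`, `delay_tc`, `delay_ct`,
#'   `free_decay`.  Unknown names are rejected.
#' @return An object of class `tc_model`.
#' @examples
#' spec <- tc_model()
#' spec$delay_tc  # 3 ms
#' nrow(free_connections(spec))  # 12
#' @export
tc_model <- function(...) {
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == "")))
    stop("all overrides must be named")

  populations <- .pops_tc
  inhibitory <- .pops_inhib
  np <- length(populations)
  edges <- .default_edges()

  gM <- setNames(numeric(np), populations)
  gH <- setNames(numeric(np), populations)
  gM[c("tp", "rl")] <- 1
  gH[c("tp", "rl")] <- 0.5

  spec <- list(
    populations = populations,
    inhibitory = inhibitory,
    kinetics = .default_kinetics(),
    gains = .edge_gain_matrices(edges, populations, inhibitory),
    gM = gM, gH = gH,
    free_mask = .free_edges,
    C = 8, V_R = -40,
    Sigma = setNames(rep(8, np), populations),
    V_L = -70, g_L = 1,
    delay_tc = 3, delay_ct = 8,
    free_decay = c("AMPA", "NMDA"),
    input_target = "rl"
  )

  for (key in names(overrides)) {
    if (!key %in% names(spec))
      stop("unknown model override: '", key, "'")
    if (key == "kinetics") {
      spec$kinetics <- modifyList(spec$kinetics, overrides$kinetics)
    } else if (key == "Sigma" && length(overrides$Sigma) == 1) {
      spec$Sigma[] <- overrides$Sigma
    } else {
      spec[[key]] <- overrides[[key]]
    }
  }
  class(spec) <- "tc_model"
  validate_model(spec)
  spec
}

#' The estimable (free) connections of a model
#'
#' @param spec a `tc_model`
#' @return data frame with columns `source`, `target`
#' @export
free_connections <- function(spec) spec$free_mask

#' Names of all estimable model quantities
#'
#' The 12 free connection gains (as `"source->target"`) followed by the
#' free channel decay rates (`"kappa_AMPA"`, `"kappa_NMDA"`).
#'
#' @param spec a `tc_model`
#' @return character vector
#' @export
free_quantities <- function(spec) {
  c(paste0(spec$free_mask$source, "->", spec$free_mask$target),
    paste0("kappa_", spec$free_decay))
}

#' Validate a model specification
#'
#' Enforces the structural invariants of the model family: positive rate
#' constants and dispersions, strictly positive conduction delays,
#' excitatory reversal potentials above inhibitory ones, M/H channels
#' restricted to tp and rl, inhibitory sources coupling only through
#' GABA channels and excitatory sources only through AMPA/NMDA.
#'
#' @param spec a `tc_model`
#' @return the spec, invisibly; errors describe the violated invariant
#' @export
validate_model <- function(spec) {
  k <- spec$kinetics
  if (any(k$kappa <= 0)) stop("all channel rate constants must be positive")
  if (min(k$V_rev[c("AMPA", "NMDA")]) <= max(k$V_rev[c("GABA_A", "GABA_B")]))
    stop("excitatory reversal potentials must exceed inhibitory ones")
  if (k$alpha_NMDA <= 0) stop("alpha_NMDA must be positive")
  if (any(spec$Sigma <= 0)) stop("Sigma must be positive")
  if (spec$delay_tc <= 0 || spec$delay_ct <= 0)
    stop("conduction delays must be strictly positive")
  if (spec$g_L <= 0 || any(spec$C <= 0)) stop("C and g_L must be positive")

  pops <- spec$populations
  mh_allowed <- intersect(c("tp", "rl"), pops)
  bad_mh <- pops[(spec$gM > 0 | spec$gH > 0) & !pops %in% mh_allowed]
  if (length(bad_mh))
    stop("M/H channels are only permitted on tp and rl; found on: ",
         paste(bad_mh, collapse = ", "))

  inh <- intersect(spec$inhibitory, pops)
  exc <- setdiff(pops, inh)
  for (kk in c("AMPA", "NMDA")) {
    bad <- inh[colSums(abs(spec$gains[[kk]][, inh, drop = FALSE])) > 0]
    if (length(bad))
      stop("inhibitory source(s) ", paste(bad, collapse = ", "),
           " may not couple through ", kk)
  }
  for (kk in c("GABA_A", "GABA_B")) {
    bad <- exc[colSums(abs(spec$gains[[kk]][, exc, drop = FALSE])) > 0]
    if (length(bad))
      stop("excitatory source(s) ", paste(bad, collapse = ", "),
           " may not couple through ", kk)
  }
  if (any(vapply(spec$gains, function(m) any(m < 0), logical(1))))
    stop("connection gains must be non-negative")
  invisible(spec)
}

#' Population firing sigmoid
#'
#' Proportion of cells firing as a function of the population mean
#' depolarisation: the Gaussian cumulative distribution of
#' `(mu_V - V_R) / Sigma`, i.e. the CDF of the presynaptic depolarisation
#' around the firing threshold.
#'
#' @param mu_V mean membrane potential (mV)
#' @param V_R threshold potential (mV), default -40
#' @param Sigma dispersion of depolarisation about the mean (mV), > 0
#' @return firing proportion in `[0, 1]`
#' @export
firing_rate <- function(mu_V, V_R = -40, Sigma = 8) {
  if (any(Sigma <= 0)) stop("Sigma must be positive")
  pnorm((mu_V - V_R) / Sigma)
}

#' NMDA magnesium-block gating
#'
#' Voltage dependence of the NMDA conductance:
#' `f(V) = 1 / (1 + 0.2 exp(-alpha_NMDA * V))`, a sigmoid that relieves the
#' magnesium block with depolarisation.
#'
#' @param V membrane potential (mV)
#' @param alpha_NMDA gating steepness (1/mV), > 0
#' @return gating factor in `(0, 1)`
#' @export
mg_block <- function(V, alpha_NMDA = 0.06) {
  if (alpha_NMDA <= 0) stop("alpha_NMDA must be positive")
  1 / (1 + 0.2 * exp(-alpha_NMDA * V))
}

# ---- state handling ---------------------------------------------------------

#' Construct a model state
#'
#' @param spec a `tc_model`
#' @param V named voltage vector (mV); recycled scalar allowed
#' @param g population-by-channel conductance matrix (zeros if omitted)
#' @return object of class `tc_state`
#' @export
tc_state <- function(spec, V = spec$V_L, g = NULL) {
  pops <- spec$populations
  np <- length(pops)
  Vv <- setNames(rep_len(V, np), pops)
  if (!is.null(names(V))) Vv[names(V)] <- V
  if (is.null(g)) g <- matrix(0, np, 6, dimnames = list(pops, .kinds))
  structure(list(V = Vv, g = g), class = "tc_state")
}

# delay matrix (target x source): thalamo-cortical and cortico-thalamic
# edges are delayed, everything intra-compartment is instantaneous
.delay_matrix <- function(spec) {
  pops <- spec$populations
  np <- length(pops)
  thal <- pops %in% .pops_thalamic
  D <- matrix(0, np, np, dimnames = list(pops, pops))
  D[!thal, thal] <- spec$delay_tc  # thalamic source -> cortical target
  D[thal, !thal] <- spec$delay_ct  # cortical source -> thalamic target
  D
}

# flatten a spec to the arrays the compiled integrator consumes
.model_pack <- function(spec) {
  pops <- spec$populations
  np <- length(pops)
  D <- .delay_matrix(spec)
  delays <- sort(unique(c(0, D[D > 0])))
  G <- array(0, dim = c(np, np, 4, length(delays)))
  for (k in seq_along(.syn_kinds)) {
    gk <- spec$gains[[.syn_kinds[k]]]
    for (d in seq_along(delays)) {
      sel <- D == delays[d]
      G[, , k, d][sel] <- gk[sel]
    }
  }
  list(np = np, delays = delays, gains = as.numeric(G),
       gM = as.numeric(spec$gM), gH = as.numeric(spec$gH),
       C = rep_len(as.numeric(spec$C), np),
       Sigma = as.numeric(spec$Sigma),
       kappa = as.numeric(spec$kinetics$kappa),
       Vrev = as.numeric(spec$kinetics$V_rev),
       alpha_NMDA = spec$kinetics$alpha_NMDA,
       V_R = spec$V_R, V_L = spec$V_L, g_L = spec$g_L)
}

#' Time derivative of the model state (reference implementation)
#'
#' Pure-R evaluation of the conductance equations: voltage change equals
#' leak plus channel currents `g_n (V_n - V)` (NMDA additionally gated by
#' [mg_block()]) plus exogenous drive, divided by the capacitance;
#' conductances relax at rate `kappa_n` towards the coupled presynaptic
#' firing.  Connections crossing the thalamocortical boundary read the
#' presynaptic potential from `history` at `t - delay`; all other terms use
#' the instantaneous state.  The compiled integrator implements the same
#' dynamics; the two are cross-checked in the test suite.
#'
#' @param spec a `tc_model`
#' @param state a `tc_state`
#' @param u exogenous drive per population (scalar or named vector)
#' @param t current time (ms)
#' @param history `NULL` for a constant (pre-stimulus) history equal to
#'   `state`, or a function `history(t)` returning the voltage vector at
#'   time `t`; must cover `t - max(delay_tc, delay_ct)`
#' @return `tc_state`-shaped list of derivatives (`V` in mV/ms)
#' @export
state_derivative <- function(spec, state, u = 0, t = 0, history = NULL) {
  pops <- spec$populations
  np <- length(pops)
  uu <- setNames(rep_len(0, np), pops)
  if (!is.null(names(u))) uu[names(u)] <- u else uu[] <- rep_len(u, np)

  V <- state$V
  D <- .delay_matrix(spec)
  horizon <- max(D)
  if (is.null(history)) {
    Vhist <- function(tq) V
  } else {
    Vhist <- function(tq) {
      h <- history(tq)
      if (is.null(h) || length(h) != np || any(!is.finite(h)))
        stop("history must provide finite states back to t - ", horizon, " ms")
      h
    }
  }

  Sig <- spec$Sigma
  f_inst <- firing_rate(V, spec$V_R, Sig)
  # per-source firing seen by each target, honouring edge delays
  delays <- sort(unique(c(0, D[D > 0])))
  f_by_delay <- lapply(delays, function(d) {
    if (d == 0) f_inst else firing_rate(Vhist(t - d), spec$V_R, Sig)
  })

  sigma_t <- matrix(0, np, 4, dimnames = list(pops, .syn_kinds))
  for (k in seq_along(.syn_kinds)) {
    gk <- spec$gains[[.syn_kinds[k]]]
    for (d in seq_along(delays)) {
      sel <- D == delays[d]
      gk_d <- gk * sel
      sigma_t[, k] <- sigma_t[, k] + as.numeric(gk_d %*% f_by_delay[[d]])
    }
  }

  kin <- spec$kinetics
  g <- state$g
  dV <- spec$g_L * (spec$V_L - V) + uu
  dV <- dV + g[, "AMPA"] * (kin$V_rev["AMPA"] - V)
  dV <- dV + g[, "NMDA"] * mg_block(V, kin$alpha_NMDA) * (kin$V_rev["NMDA"] - V)
  dV <- dV + g[, "GABA_A"] * (kin$V_rev["GABA_A"] - V)
  dV <- dV + g[, "GABA_B"] * (kin$V_rev["GABA_B"] - V)
  dV <- dV + g[, "M"] * (kin$V_rev["M"] - V) + g[, "H"] * (kin$V_rev["H"] - V)
  dV <- dV / rep_len(spec$C, np)

  dg <- matrix(0, np, 6, dimnames = list(pops, .kinds))
  for (k in .syn_kinds) dg[, k] <- kin$kappa[k] * (sigma_t[, k] - g[, k])
  dg[, "M"] <- kin$kappa["M"] * (spec$gM * f_inst - g[, "M"])
  dg[, "H"] <- kin$kappa["H"] * (spec$gH * (1 - f_inst) - g[, "H"])

  structure(list(V = setNames(dV, pops), g = dg), class = "tc_state")
}

#' Steady state of the model
#'
#' Finds the fixed point of the conductance equations under a constant
#' drive by damped Newton root-finding on the voltage nullcline (at a fixed
#' point every conductance equals its coupled firing target, so the problem
#' reduces to the population voltages), starting from the leak reversal.
#'
#' @param spec a `tc_model`
#' @param u0 constant exogenous drive (scalar or per-population vector)
#' @param tol maximum allowed residual derivative (mV/ms)
#' @return a `tc_state` with attribute `"residual"`
#' @export
find_steady_state <- function(spec, u0 = 0, tol = 1e-9) {
  np <- length(spec$populations)
  uu <- setNames(rep_len(0, np), spec$populations)
  if (!is.null(names(u0))) uu[names(u0)] <- u0 else uu[] <- rep_len(u0, np)
  pack <- .model_pack(spec)
  out <- .tc_steady_cpp(pack, as.numeric(uu), tol = min(tol, 1e-12))
  if (!isTRUE(out$converged) && out$residual > tol) {
    # Newton stalled away from the basin: relax towards the attractor by
    # integration from the leak reversal, then retry from there
    init <- tc_state(spec)
    nst <- 2000L
    U <- matrix(rep(as.numeric(uu), each = 2L * nst + 1L), 2L * nst + 1L, np)
    relax <- .tc_integrate_cpp(pack, U, 0.25, nst, nst,
                               as.numeric(init$V), as.numeric(init$g))
    if (is.null(relax$diverged_at)) {
      out <- .tc_steady_cpp(pack, as.numeric(uu), tol = min(tol, 1e-12),
                            Vstart = as.numeric(relax$V[nrow(relax$V), ]))
    }
  }
  if (!isTRUE(out$converged) && out$residual > tol)
    stop("steady-state search did not converge; residual = ",
         format(out$residual))
  st <- tc_state(spec,
                 V = setNames(out$V, spec$populations),
                 g = matrix(out$g, np, 6,
                            dimnames = list(spec$populations, .kinds)))
  attr(st, "residual") <- out$residual
  st
}

#' Integrate the model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the delayed conductance
#' equations.  Delayed presynaptic firing is read from a stored history
#' with linear interpolation and held fixed across the stages of each step;
#' output is resampled to `out_dt`.
#'
#' @param spec a `tc_model`
#' @param u exogenous drive: `NULL` (none), or a function `u(t)` accepting
#'   a time vector and returning a `length(t)` x n-population matrix
#' @param t_span total duration (ms); must cover the longest delay
#' @param dt integration step (ms), at most 0.5
#' @param init `"steady"` (default) or a `tc_state`
#' @param out_dt output sampling step (ms), a multiple of `dt`
#' @return object of class `tc_trajectory`: `t`, voltage matrix `V`
#'   (time x population) and conductance array `g`
#' @export
tc_integrate <- function(spec, u = NULL, t_span = 300, dt = 0.25,
                         init = "steady", out_dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (dt > 0.5) stop("dt must not exceed 0.5 ms")
  if (t_span <= 0) stop("t_span must be positive")
  if (t_span < max(spec$delay_tc, spec$delay_ct))
    stop("t_span must cover the longest conduction delay")
  nsteps <- round(t_span / dt)
  if (abs(nsteps * dt - t_span) > 1e-8)
    stop("t_span must be a multiple of dt")
  stride <- round(out_dt / dt)
  if (stride < 1 || abs(stride * dt - out_dt) > 1e-8)
    stop("out_dt must be a positive multiple of dt")
  if (nsteps %% stride != 0)
    stop("t_span must be a multiple of out_dt")

  pops <- spec$populations
  np <- length(pops)
  if (identical(init, "steady")) init <- find_steady_state(spec)
  stopifnot(inherits(init, "tc_state"))

  th <- seq(0, t_span, by = dt / 2)
  if (is.null(u)) {
    U <- matrix(0, length(th), np)
  } else {
    U <- u(th)
    if (is.null(dim(U))) U <- matrix(rep(U, np), length(th), np)
    stopifnot(nrow(U) == length(th), ncol(U) == np)
  }

  out <- .tc_integrate_cpp(.model_pack(spec), U, dt, nsteps, stride,
                           as.numeric(init$V), as.numeric(init$g))
  if (!is.null(out$diverged_at))
    stop("non-finite state encountered at t = ", out$diverged_at, " ms")
  V <- out$V
  dimnames(V) <- list(NULL, pops)
  g <- array(out$g, dim = c(nrow(V), np, 6),
             dimnames = list(NULL, pops, .kinds))
  structure(list(t = out$t, V = V, g = g), class = "tc_trajectory")
}

#' @export
print.tc_model <- function(x, ...) {
  cat("Thalamocortical conductance model:", length(x$populations),
      "populations (", paste(x$populations, collapse = ", "), ")\n")
  cat("  free connections:", nrow(x$free_mask),
      "| free decay rates:", paste(x$free_decay, collapse = ", "), "\n")
  cat("  delays: thalamo-cortical", x$delay_tc, "ms, cortico-thalamic",
      x$delay_ct, "ms\n")
  invisible(x)
}

#' @export
print.tc_trajectory <- function(x, ...) {
  cat("tc_trajectory:", nrow(x$V), "samples x", ncol(x$V), "populations, t in [",
      min(x$t), ",", max(x$t), "] ms\n")
  invisible(x)
}
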