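# Seeded synthetic cohorts.
#
# The generator emulates the data shape of a three-condition visual
# long-term-potentiation study: per subject, source-level evoked responses
# (0-300 ms at 1000 Hz) for pre-tetanus, early and late post-tetanus
# blocks, generated from the thalamocortical model itself with known
# subject-level parameter draws and condition effects, plus white Gaussian
# observation noise at a controlled signal-to-noise ratio.

# per-subject RNG stream: independent of cohort size, distinct across
# seeds; kept below 2^31
.subject_seed <- function(seed, i) {
  (as.numeric(seed) * 100003 + i * 7919) %% 2147483629
}

# normalise an effects argument into an effect-rows x free-quantities
# beta matrix
.effects_to_beta <- function(effects, design, qn) {
  nr <- nrow(design$X)
  B <- matrix(0, nr, length(qn), dimnames = list(rownames(design$X), qn))
  if (is.null(effects)) return(B)
  if (is.matrix(effects)) {
    bad <- setdiff(colnames(effects), qn)
    if (length(bad)) stop("effect on non-free quantity: ",
                          paste(bad, collapse = ", "))
    B[, colnames(effects)] <- effects
    return(B)
  }
  if (!is.list(effects)) effects <- list(effects)
  if (length(effects) > nr)
    stop("more effect rows than the design has")
  for (k in seq_along(effects)) {
    e <- effects[[k]]
    bad <- setdiff(names(e), qn)
    if (length(bad)) stop("effect on non-free quantity: ",
                          paste(bad, collapse = ", "))
    B[k, names(e)] <- e
  }
  B
}

#' Generate a synthetic three-condition cohort
#'
#' Per subject: subject-level log-scalings `theta` are drawn from the
#' shrinkage prior (Normal(0, `theta_sd`^2)), the three condition
#' waveforms are simulated from the model under the design and shared
#' condition effects, and white Gaussian noise is added with standard
#' deviation `sd(signal) / sqrt(snr)` per condition, so the per-condition
#' signal-to-noise variance ratio equals `snr`.  All randomness derives
#' from `seed` through a per-subject stream, so subject i's data do not
#' depend on the cohort size.
#'
#' @param n_subjects cohort size (the emulated study has 20)
#' @param design a `tc_design`
#' @param effects condition effects in log units: named numeric (single
#'   effect row), list of named numerics (one per row), or a full beta
#'   matrix; names must be free quantities
#' @param snr per-condition signal/noise variance ratio; `Inf` disables
#'   noise
#' @param seed integer seed
#' @param spec,obs generating model and observation parameters
#' @param t_grid output time grid (ms)
#' @param dt integration step (ms)
#' @param theta_sd between-subject standard deviation of `theta`
#' @return object of class `tc_cohort`: `dataset` (a `tc_dataset`) and
#'   `truth` (theta draws, beta matrix, design name, snr, seed)
#' @export
generate_cohort <- function(n_subjects, design = condition_design("linear"),
                            effects = NULL, snr = 5, seed = 1,
                            spec = tc_model(), obs = observation_params(),
                            t_grid = seq(0, 300), dt = 0.25,
                            theta_sd = 0.25) {
  stopifnot(n_subjects >= 1)
  if (snr <= 0) stop("snr must be positive")
  qn <- free_quantities(spec)
  B <- .effects_to_beta(effects, design, qn)

  theta <- matrix(NA_real_, n_subjects, length(qn),
                  dimnames = list(NULL, qn))
  waves <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    .with_seed(.subject_seed(seed, i), {
      th <- rnorm(length(qn), 0, theta_sd)
      theta[i, ] <- th
      pv <- parameter_vector(spec, design, theta = setNames(th, qn), beta = B)
      Y <- simulate_erp(spec, pv, obs, design, t_grid, dt = dt)
      if (is.finite(snr)) {
        for (cc in seq_len(ncol(Y))) {
          noise_sd <- sd(Y[, cc]) / sqrt(snr)
          Y[, cc] <- Y[, cc] + rnorm(nrow(Y), 0, noise_sd)
        }
      }
      attr(Y, "steady") <- NULL
      attr(Y, "t") <- NULL
      waves[[i]] <- Y
    })
  }

  dataset <- structure(list(
    subjects = sprintf("sub-%02d", seq_len(n_subjects)),
    t = t_grid,
    sampling_rate = 1000 / (t_grid[2] - t_grid[1]),
    condition_labels = .cond_labels,
    waves = waves,
    provenance = list(source = "tcdcm::generate_cohort", seed = seed,
                      design = design$name, snr = snr,
                      package_version = as.character(utils::packageVersion("tcdcm")))),
    class = "tc_dataset")

  structure(list(dataset = dataset,
                 truth = list(theta = theta, beta = B,
                              design = design$name, snr = snr, seed = seed,
                              theta_sd = theta_sd)),
            class = "tc_cohort")
}

#' Canonical LTP recovery scenario
#'
#' A 20-subject, SNR-5 cohort under the combination design with effects
#' placed on the connections where visual LTP studies localise change:
#' linear effects (+0.2 log units) on rl->ss, ss->sp, sp->sp and si->ss;
#' nonlinear effects on ss->sp (+0.2), ss->si (+0.2), sp->dp (-0.2) and
#' the AMPA decay rate (-0.2, i.e. a lengthened AMPA time constant).
#'
#' @param seed integer seed
#' @param n_subjects cohort size
#' @param snr signal-to-noise variance ratio
#' @param ... further arguments passed to [generate_cohort()]
#' @return a `tc_cohort`
#' @export
canonical_ltp_scenario <- function(seed = 1, n_subjects = 20, snr = 5, ...) {
  effects <- list(
    nonlinear = c("ss->sp" = 0.2, "ss->si" = 0.2, "sp->dp" = -0.2,
                  "kappa_AMPA" = -0.2),
    linear = c("rl->ss" = 0.2, "ss->sp" = 0.2, "sp->sp" = 0.2,
               "si->ss" = 0.2)
  )
  generate_cohort(n_subjects, condition_design("combination"),
                  effects = effects, snr = snr, seed = seed, ...)
}

#' @export
print.tc_cohort <- function(x, ...) {
  d <- x$dataset
  cat("tc_cohort:", length(d$waves), "subjects x",
      length(d$condition_labels), "conditions x", length(d$t), "samples\n")
  cat("  generating design:", x$truth$design, "| snr:", x$truth$snr,
      "| seed:", x$truth$seed, "\n")
  invisible(x)
}

#' @export
print.tc_dataset <- function(x, ...) {
  cat("tc_dataset:", length(x$waves), "subjects,",
      length(x$t), "samples at", x$sampling_rate, "Hz\n")
  invisible(x)
}
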