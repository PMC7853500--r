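# Bayesian model selection across subjects.
#
# Fixed effects (FFX): per-subject free energies are summed per model;
# differences of summed F are group log-Bayes factors.  Random effects
# (RFX): a variational Dirichlet model of between-subject model
# frequencies, giving expected frequencies, exceedance probabilities,
# the Bayesian omnibus risk (posterior probability of the equal-frequency
# null) and protected exceedance probabilities.

.check_evidence <- function(F) {
  F <- as.matrix(F)
  if (ncol(F) < 2) stop("Bayesian model selection needs at least 2 models")
  if (nrow(F) < 1) stop("evidence table needs at least 1 subject")
  if (any(!is.finite(F))) stop("all free energies must be finite")
  if (is.null(colnames(F))) colnames(F) <- paste0("model", seq_len(ncol(F)))
  F
}

#' Fixed-effects Bayesian model selection
#'
#' Sums free energies over subjects per model.  Posterior model
#' probabilities assume a uniform model prior; ΔF is reported against the
#' weakest model, and the winning margin against the runner-up.
#'
#' @param F subjects x models matrix of free energies (log evidences)
#' @return list with `group_F`, `delta_F` (vs the weakest model),
#'   `delta_F_runner_up` (winner minus runner-up), `posterior`, `winner`
#' @export
ffx_bms <- function(F) {
  F <- .check_evidence(F)
  gF <- colSums(F)
  post <- exp(gF - max(gF))
  post <- post / sum(post)
  ord <- order(gF, decreasing = TRUE)
  list(group_F = gF,
       delta_F = gF - min(gF),
       delta_F_runner_up = gF[ord[1]] - gF[ord[2]],
       posterior = post,
       winner = names(gF)[ord[1]])
}

# run code with a local RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# variational Dirichlet posterior over model frequencies
.rfx_vb <- function(F, alpha0 = 1, tol = 1e-8, max_iter = 500) {
  n <- nrow(F); K <- ncol(F)
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      # evidence lower bound of the frequency model (H1)
      Es <- digamma(alpha) - digamma(sum(alpha))
      elbo <- sum(u * F) + sum(u %*% Es) +
        lgamma(K * alpha0) - K * lgamma(alpha0) +
        sum((alpha0 - 1) * Es) -
        (lgamma(sum(alpha)) - sum(lgamma(alpha)) +
           sum((alpha - 1) * Es)) -
        sum(u * log(pmax(u, 1e-300)))
      return(list(alpha = alpha, u = u, elbo = elbo, iterations = it))
    }
    alpha <- alpha_new
  }
  stop("Dirichlet updates did not converge; residual = ",
       format(max(abs(alpha_new - alpha))))
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet inference on between-subject model frequencies.
#' Exceedance probabilities are estimated by Monte-Carlo sampling of the
#' posterior Dirichlet with a fixed seed.  The Bayesian omnibus risk (BOR)
#' is the posterior probability of the equal-frequency null model, and the
#' protected exceedance probability is
#' `pxp = xp * (1 - BOR) + BOR / K`.
#'
#' @param F subjects x models matrix of free energies
#' @param n_samples Dirichlet samples for exceedance probabilities
#' @param seed RNG seed for the sampling step (restored afterwards)
#' @param alpha0 Dirichlet prior count per model
#' @return list with `expected_freq`, `alpha`, `xp`, `pxp`, `bor`
#' @export
rfx_bms <- function(F, n_samples = 1e5, seed = 1, alpha0 = 1) {
  F <- .check_evidence(F)
  n <- nrow(F); K <- ncol(F)
  vb <- .rfx_vb(F, alpha0)

  # null model: all frequencies equal, subjects assigned by marginal evidence
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  F0 <- sum(apply(F, 1, lse)) - n * log(K)
  bor <- 1 / (1 + exp(vb$elbo - F0))

  xp <- .with_seed(seed, {
    sm <- matrix(rgamma(n_samples * K, shape = rep(vb$alpha, each = n_samples)),
                 n_samples, K)
    win <- max.col(sm, ties.method = "first")
    tabulate(win, K) / n_samples
  })
  pxp <- xp * (1 - bor) + bor / K
  ef <- vb$alpha / sum(vb$alpha)
  names(ef) <- names(xp) <- names(pxp) <- colnames(F)
  list(expected_freq = ef, alpha = vb$alpha, xp = xp, pxp = pxp, bor = bor)
}

#' Fit and compare candidate models across a cohort
#'
#' Convenience pipeline: inverts every subject under every candidate
#' (a model/design/observation triple), assembles the evidence table, and
#' returns fixed- and random-effects selection results.
#'
#' @param dataset a `tc_dataset` (or `tc_cohort`)
#' @param candidates named list; each element a list with `spec`, `design`
#'   and optionally `obs`
#' @param settings inversion settings passed to [invert_evoked()]
#' @param n_samples,seed passed to [rfx_bms()]
#' @return list with `evidence` (subjects x models), `ffx`, `rfx`, `fits`
#' @export
compare_models <- function(dataset, candidates, settings = list(),
                           n_samples = 1e5, seed = 1) {
  if (inherits(dataset, "tc_cohort")) dataset <- dataset$dataset
  if (length(candidates) < 2)
    stop("Bayesian model selection needs at least 2 models")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  ns <- length(dataset$waves)
  E <- matrix(NA_real_, ns, length(candidates),
              dimnames = list(dataset$subjects, names(candidates)))
  fits <- list()
  for (m in names(candidates)) {
    cand <- candidates[[m]]
    obs <- if (!is.null(cand$obs)) cand$obs else observation_params()
    fits[[m]] <- lapply(seq_len(ns), function(i) {
      invert_evoked(dataset$waves[[i]], cand$spec, obs, cand$design,
                    settings = c(settings, list(t_grid = dataset$t)))
    })
    E[, m] <- vapply(fits[[m]], function(f) f$F, numeric(1))
  }
  list(evidence = E, ffx = ffx_bms(E),
       rfx = rfx_bms(E, n_samples = n_samples, seed = seed), fits = fits)
}
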