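# Group-level statistics on condition-specific parameter estimates:
# repeated-measures MANOVA (Wilks' lambda with Rao's F), univariate
# repeated-measures follow-ups with Greenhouse-Geisser correction, and
# Benjamini-Hochberg FDR across parameters.

#' Condition-specific parameter values for one subject
#'
#' Materialises the quantities entering the group statistics: for each
#' condition, each free quantity's value after applying the subject-level
#' and condition-effect scalings, `base * exp(theta + sum_k beta_k X[k,c])`.
#' Connection entries are reported as coupling strengths (the edge's
#' primary-channel gain); free decay entries are reported as time
#' constants in ms (the reciprocal rate, so a positive rate scaling
#' shortens the time constant).
#'
#' @param posterior a `tc_posterior` fitted under `design`
#' @param design the `tc_design` used for the fit
#' @param spec the `tc_model` used for the fit
#' @return 3 x quantity matrix (conditions in rows)
#' @export
condition_parameters <- function(posterior, design, spec) {
  if (!identical(posterior$design, design$name))
    stop("posterior was fitted under design '", posterior$design,
         "', not '", design$name, "'")
  lay <- posterior$layout
  qn <- lay$free_names
  theta <- posterior$mean[lay$kind == "theta"]
  names(theta) <- qn
  B <- matrix(0, lay$n_rows, length(qn), dimnames = list(NULL, qn))
  for (k in seq_len(lay$n_rows)) {
    sel <- lay$kind == "beta" & lay$row == k
    B[k, lay$quantity[sel]] <- posterior$mean[sel]
  }

  # baseline values: primary-channel gain per free edge, time constant per
  # free decay rate
  fm <- spec$free_mask
  base <- numeric(length(qn))
  names(base) <- qn
  for (r in seq_len(nrow(fm))) {
    nm <- paste0(fm$source[r], "->", fm$target[r])
    kk <- if (fm$source[r] %in% spec$inhibitory) "GABA_A" else "AMPA"
    base[nm] <- spec$gains[[kk]][fm$target[r], fm$source[r]]
  }
  is_decay <- grepl("^kappa_", qn)
  for (nm in qn[is_decay])
    base[nm] <- 1 / spec$kinetics$kappa[sub("^kappa_", "", nm)]

  out <- matrix(NA_real_, 3, length(qn),
                dimnames = list(.cond_labels, qn))
  for (cc in 1:3) {
    s <- theta + if (lay$n_rows > 0)
      as.numeric(t(B) %*% design$X[, cc]) else 0
    v <- base * exp(s)
    v[is_decay] <- base[is_decay] * exp(-s[is_decay])
    out[cc, ] <- v
  }
  out
}

#' Assemble a subjects x conditions x parameters table
#'
#' @param fits list of `tc_posterior`, one per subject
#' @param design,spec as used for the fits
#' @return 3-dimensional array suitable for [rm_manova()] and
#'   [univariate_followups()]
#' @export
parameter_table <- function(fits, design, spec) {
  mats <- lapply(fits, condition_parameters, design = design, spec = spec)
  arr <- array(NA_real_, dim = c(length(fits), 3, ncol(mats[[1]])),
               dimnames = list(NULL, .cond_labels, colnames(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

# difference scores against the first condition: n x (2 * P)
.diff_scores <- function(tab) {
  if (length(dim(tab)) == 2) tab <- array(tab, dim = c(dim(tab), 1),
                                          dimnames = c(dimnames(tab), list("par")))
  n <- dim(tab)[1]; P <- dim(tab)[3]
  D <- matrix(NA_real_, n, 2 * P)
  cn <- character(2 * P)
  for (p in seq_len(P)) {
    D[, 2 * p - 1] <- tab[, 2, p] - tab[, 1, p]
    D[, 2 * p] <- tab[, 3, p] - tab[, 1, p]
    nm <- dimnames(tab)[[3]][p]
    cn[(2 * p - 1):(2 * p)] <- paste0(nm, c(":d21", ":d31"))
  }
  colnames(D) <- cn
  D
}

#' Repeated-measures MANOVA for a condition effect
#'
#' Tests the within-subject effect of condition on the parameter vector
#' via difference scores against the pre condition: Wilks'
#' `lambda = det(E) / det(E + H)` computed from the eigenvalues of
#' `E^-1 H`, with Rao's F approximation.
#'
#' @param tab subjects x 3 conditions x parameters array (a
#'   subjects x 3 matrix is treated as one parameter)
#' @return list with `lambda`, `F`, `df`, `p`, and the number of
#'   dependent variables `n_dv`
#' @export
rm_manova <- function(tab) {
  D <- .diff_scores(tab)
  n <- nrow(D); p <- ncol(D)
  if (n <= p)
    stop("need more subjects (", n, ") than dependent variables (", p,
         "); consider subsetting the parameters")
  ybar <- colMeans(D)
  Dc <- sweep(D, 2, ybar)
  E <- crossprod(Dc)
  H <- n * tcrossprod(ybar)
  qrE <- qr(E)
  if (qrE$rank < p) {
    bad <- colnames(D)[qrE$pivot[(qrE$rank + 1):p]]
    stop("error SSCP matrix is singular; collinear variables: ",
         paste(bad, collapse = ", "))
  }
  ev <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  lambda <- prod(1 / (1 + ev))

  # Rao's approximation (exact here since the hypothesis has one df)
  q <- 1
  v <- n - 1
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- (v - (p - q + 1) / 2) * s - p * q / 2 + 1
  lam_s <- lambda^(1 / s)
  Fstat <- (1 - lam_s) / lam_s * df2 / df1
  list(lambda = lambda, F = Fstat, df = c(df1, df2),
       p = pf(Fstat, df1, df2, lower.tail = FALSE), n_dv = p)
}

#' Benjamini-Hochberg FDR rejection set
#'
#' Step-up false-discovery-rate control across a vector of p-values.
#'
#' @param p p-values
#' @param q FDR level
#' @return list with `p_adjusted` and logical `reject`
#' @export
fdr_reject <- function(p, q = 0.05) {
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

# one-parameter repeated-measures ANOVA over 3 conditions, plus the
# Greenhouse-Geisser corrected and the multivariate (Hotelling) p
.rm_anova_one <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  mc <- colMeans(Y); ms <- rowMeans(Y)
  ss_cond <- n * sum((mc - gm)^2)
  resid <- Y - outer(ms, mc, "+") + gm
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_err <= 0) return(NULL)
  Fstat <- (ss_cond / df1) / (ss_err / df2)

  # Greenhouse-Geisser epsilon from the double-centred covariance
  S <- var(Y)
  Cc <- diag(k) - 1 / k
  Sc <- Cc %*% S %*% Cc
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)

  # multivariate (Hotelling) test on the difference scores
  Dm <- Y[, -1, drop = FALSE] - Y[, 1]
  dbar <- colMeans(Dm)
  Sd <- var(Dm)
  p_mv <- NA_real_
  T2 <- tryCatch(n * as.numeric(t(dbar) %*% solve(Sd, dbar)),
                 error = function(e) NA_real_)
  if (is.finite(T2)) {
    Fm <- T2 * (n - k + 1) / ((n - 1) * (k - 1))
    p_mv <- pf(Fm, k - 1, n - k + 1, lower.tail = FALSE)
  }

  list(F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE),
       gg_epsilon = eps,
       p_gg = pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE),
       p_mv = p_mv)
}

#' Univariate repeated-measures follow-ups with FDR correction
#'
#' One-way repeated-measures ANOVA per parameter across the three
#' conditions, reported with and without Greenhouse-Geisser correction
#' and with the multivariate (Hotelling) p for reference.
#' Benjamini-Hochberg adjustment is applied across parameters (to the
#' Greenhouse-Geisser p by default).  Parameters with zero variance are
#' flagged, excluded from the correction, and reported with NA statistics.
#'
#' @param tab subjects x 3 conditions x parameters array
#' @param q FDR level for the `significant` column
#' @param adjust which p-value the FDR correction uses:
#'   `"gg"` (default) or `"uncorrected"`
#' @return data frame, one row per parameter: F, dfs, p-values, FDR
#'   adjusted p, significance, direction (sign of post-minus-pre change),
#'   and exclusion flag
#' @export
univariate_followups <- function(tab, q = 0.05,
                                 adjust = c("gg", "uncorrected")) {
  adjust <- match.arg(adjust)
  if (length(dim(tab)) == 2) tab <- array(tab, dim = c(dim(tab), 1))
  P <- dim(tab)[3]
  pn <- dimnames(tab)[[3]]
  if (is.null(pn)) pn <- paste0("par", seq_len(P))
  rows <- vector("list", P)
  for (p in seq_len(P)) {
    Y <- tab[, , p]
    if (all(abs(Y - mean(Y)) < 1e-300) || var(as.numeric(Y)) == 0) {
      rows[[p]] <- data.frame(parameter = pn[p], F = NA, df1 = NA, df2 = NA,
                              p = NA, gg_epsilon = NA, p_gg = NA, p_mv = NA,
                              direction = 0, excluded = TRUE)
      next
    }
    a <- .rm_anova_one(Y)
    if (is.null(a)) {
      rows[[p]] <- data.frame(parameter = pn[p], F = NA, df1 = NA, df2 = NA,
                              p = NA, gg_epsilon = NA, p_gg = NA, p_mv = NA,
                              direction = 0, excluded = TRUE)
      next
    }
    direction <- sign(mean(colMeans(Y[, 2:3, drop = FALSE])) - mean(Y[, 1]))
    rows[[p]] <- data.frame(parameter = pn[p], F = a$F, df1 = a$df1,
                            df2 = a$df2, p = a$p, gg_epsilon = a$gg_epsilon,
                            p_gg = a$p_gg, p_mv = a$p_mv,
                            direction = direction, excluded = FALSE)
  }
  out <- do.call(rbind, rows)
  praw <- if (adjust == "gg") out$p_gg else out$p
  ok <- !out$excluded & !is.na(praw)
  out$p_fdr <- NA_real_
  bh <- fdr_reject(praw[ok], q)
  out$p_fdr[ok] <- bh$p_adjusted
  out$significant <- FALSE
  out$significant[ok] <- bh$reject
  rownames(out) <- NULL
  out
}
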