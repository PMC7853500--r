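# shared fixtures (built in code, cheap) and independent oracles

tc_spec <- tc_model()
tc_obs_default <- observation_params()

# Gibbs-sampler oracle for the random-effects frequency model: alternates
# subject assignments z | r and frequencies r | z.  Used only as an
# independent check of the variational implementation.
gibbs_rfx_oracle <- function(F, n_iter = 4000, burn = 1000, alpha0 = 1,
                             seed = 1) {
  n <- nrow(F); K <- ncol(F)
  set.seed(seed)
  r <- rep(1 / K, K)
  acc <- numeric(K)
  kept <- 0
  for (it in seq_len(n_iter)) {
    lw <- sweep(F, 2, log(r), "+")
    lw <- lw - apply(lw, 1, max)
    pz <- exp(lw) / rowSums(exp(lw))
    z <- vapply(seq_len(n), function(i) sample.int(K, 1, prob = pz[i, ]),
                integer(1))
    counts <- tabulate(z, K)
    g <- rgamma(K, shape = alpha0 + counts)
    r <- g / sum(g)
    if (it > burn) { acc <- acc + r; kept <- kept + 1 }
  }
  acc / kept
}

# one noise-free simulated subject under given effects (memoised per key)
.sim_cache <- new.env(parent = emptyenv())
sim_subject <- function(key, design, beta = NULL, theta = 0, dt = 0.5) {
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  pv <- parameter_vector(tc_spec, design, theta = theta, beta = beta)
  Y <- simulate_erp(tc_spec, pv, tc_obs_default, design, dt = dt)
  .sim_cache[[key]] <- Y
  Y
}
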