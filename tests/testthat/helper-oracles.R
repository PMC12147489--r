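# Independent oracles and instance generators used across the suite.
# The brute-force likelihood enumerates every latent path (u, c_1..c_T)
# directly from the model definition; it never touches the recursive code.

brute_force_loglik <- function(params, data) {
  spec <- params$spec
  N <- dim(data$Y)[1]
  grid <- as.matrix(expand.grid(rep(list(seq_len(spec$K)), spec$T)))
  ll <- numeric(N)
  for (i in seq_len(N)) {
    x <- if (is.null(data$X)) numeric(0) else data$X[i, ]
    g <- profile_prevalence(x, params$beta)
    tot <- 0
    for (u in seq_len(spec$S)) for (gi in seq_len(nrow(grid))) {
      pr <- g[u]
      for (t in seq_len(spec$T)) {
        cc <- grid[gi, t]
        z <- if (is.null(data$Z)) numeric(0) else data$Z[i, t, ]
        eta <- class_prevalence(z, params$alpha, u, t)
        pr <- pr * eta[cc] * exp(emission_logprob(data$Y[i, t, ], params, cc, t))
      }
      tot <- tot + pr
    }
    ll[i] <- log(tot)
  }
  ll
}

# Posterior theta_i(u, c_t) by explicit enumeration then marginalization.
brute_force_posterior <- function(params, data) {
  spec <- params$spec
  N <- dim(data$Y)[1]
  grid <- as.matrix(expand.grid(rep(list(seq_len(spec$K)), spec$T)))
  theta <- array(0, dim = c(N, spec$S, spec$T, spec$K))
  for (i in seq_len(N)) {
    x <- if (is.null(data$X)) numeric(0) else data$X[i, ]
    g <- profile_prevalence(x, params$beta)
    joint <- matrix(0, spec$S, nrow(grid))
    for (u in seq_len(spec$S)) for (gi in seq_len(nrow(grid))) {
      pr <- g[u]
      for (t in seq_len(spec$T)) {
        cc <- grid[gi, t]
        z <- if (is.null(data$Z)) numeric(0) else data$Z[i, t, ]
        eta <- class_prevalence(z, params$alpha, u, t)
        pr <- pr * eta[cc] * exp(emission_logprob(data$Y[i, t, ], params, cc, t))
      }
      joint[u, gi] <- pr
    }
    joint <- joint / sum(joint)
    for (t in seq_len(spec$T)) for (cc in seq_len(spec$K)) {
      sel <- grid[, t] == cc
      theta[i, , t, cc] <- rowSums(joint[, sel, drop = FALSE])
    }
  }
  theta
}

# Random valid parameters for a given spec.
random_params <- function(spec) {
  rmax <- max(spec$r)
  tb <- if (spec$rho_time_invariant) 1L else spec$T
  rho <- array(0, dim = c(spec$M, rmax, spec$K, tb))
  for (m in seq_len(spec$M)) for (c in seq_len(spec$K)) for (b in seq_len(tb)) {
    g <- rgamma(spec$r[m], 1)
    rho[m, seq_len(spec$r[m]), c, b] <- g / sum(g)
  }
  beta <- matrix(0, spec$S, spec$P + 1L)
  if (spec$S > 1) beta[-1, ] <- rnorm((spec$S - 1) * (spec$P + 1), 0, 0.8)
  alpha <- array(0, dim = c(spec$T, spec$S, spec$K, spec$Q + 1L))
  if (spec$K > 1)
    alpha[, , -1, ] <- rnorm(spec$T * spec$S * (spec$K - 1) * (spec$Q + 1), 0, 0.8)
  lcpm_params(spec, rho, beta, alpha)
}

# Random small instance: spec, params and a panel (optionally with
# missing outcome cells and covariates).
random_instance <- function(N = 4, K = NULL, S = NULL, T = NULL, M = NULL,
                            with_cov = NULL, miss = 0.1) {
  if (is.null(K)) K <- sample(1:3, 1)
  if (is.null(S)) S <- sample(1:3, 1)
  if (is.null(T)) T <- sample(1:4, 1)
  if (is.null(M)) M <- sample(1:3, 1)
  if (is.null(with_cov)) with_cov <- runif(1) < 0.5
  r <- sample(2:3, M, replace = TRUE)
  spec <- lcpm_spec(K = K, S = S, T = T, M = M, r = r,
                    P = if (with_cov) 1L else 0L,
                    Q = if (with_cov) 1L else 0L,
                    rho_time_invariant = runif(1) < 0.7)
  params <- random_params(spec)
  X <- if (with_cov) matrix(rnorm(N, 1, 1), N, 1) else NULL
  Z <- if (with_cov) array(rnorm(N * T, 1, 1), dim = c(N, T, 1)) else NULL
  sim <- simulate_from_params(params, X = X, Z = Z, N = N)
  Y <- sim$data$Y
  if (miss > 0) Y[runif(length(Y)) < miss] <- NA_integer_
  list(spec = spec, params = params, data = lcpm_data(Y, X = X, Z = Z))
}
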