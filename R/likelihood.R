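# Observed-data likelihood via the forward-backward recursion.
#
# All quantities are computed in log space, vectorized over subjects, so
# that products of T*M small probabilities never underflow.

# log gamma_u(x_i): N x S matrix of log profile-prevalence probabilities.
.log_gamma <- function(params, data, N) {
  Xint <- .design_x(data, N)
  lp <- Xint %*% t(params$beta)
  lp - .row_lse(lp)
}

# log eta_{c|u}^{(t)}(z_it): [N, T, S, K] array.
.log_eta <- function(params, data, N) {
  spec <- params$spec
  out <- array(0, dim = c(N, spec$T, spec$S, spec$K))
  for (t in seq_len(spec$T)) {
    Zint <- .design_z(data, t, N)
    for (u in seq_len(spec$S)) {
      A <- matrix(params$alpha[t, u, , ], nrow = spec$K)
      lp <- Zint %*% t(A)
      out[, t, u, ] <- lp - .row_lse(lp)
    }
  }
  out
}

# log emission P(y_it | C_t = c): [N, T, K] array; missing items contribute 0.
# Probabilities are floored at .LOG_FLOOR inside the log only.
.log_emissions <- function(params, data, N) {
  spec <- params$spec
  out <- array(0, dim = c(N, spec$T, spec$K))
  for (t in seq_len(spec$T)) {
    rho_t <- .rho_at(params, t)
    for (m in seq_len(spec$M)) {
      v <- data$Y[, t, m]
      obs <- which(!is.na(v))
      if (!length(obs)) next
      vo <- v[obs]
      for (c in seq_len(spec$K)) {
        p <- rho_t[m, , c][vo]
        out[obs, t, c] <- out[obs, t, c] + log(pmax(p, .LOG_FLOOR))
      }
    }
  }
  out
}

#' Forward-backward recursion over the latent class sequence
#'
#' Computes, for every subject, the forward probabilities
#' \eqn{\psi_{it}(u, c_t) = P(Y_1..Y_t, C_t = c_t \mid U = u, z)} and the
#' backward probabilities \eqn{\lambda_{it}(u) = P(Y_{t+1}..Y_T \mid U = u,
#' z)} on the log scale, together with the per-subject observed-data
#' log-likelihood. The recursion replaces the \eqn{S K^T} enumeration of
#' latent paths with an \eqn{O(T S K^2)} sweep.
#'
#' @param params An [lcpm_params()] object.
#' @param data An [lcpm_data()] panel.
#' @return A list with components `log_psi` (list over t of `[N, S, K]`
#'   arrays), `log_lambda` (list over t of `[N, S]` matrices), `log_gamma`
#'   (`[N, S]`), `loglik_i` (length-N vector) and `loglik` (total).
#' @export
forward_backward <- function(params, data) {
  spec <- params$spec
  d <- dim(data$Y)
  if (d[2L] != spec$T || d[3L] != spec$M)
    stop("panel dimensions do not match the parameter specification")
  N <- d[1L]
  lgam <- .log_gamma(params, data, N)
  leta <- .log_eta(params, data, N)
  lemi <- .log_emissions(params, data, N)
  K <- spec$K; S <- spec$S; T <- spec$T

  # forward: psi[t][i,u,c]
  log_psi <- vector("list", T)
  for (t in seq_len(T)) {
    cur <- array(0, dim = c(N, S, K))
    for (u in seq_len(S)) {
      base <- leta[, t, u, , drop = TRUE]
      base <- matrix(base, N, K) + matrix(lemi[, t, ], N, K)
      if (t > 1L) {
        prev <- matrix(log_psi[[t - 1L]][, u, ], N, K)
        base <- base + .row_lse(prev)
      }
      cur[, u, ] <- base
    }
    log_psi[[t]] <- cur
  }

  # backward: lambda[t][i,u], lambda[T] = 0
  log_lambda <- vector("list", T)
  log_lambda[[T]] <- matrix(0, N, S)
  if (T > 1L) for (t in (T - 1L):1L) {
    cur <- matrix(0, N, S)
    for (u in seq_len(S)) {
      nxt <- matrix(leta[, t + 1L, u, ], N, K) + matrix(lemi[, t + 1L, ], N, K) +
        log_lambda[[t + 1L]][, u]
      cur[, u] <- .row_lse(nxt)
    }
    log_lambda[[t]] <- cur
  }

  # subject log-likelihood: lse over u of lgam + lse_c psi[T]
  top <- matrix(0, N, S)
  for (u in seq_len(S)) top[, u] <- .row_lse(matrix(log_psi[[T]][, u, ], N, K))
  loglik_i <- .row_lse(lgam + top)

  list(log_psi = log_psi, log_lambda = log_lambda, log_gamma = lgam,
       log_eta = leta, log_emissions = lemi,
       loglik_i = loglik_i, loglik = sum(loglik_i))
}

#' Observed-data log-likelihood of an LCPM
#'
#' @inheritParams forward_backward
#' @return A list with `loglik` (total) and `loglik_i` (per subject).
#' @export
lcpm_loglik <- function(params, data) {
  fb <- forward_backward(params, data)
  list(loglik = fb$loglik, loglik_i = fb$loglik_i)
}

#' E-step posterior membership probabilities
#'
#' Combines the forward and backward passes into the posterior
#' probabilities \eqn{\theta_i(u, c_t) = \gamma_u(x_i) \psi_{it}(u, c_t)
#' \lambda_{it}(u) / L_i} and their marginals \eqn{\theta_i(u)} and
#' \eqn{\theta_i(c_t)}. The stored posterior has dimension
#' `N x S x T x K` rather than the full `K^T x S` path distribution.
#'
#' @inheritParams forward_backward
#' @return An object of class `"lcpm_posterior"`: list with `theta_u_ct`
#'   (`[N, S, T, K]`), `theta_u` (`[N, S]`), `theta_ct` (`[N, T, K]`),
#'   `loglik_i`, and `loglik`.
#' @export
e_step <- function(params, data) {
  spec <- params$spec
  N <- dim(data$Y)[1L]
  fb <- forward_backward(params, data)
  if (any(!is.finite(fb$loglik_i))) {
    bad <- which(!is.finite(fb$loglik_i))
    stop("zero observed-data likelihood (impossible data under the current ",
         "parameters) for subject(s): ", paste(utils::head(bad, 10L), collapse = ", "))
  }
  K <- spec$K; S <- spec$S; T <- spec$T
  theta_u_ct <- array(0, dim = c(N, S, T, K))
  for (t in seq_len(T)) {
    for (u in seq_len(S)) {
      lt <- fb$log_gamma[, u] + matrix(fb$log_psi[[t]][, u, ], N, K) +
        fb$log_lambda[[t]][, u] - fb$loglik_i
      theta_u_ct[, u, t, ] <- exp(lt)
    }
  }
  theta_u <- matrix(0, N, S)
  for (u in seq_len(S)) theta_u[, u] <- rowSums(matrix(theta_u_ct[, u, T, ], N, K))
  theta_ct <- array(0, dim = c(N, T, K))
  for (t in seq_len(T)) for (c in seq_len(K))
    theta_ct[, t, c] <- rowSums(matrix(theta_u_ct[, , t, c], N, S))
  structure(list(theta_u_ct = theta_u_ct, theta_u = theta_u,
                 theta_ct = theta_ct, loglik_i = fb$loglik_i,
                 loglik = fb$loglik),
            class = "lcpm_posterior")
}
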