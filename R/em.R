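# Maximum-likelihood estimation: EM with a recursive E-step, closed-form
# M-step for rho (MAR-corrected under item nonresponse), Newton-Raphson
# updates for the multinomial-logit coefficient blocks, multi-start
# orchestration and boundary-solution handling.

#' Control settings for the EM fit
#'
#' @param max_em_iter Maximum EM iterations per start.
#' @param tol_loglik Relative log-likelihood change below which (jointly with
#'   `tol_param`) the algorithm is declared converged.
#' @param tol_param Maximum absolute parameter change threshold.
#' @param n_starts Number of random initializations; the start with the
#'   highest final log-likelihood wins (ties go to the lowest start index).
#' @param seed Optional RNG seed consumed once at the head of the fit.
#' @param newton_steps_per_m Damped Newton-Raphson steps taken on the
#'   coefficient blocks per M-step; the default 1 yields a generalized EM.
#' @param ridge Hessian regularization added when a Newton solve fails.
#' @param boundary_threshold Minimal expected class-within-profile mass
#'   below which covariate slopes are frozen at zero; `NULL` means
#'   `1e-3 * N`.
#' @return A list of class `"lcpm_control"`.
#' @export
lcpm_control <- function(max_em_iter = 5000L, tol_loglik = 1e-8,
                         tol_param = 1e-6, n_starts = 10L, seed = NULL,
                         newton_steps_per_m = 1L, ridge = 1e-6,
                         boundary_threshold = NULL) {
  stopifnot(tol_loglik > 0, tol_param > 0, n_starts >= 1L, max_em_iter >= 1L)
  structure(list(max_em_iter = as.integer(max_em_iter),
                 tol_loglik = tol_loglik, tol_param = tol_param,
                 n_starts = as.integer(n_starts), seed = seed,
                 newton_steps_per_m = as.integer(newton_steps_per_m),
                 ridge = ridge, boundary_threshold = boundary_threshold),
            class = "lcpm_control")
}

# Random starting values: rho rows are an equal blend of a flat Dirichlet
# draw and the empirical item margins; coefficients are N(0, 0.5) with the
# baseline rows exactly zero.
.init_params <- function(data, spec) {
  rmax <- max(spec$r)
  t_blocks <- if (spec$rho_time_invariant) 1L else spec$T
  rho <- array(0, dim = c(spec$M, rmax, spec$K, t_blocks))
  for (m in seq_len(spec$M)) {
    v <- data$Y[, , m]
    counts <- tabulate(v[!is.na(v)], nbins = spec$r[m]) + 0.5
    marg <- counts / sum(counts)
    for (c in seq_len(spec$K)) for (tb in seq_len(t_blocks)) {
      g <- stats::rgamma(spec$r[m], shape = 1)
      rho[m, seq_len(spec$r[m]), c, tb] <- 0.5 * g / sum(g) + 0.5 * marg
    }
  }
  beta <- matrix(0, spec$S, spec$P + 1L)
  if (spec$S > 1L)
    beta[-1L, ] <- stats::rnorm((spec$S - 1L) * (spec$P + 1L), 0, 0.5)
  alpha <- array(0, dim = c(spec$T, spec$S, spec$K, spec$Q + 1L))
  if (spec$K > 1L)
    alpha[, , -1L, ] <- stats::rnorm(spec$T * spec$S * (spec$K - 1L) * (spec$Q + 1L), 0, 0.5)
  lcpm_params(spec, rho, beta, alpha)
}

# M-step for rho (closed form). With item nonresponse the update follows
# the MAR correction: subjects missing item m at time t contribute their
# posterior class mass times the previous iteration's rho.
m_step_rho <- function(data, posterior, spec, rho_old) {
  rmax <- max(spec$r)
  t_blocks <- if (spec$rho_time_invariant) 1L else spec$T
  rho <- rho_old
  N <- dim(data$Y)[1L]
  for (m in seq_len(spec$M)) {
    rm_ <- spec$r[m]
    for (tb in seq_len(t_blocks)) {
      tset <- if (spec$rho_time_invariant) seq_len(spec$T) else tb
      for (c in seq_len(spec$K)) {
        num <- numeric(rm_); den <- 0
        for (t in tset) {
          w <- posterior$theta_ct[, t, c]
          v <- data$Y[, t, m]
          miss <- is.na(v)
          for (k in seq_len(rm_)) {
            idx <- which(v == k)
            if (length(idx)) num[k] <- num[k] + sum(w[idx])
          }
          if (any(miss))
            num <- num + sum(w[miss]) * rho_old[m, seq_len(rm_), c, tb]
          den <- den + sum(w)
        }
        if (den > 1e-12) rho[m, seq_len(rm_), c, tb] <- num / den
        # else: degenerate (empty) class, keep previous values
      }
    }
  }
  rho
}

# One damped Newton-Raphson pass on beta for the weighted multinomial-logit
# objective sum_i sum_u theta_i(u) log gamma_u(x_i).
.newton_beta <- function(Xint, theta_u, beta, control) {
  S <- nrow(beta); pp <- ncol(Xint)
  if (S == 1L) return(beta)
  obj <- function(B) {
    lp <- Xint %*% t(B)
    lg <- lp - .row_lse(lp)
    sum(theta_u * lg)
  }
  for (step in seq_len(control$newton_steps_per_m)) {
    lp <- Xint %*% t(beta)
    G <- .softmax_rows(lp)
    f0 <- sum(theta_u * (lp - .row_lse(lp)))
    sc <- numeric((S - 1L) * pp)
    H <- matrix(0, (S - 1L) * pp, (S - 1L) * pp)
    for (u in 2L:S) {
      iu <- ((u - 2L) * pp + 1L):((u - 1L) * pp)
      sc[iu] <- crossprod(Xint, theta_u[, u] - G[, u])
      for (v in 2L:S) {
        iv <- ((v - 2L) * pp + 1L):((v - 1L) * pp)
        w <- G[, u] * ((u == v) - G[, v])
        H[iu, iv] <- -crossprod(Xint, Xint * w)
      }
    }
    delta <- tryCatch(solve(-H, sc),
                      error = function(e) solve(-H + control$ridge * diag(nrow(H)), sc))
    lam <- 1
    repeat {
      cand <- beta
      cand[-1L, ] <- beta[-1L, ] + lam * matrix(delta, S - 1L, pp, byrow = TRUE)
      if (obj(cand) >= f0 - 1e-10) { beta <- cand; break }
      lam <- lam / 2
      if (lam < 1e-8) break  # keep previous values
    }
  }
  beta
}

# One damped Newton-Raphson pass on one (t, u) block of alpha for the
# objective sum_i sum_c theta_i(u, c_t) log eta_{c|u}^{(t)}(z_it).
# `free_cols` marks coefficient columns (intercept first) left free per
# class; frozen slopes stay exactly zero.
.newton_alpha_block <- function(Zint, W, A, free_cols, control) {
  K <- nrow(A); pp <- ncol(Zint)
  if (K == 1L) return(A)
  obj <- function(Amat) {
    lp <- Zint %*% t(Amat)
    sum(W * (lp - .row_lse(lp)))
  }
  free_idx <- which(as.vector(t(free_cols[-1L, , drop = FALSE])))  # (c,q) row-major over c=2..K
  if (!length(free_idx)) return(A)
  for (step in seq_len(control$newton_steps_per_m)) {
    lp <- Zint %*% t(A)
    Eta <- .softmax_rows(lp)
    f0 <- sum(W * (lp - .row_lse(lp)))
    wi <- rowSums(W)
    sc <- numeric((K - 1L) * pp)
    H <- matrix(0, (K - 1L) * pp, (K - 1L) * pp)
    for (c in 2L:K) {
      ic <- ((c - 2L) * pp + 1L):((c - 1L) * pp)
      sc[ic] <- crossprod(Zint, W[, c] - wi * Eta[, c])
      for (d in 2L:K) {
        id <- ((d - 2L) * pp + 1L):((d - 1L) * pp)
        w <- wi * Eta[, c] * ((c == d) - Eta[, d])
        H[ic, id] <- -crossprod(Zint, Zint * w)
      }
    }
    sc <- sc[free_idx]
    Hf <- H[free_idx, free_idx, drop = FALSE]
    delta <- tryCatch(solve(-Hf, sc),
                      error = function(e) solve(-Hf + control$ridge * diag(nrow(Hf)), sc))
    lam <- 1
    repeat {
      cand <- A
      full <- numeric((K - 1L) * pp)
      full[free_idx] <- lam * delta
      cand[-1L, ] <- A[-1L, , drop = FALSE] +
        matrix(full, K - 1L, pp, byrow = TRUE)
      if (obj(cand) >= f0 - 1e-10) { A <- cand; break }
      lam <- lam / 2
      if (lam < 1e-8) break
    }
  }
  A
}

#' Newton-Raphson update of the structural coefficients
#'
#' Performs damped Newton-Raphson steps on the expected complete-data
#' log-likelihood terms for `beta` (profile prevalence) and `alpha`
#' (class given profile), holding the E-step posterior weights fixed. Each
#' term is a weighted multinomial-logistic log-likelihood; baseline rows and
#' boundary-frozen slopes stay exactly zero. When a block has no covariates
#' the exact closed-form maximizer (posterior-weighted frequencies mapped to
#' baseline-category logits) is used instead.
#'
#' @param data An [lcpm_data()] panel.
#' @param posterior An `"lcpm_posterior"` from [e_step()].
#' @param params Current [lcpm_params()].
#' @param control An [lcpm_control()].
#' @param frozen Optional logical array `[T, S, K]`; `TRUE` freezes the
#'   covariate slopes of that class-within-profile cell at zero.
#' @return The parameter set with updated `beta` and `alpha`.
#' @export
newton_update <- function(data, posterior, params, control = lcpm_control(),
                          frozen = NULL) {
  spec <- params$spec
  N <- dim(data$Y)[1L]
  if (is.null(frozen)) frozen <- array(FALSE, dim = c(spec$T, spec$S, spec$K))
  beta <- params$beta
  if (spec$S > 1L) {
    if (spec$P == 0L) {
      g <- pmax(colMeans(posterior$theta_u), .LOG_FLOOR)
      beta[, 1L] <- log(g / g[1L])
      beta[1L, 1L] <- 0
    } else {
      beta <- .newton_beta(.design_x(data, N), posterior$theta_u, beta, control)
    }
  }
  alpha <- params$alpha
  if (spec$K > 1L) {
    for (t in seq_len(spec$T)) {
      Zint <- .design_z(data, t, N)
      for (u in seq_len(spec$S)) {
        W <- matrix(posterior$theta_u_ct[, u, t, ], N, spec$K)
        block_frozen <- any(frozen[t, u, ])
        if (spec$Q == 0L || block_frozen) {
          # intercept-only closed form (exact M-step)
          e <- pmax(colSums(W), .LOG_FLOOR)
          A <- matrix(alpha[t, u, , ], nrow = spec$K)
          A[] <- 0
          A[, 1L] <- log(e / e[1L])
          if (spec$Q > 0L) A[, -1L] <- 0
          alpha[t, u, , ] <- A
        } else {
          A <- matrix(alpha[t, u, , ], nrow = spec$K)
          free_cols <- matrix(TRUE, spec$K, spec$Q + 1L)
          alpha[t, u, , ] <- .newton_alpha_block(Zint, W, A, free_cols, control)
        }
      }
    }
  }
  out <- params
  out$beta <- beta
  out$alpha <- alpha
  out
}

# Single EM run from given starting values.
.em_run <- function(data, spec, params, control, frozen) {
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  post <- NULL
  prev_ll <- -Inf
  repeat {
    iter <- iter + 1L
    post <- e_step(params, data)
    ll <- post$loglik
    trace <- c(trace, ll)
    if (iter > 1L) {
      rel <- abs(ll - prev_ll) / (abs(prev_ll) + 1e-10)
      if (rel < control$tol_loglik && param_change < control$tol_param) {
        converged <- TRUE
        break
      }
    }
    if (iter >= control$max_em_iter) break
    prev_ll <- ll
    new_rho <- m_step_rho(data, post, spec, params$rho)
    cand <- params
    cand$rho <- new_rho
    cand <- newton_update(data, post, cand, control, frozen)
    param_change <- max(abs(cand$rho - params$rho),
                        abs(cand$beta - params$beta),
                        abs(cand$alpha - params$alpha))
    params <- cand
  }
  list(params = params, posterior = post, loglik = post$loglik,
       trace = trace, converged = converged, n_iter = iter)
}

# Expected class-within-profile masses sum_i theta_i(u, c_t): [T, S, K].
.cell_mass <- function(posterior, spec) {
  out <- array(0, dim = c(spec$T, spec$S, spec$K))
  for (t in seq_len(spec$T)) for (u in seq_len(spec$S))
    out[t, u, ] <- colSums(matrix(posterior$theta_u_ct[, u, t, ],
                                  ncol = spec$K))
  out
}

#' Fit a latent class profile model by maximum likelihood
#'
#' Runs `n_starts` randomized EM initializations, each alternating the
#' recursive E-step with the closed-form rho update and damped
#' Newton-Raphson coefficient updates, and returns the start with the
#' highest final log-likelihood. After convergence, class-within-profile
#' cells with expected mass below the boundary threshold are detected; the
#' covariate slopes of the affected time-profile blocks are then frozen at
#' zero (intercept-only) and the fit is continued until it reconverges.
#' Frozen slopes are excluded from the free-parameter count.
#'
#' @param data An [lcpm_data()] panel.
#' @param spec An [lcpm_spec()].
#' @param control An [lcpm_control()].
#' @param start Optional [lcpm_params()] used as a single deterministic
#'   start (overrides `n_starts`).
#' @return An object of class `"lcpm_fit"`.
#' @export
fit_lcpm <- function(data, spec, control = lcpm_control(), start = NULL) {
  validate_data(data, spec)
  N <- dim(data$Y)[1L]
  if (!is.null(control$seed)) set.seed(control$seed)
  no_frozen <- array(FALSE, dim = c(spec$T, spec$S, spec$K))
  starts <- if (is.null(start)) control$n_starts else 1L
  runs <- vector("list", starts)
  for (s in seq_len(starts)) {
    p0 <- if (is.null(start)) .init_params(data, spec) else start
    runs[[s]] <- .em_run(data, spec, p0, control, no_frozen)
  }
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best_idx <- which.max(lls)  # ties: lowest index
  best <- runs[[best_idx]]

  # boundary-solution handling: freeze slopes of near-empty cells, refit
  thr <- if (is.null(control$boundary_threshold)) 1e-3 * N else control$boundary_threshold
  boundary_flags <- no_frozen
  if (spec$K > 1L && spec$Q > 0L) {
    mass <- .cell_mass(best$posterior, spec)
    boundary_flags <- mass < thr
    if (any(boundary_flags)) {
      frozen_params <- best$params
      for (t in seq_len(spec$T)) for (u in seq_len(spec$S)) {
        if (any(boundary_flags[t, u, ])) {
          a <- matrix(frozen_params$alpha[t, u, , ], nrow = spec$K)
          a[, -1L] <- 0
          frozen_params$alpha[t, u, , ] <- a
        }
      }
      refit <- .em_run(data, spec, frozen_params, control, boundary_flags)
      best$params <- refit$params
      best$posterior <- refit$posterior
      best$loglik <- refit$loglik
      best$trace <- c(best$trace, refit$trace)
      best$converged <- refit$converged
      best$n_iter <- best$n_iter + refit$n_iter
    }
  }

  structure(list(params = best$params, loglik = best$loglik,
                 loglik_trace = best$trace, converged = best$converged,
                 n_iter = best$n_iter, start_index = best_idx,
                 start_logliks = lls, boundary_flags = boundary_flags,
                 posterior = best$posterior, spec = spec, N = N,
                 control = control, data = data),
            class = "lcpm_fit")
}

#' @export
print.lcpm_fit <- function(x, ...) {
  cat("LCPM fit\n")
  cat(sprintf("  K = %d classes, S = %d profiles, T = %d, N = %d\n",
              x$spec$K, x$spec$S, x$spec$T, x$N))
  cat(sprintf("  log-likelihood: %.4f  (start %d of %d, %sconverged, %d iterations)\n",
              x$loglik, x$start_index, length(x$start_logliks),
              if (x$converged) "" else "NOT ", x$n_iter))
  cat(sprintf("  free parameters: %d   BIC: %.2f\n",
              attr(logLik(x), "df"), stats::BIC(x)))
  if (any(x$boundary_flags))
    cat(sprintf("  boundary solutions: slopes frozen in %d time-profile block(s)\n",
                sum(apply(x$boundary_flags, c(1, 2), any))))
  invisible(x)
}

#' @export
logLik.lcpm_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- n_parameters(object$spec,
                                  boundary_flags = object$boundary_flags)
  attr(val, "nobs") <- object$N
  class(val) <- "logLik"
  val
}

#' @export
nobs.lcpm_fit <- function(object, ...) object$N
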