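# Asymptotic inference from the observed information matrix.
#
# The score of the observed-data log-likelihood is available analytically
# through Fisher's identity: it equals the posterior-expected complete-data
# score, so one E-step per evaluation suffices. The observed information is
# the negative Jacobian of that score, obtained by central differences of
# the analytic score (two E-steps per free parameter).

# Analytic score of the observed-data log-likelihood on the working scale.
.score_obs <- function(vec, data, spec, frozen) {
  params <- unpack_params(vec, spec, frozen)
  post <- e_step(params, data)
  tab <- free_param_table(spec, frozen)
  N <- dim(data$Y)[1L]
  out <- numeric(nrow(tab))

  # rho logits: sum_t sum_{i observed} theta_i(c_t) (I(y = k) - rho_k)
  t_blocks <- if (spec$rho_time_invariant) 1L else spec$T
  for (m in seq_len(spec$M)) for (c in seq_len(spec$K))
    for (tb in seq_len(t_blocks)) {
      idx <- which(tab$type == "rho" & tab$m == m & tab$c == c & tab$t == tb)
      if (!length(idx)) next
      tset <- if (spec$rho_time_invariant) seq_len(spec$T) else tb
      sc <- numeric(length(idx))
      for (t in tset) {
        v <- data$Y[, t, m]
        obs <- !is.na(v)
        if (!any(obs)) next
        w <- post$theta_ct[obs, t, c]
        rho_k <- params$rho[m, , c, tb]
        for (j in seq_along(idx)) {
          k <- tab$k[idx[j]]
          sc[j] <- sc[j] + sum(w * ((v[obs] == k) - rho_k[k]))
        }
      }
      out[idx] <- sc
    }

  # beta: sum_i x_i (theta_i(u) - gamma_u(x_i))
  if (spec$S > 1L) {
    Xint <- .design_x(data, N)
    G <- .softmax_rows(Xint %*% t(params$beta))
    for (u in 2L:spec$S) {
      idx <- which(tab$type == "beta" & tab$u == u)
      sc_full <- drop(crossprod(Xint, post$theta_u[, u] - G[, u]))
      out[idx] <- sc_full[tab$q[idx] + 1L]
    }
  }

  # alpha: sum_i z_it (theta_i(u, c_t) - theta_i(u) eta_{c|u}^{(t)})
  if (spec$K > 1L) for (t in seq_len(spec$T)) {
    Zint <- .design_z(data, t, N)
    for (u in seq_len(spec$S)) {
      A <- matrix(params$alpha[t, u, , ], nrow = spec$K)
      Eta <- .softmax_rows(Zint %*% t(A))
      wi <- post$theta_u[, u]
      for (c in 2L:spec$K) {
        idx <- which(tab$type == "alpha" & tab$t == t & tab$u == u & tab$c == c)
        if (!length(idx)) next
        sc_full <- crossprod(Zint, post$theta_u_ct[, u, t, c] - wi * Eta[, c])
        out[idx] <- sc_full[tab$q[idx] + 1L]
      }
    }
  }
  out
}

#' Observed information matrix at the maximum-likelihood estimate
#'
#' Computes minus the Hessian of the observed-data log-likelihood over the
#' free parameters on a working scale (baseline-category logits for the
#' item-response probabilities, raw coefficients for `beta` and `alpha`;
#' boundary-frozen slopes are excluded). The score is evaluated analytically
#' via Fisher's identity and differentiated by central differences.
#'
#' @param fit An `"lcpm_fit"`, or an [lcpm_params()] object (then `data`
#'   must be given).
#' @param data Panel used for the fit (taken from `fit` when omitted).
#' @param frozen Boundary flags (taken from `fit` when omitted).
#' @param h Relative step size for the central differences.
#' @return An object of class `"lcpm_inference"`: the information matrix,
#'   working-scale estimates and standard errors, the eigenvalue spectrum,
#'   and a local-identifiability flag.
#' @export
observed_information <- function(fit, data = NULL, frozen = NULL, h = 1e-5) {
  if (inherits(fit, "lcpm_fit")) {
    params <- fit$params
    if (is.null(data)) data <- fit$data
    if (is.null(frozen)) frozen <- fit$boundary_flags
  } else {
    params <- fit
    if (is.null(data)) stop("`data` is required when passing bare parameters")
  }
  spec <- params$spec
  if (is.null(frozen)) frozen <- array(FALSE, dim = c(spec$T, spec$S, spec$K))
  vec <- pack_params(params, frozen)
  p <- length(vec)
  J <- matrix(0, p, p)
  for (j in seq_len(p)) {
    hj <- h * (1 + abs(vec[j]))
    vp <- vec; vp[j] <- vec[j] + hj
    vm <- vec; vm[j] <- vec[j] - hj
    J[, j] <- (.score_obs(vp, data, spec, frozen) -
               .score_obs(vm, data, spec, frozen)) / (2 * hj)
  }
  info <- -(J + t(J)) / 2
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  min_ev <- min(ev); max_ev <- max(ev)
  identifiable <- is.finite(min_ev) && min_ev > 1e-8 * max(max_ev, 0)
  V <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(V)) {
    V <- MASS::ginv(info)
    identifiable <- FALSE
  }
  se <- sqrt(pmax(diag(V), 0))
  tab <- free_param_table(spec, frozen)
  structure(list(info = info, vcov = V, estimate = vec, se = se,
                 free = tab, eigenvalues = ev,
                 min_eigenvalue = min_ev,
                 condition_number = max_ev / max(min_ev, .Machine$double.eps),
                 identifiable = identifiable,
                 params = params, spec = spec, frozen = frozen),
            class = "lcpm_inference")
}

#' Local identifiability check
#'
#' The model is locally identifiable at the estimate when the observed
#' Fisher information is positive definite; the check requires the smallest
#' eigenvalue to exceed `1e-8` times the largest.
#'
#' @param inf An `"lcpm_inference"` object.
#' @return List with `identifiable`, the eigenvalue extremes and spectrum.
#' @export
check_local_identifiability <- function(inf) {
  stopifnot(inherits(inf, "lcpm_inference"))
  list(identifiable = inf$identifiable,
       min_eigenvalue = inf$min_eigenvalue,
       max_eigenvalue = max(inf$eigenvalues),
       condition_number = inf$condition_number,
       eigenvalues = inf$eigenvalues)
}

#' Wald intervals, odds ratios and the coefficient table
#'
#' Item-response probabilities are reported on the probability scale with
#' delta-method standard errors (all `r[m]` categories per block, the last
#' being determined by the simplex constraint). Regression coefficients are
#' reported on the logit scale with odds ratios obtained by exponentiating
#' the interval endpoints. Boundary-frozen slopes appear as rows flagged
#' `constrained` with no interval.
#'
#' @param inf An `"lcpm_inference"` object.
#' @param level Coverage level of the intervals (default 0.95).
#' @return A `data.frame` with columns `parameter`, `type`, `estimate`,
#'   `se`, `lower`, `upper`, `odds_ratio`, `or_lower`, `or_upper`,
#'   `constrained`.
#' @export
wald_intervals <- function(inf, level = 0.95) {
  stopifnot(inherits(inf, "lcpm_inference"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  spec <- inf$spec
  tab <- inf$free
  rows <- list()

  # rho blocks: probability scale via the delta method
  t_blocks <- if (spec$rho_time_invariant) 1L else spec$T
  for (m in seq_len(spec$M)) for (c in seq_len(spec$K))
    for (tb in seq_len(t_blocks)) {
      idx <- which(tab$type == "rho" & tab$m == m & tab$c == c & tab$t == tb)
      if (!length(idx)) next
      rho_block <- inf$params$rho[m, seq_len(spec$r[m]), c, tb]
      Vb <- inf$vcov[idx, idx, drop = FALSE]
      for (k in seq_len(spec$r[m])) {
        # d rho_k / d logit_j = rho_k (I(k = j) - rho_j), j = 1..r-1
        g <- rho_block[k] * ((k == seq_len(spec$r[m] - 1L)) -
                             rho_block[seq_len(spec$r[m] - 1L)])
        se_k <- sqrt(max(drop(t(g) %*% Vb %*% g), 0))
        nm <- if (t_blocks == 1L) sprintf("rho_%d%d|%d", m, k, c)
              else sprintf("rho_%d%d|%d(%d)", m, k, c, tb)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = nm, type = "rho", estimate = rho_block[k], se = se_k,
          lower = rho_block[k] - z * se_k, upper = rho_block[k] + z * se_k,
          odds_ratio = NA_real_, or_lower = NA_real_, or_upper = NA_real_,
          constrained = FALSE)
      }
    }

  # coefficient rows, raw scale plus odds ratios
  coef_idx <- which(tab$type %in% c("beta", "alpha"))
  for (i in coef_idx) {
    est <- inf$estimate[i]; se <- inf$se[i]
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = tab$name[i], type = tab$type[i], estimate = est, se = se,
      lower = est - z * se, upper = est + z * se,
      odds_ratio = exp(est), or_lower = exp(est - z * se),
      or_upper = exp(est + z * se), constrained = FALSE)
  }

  # frozen slopes: explicit constrained markers
  if (spec$K > 1L && spec$Q > 0L) {
    for (t in seq_len(spec$T)) for (u in seq_len(spec$S)) {
      if (!any(inf$frozen[t, u, ])) next
      for (c in 2L:spec$K) for (q in seq_len(spec$Q)) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = sprintf("alpha_%d%d|%d(%d)", q, c, u, t),
          type = "alpha", estimate = 0, se = NA_real_,
          lower = NA_real_, upper = NA_real_,
          odds_ratio = NA_real_, or_lower = NA_real_, or_upper = NA_real_,
          constrained = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
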