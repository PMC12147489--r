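# Parameter container and the two multinomial-logit link functions.

# Row-wise max of a matrix without apply() (hot path).
.row_max <- function(x) {
  m <- x[, 1L]
  if (ncol(x) > 1L) for (j in 2L:ncol(x)) m <- pmax(m, x[, j])
  m
}

# Row-wise softmax of a matrix of linear predictors.
.softmax_rows <- function(lp) {
  lp <- lp - .row_max(lp)
  e <- exp(lp)
  e / rowSums(e)
}

# Row-wise log-sum-exp of a matrix.
.row_lse <- function(x) {
  m <- .row_max(x)
  m[!is.finite(m)] <- 0  # all -Inf rows: lse is -Inf, avoid NaN from -Inf - -Inf
  m + log(rowSums(exp(x - m)))
}

# Probability floor used inside logarithms during iteration; stored
# parameters are never clipped.
.LOG_FLOOR <- 1e-12

#' Bundle LCPM parameters
#'
#' Collects the three parameter types of the model: `rho`, the item-response
#' probabilities \eqn{P(Y_{mt} = k \mid C_t = c)}; `beta`, the
#' profile-prevalence multinomial-logit coefficients (one row per profile,
#' intercept first, baseline profile 1 fixed at zero); and `alpha`, the
#' class-given-profile coefficients (indexed time x profile x class x
#' coefficient, intercept first, baseline class 1 fixed at zero).
#'
#' @param spec An [lcpm_spec()].
#' @param rho Array `[M, max(r), K]` (time-invariant) or `[M, max(r), K, T]`.
#'   Rows must sum to one over the first `r[m]` categories.
#' @param beta Matrix `[S, P + 1]`; row 1 must be exactly zero.
#' @param alpha Array `[T, S, K, Q + 1]`; the class-1 slice must be exactly
#'   zero.
#' @return An object of class `"lcpm_params"`.
#' @export
lcpm_params <- function(spec, rho, beta, alpha) {
  stopifnot(inherits(spec, "lcpm_spec"))
  rmax <- max(spec$r)
  t_blocks <- if (spec$rho_time_invariant) 1L else spec$T
  if (length(dim(rho)) == 3L) {
    rho <- array(rho, dim = c(dim(rho), 1L))
    if (t_blocks != 1L) rho <- array(rep(rho, t_blocks),
                                     dim = c(spec$M, rmax, spec$K, t_blocks))
  }
  if (!identical(dim(rho), c(spec$M, rmax, spec$K, t_blocks)))
    stop("rho must have dimensions [M, max(r), K",
         if (t_blocks > 1L) ", T", "]")
  beta <- as.matrix(beta)
  if (!identical(dim(beta), c(spec$S, spec$P + 1L)))
    stop("beta must be an S x (P+1) matrix")
  if (!identical(dim(alpha), c(spec$T, spec$S, spec$K, spec$Q + 1L)))
    stop("alpha must have dimensions [T, S, K, Q+1]")
  out <- structure(list(rho = rho, beta = beta, alpha = alpha, spec = spec),
                   class = "lcpm_params")
  validate_params(out)
  out
}

#' @rdname lcpm_params
#' @param params An `"lcpm_params"` object.
#' @param tol Tolerance for the simplex constraints on `rho`.
#' @export
validate_params <- function(params, tol = 1e-8) {
  spec <- params$spec
  for (m in seq_len(spec$M)) {
    km <- seq_len(spec$r[m])
    block <- params$rho[m, km, , , drop = FALSE]
    if (any(block < -tol) || any(block > 1 + tol))
      stop("rho entries for item ", m, " fall outside [0, 1]")
    sums <- apply(block, c(3L, 4L), sum)
    if (any(abs(sums - 1) > tol))
      stop("rho rows for item ", m, " do not sum to 1")
    if (spec$r[m] < max(spec$r) &&
        any(params$rho[m, (spec$r[m] + 1L):max(spec$r), , ] != 0))
      stop("rho padding categories for item ", m, " must be zero")
  }
  if (any(params$beta[1L, ] != 0))
    stop("baseline profile constraint violated: beta[1, ] must be exactly 0")
  if (any(params$alpha[, , 1L, ] != 0))
    stop("baseline class constraint violated: alpha[, , 1, ] must be exactly 0")
  invisible(params)
}

# rho slice for time t as an [M, rmax, K] array.
.rho_at <- function(params, t) {
  tb <- if (params$spec$rho_time_invariant) 1L else t
  d <- dim(params$rho)
  array(params$rho[, , , tb], dim = d[1:3])
}

#' Profile-prevalence probabilities
#'
#' Evaluates \eqn{\gamma_u(x) = \exp(x'\beta_u) / \sum_s \exp(x'\beta_s)},
#' the multinomial-logit probability of each latent profile given baseline
#' covariates. An intercept of 1 is prepended to `x` internally, matching
#' the intercept column of `beta`.
#'
#' @param x Numeric vector of `P` baseline covariate values (no intercept).
#' @param beta Matrix `[S, P + 1]` of coefficients, baseline row zero.
#' @return Length-`S` probability vector summing to one.
#' @examples
#' beta <- rbind(c(0, 0), c(-1, 1))
#' profile_prevalence(1, beta)  # linear predictor 0 -> c(0.5, 0.5)
#' @export
profile_prevalence <- function(x, beta) {
  beta <- as.matrix(beta)
  if (!all(is.finite(x)))
    stop("non-finite baseline covariate value in `x`")
  if (length(x) != ncol(beta) - 1L)
    stop("`x` must supply ", ncol(beta) - 1L, " covariate values")
  lp <- drop(beta %*% c(1, x))
  e <- exp(lp - max(lp))
  e / sum(e)
}

#' Class-membership probabilities given a profile
#'
#' Evaluates \eqn{\eta_{c|u}^{(t)}(z) = \exp(z'\alpha_{c|u}^{(t)}) /
#' \sum_k \exp(z'\alpha_{k|u}^{(t)})}, the multinomial-logit probability of
#' each latent class at time `t` given profile `u` and time-dependent
#' covariates `z`. An intercept of 1 is prepended to `z` internally.
#'
#' @param z Numeric vector of `Q` time-dependent covariate values.
#' @param alpha Coefficient array `[T, S, K, Q + 1]`, class-1 slice zero.
#' @param u Profile index (1-based).
#' @param t Time index (1-based).
#' @return Length-`K` probability vector summing to one.
#' @export
class_prevalence <- function(z, alpha, u, t) {
  if (!all(is.finite(z)))
    stop("non-finite time-dependent covariate value in `z`")
  A <- matrix(alpha[t, u, , ], nrow = dim(alpha)[3L])
  if (length(z) != ncol(A) - 1L)
    stop("`z` must supply ", ncol(A) - 1L, " covariate values")
  lp <- drop(A %*% c(1, z))
  e <- exp(lp - max(lp))
  e / sum(e)
}

#' Log emission probability of one time point's item responses
#'
#' Under local independence the items observed at one time point contribute
#' \eqn{\sum_m \log \rho_{m y_m | c}} to the log-likelihood given class `c`;
#' missing items are marginalized out (contribute zero) under the
#' missing-at-random assumption. A response met by a `rho` entry of exactly
#' zero yields `-Inf`.
#'
#' @param y Integer vector of `M` responses (may contain `NA`).
#' @param params An [lcpm_params()] object.
#' @param class Class index `c`.
#' @param t Time index (relevant when `rho` varies over time).
#' @param mask Logical vector of observation flags; defaults to `!is.na(y)`.
#' @return Scalar log-probability (0 when all items are missing).
#' @export
emission_logprob <- function(y, params, class, t = 1L, mask = !is.na(y)) {
  spec <- params$spec
  rho_t <- .rho_at(params, t)
  total <- 0
  for (m in seq_len(spec$M)) {
    if (!mask[m]) next
    k <- y[m]
    if (is.na(k) || k < 1L || k > spec$r[m])
      stop("response for item ", m, " outside 1..", spec$r[m])
    p <- rho_t[m, k, class]
    total <- total + if (p > 0) log(p) else -Inf
  }
  total
}
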