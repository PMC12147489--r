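#' Define the structure of a latent class profile model
#'
#' A latent class profile model (LCPM) couples two layers of categorical
#' latent variables: a latent class \eqn{C_t} with `K` levels at each of `T`
#' time points, measured by `M` categorical items, and a latent profile `U`
#' with `S` levels whose categories index whole class trajectories.
#' Profile membership may depend on `P` baseline covariates through a
#' multinomial logit, and class membership given a profile may depend on `Q`
#' time-dependent covariates through a second multinomial logit.
#'
#' @param K Number of latent classes per time point (>= 1).
#' @param S Number of latent profiles (>= 1).
#' @param T Number of time points (>= 1).
#' @param M Number of categorical outcome items (>= 1).
#' @param r Integer vector of length `M` giving the number of response
#'   categories of each item (each >= 2). A single value is recycled.
#' @param P Number of baseline covariates, excluding the intercept.
#' @param Q Number of time-dependent covariates, excluding the intercept.
#' @param rho_time_invariant Logical; if `TRUE` (default) the item-response
#'   probabilities are constrained equal across time points, which keeps the
#'   interpretation of class labels comparable over time.
#'
#' @return An object of class `"lcpm_spec"`.
#' @examples
#' sp <- lcpm_spec(K = 2, S = 2, T = 3, M = 4, r = 2, P = 1, Q = 1)
#' n_response_patterns(sp)  # (2^4)^3 = 4096
#' @export
lcpm_spec <- function(K, S, T, M, r, P = 0L, Q = 0L, rho_time_invariant = TRUE) {
  K <- as.integer(K); S <- as.integer(S); T <- as.integer(T); M <- as.integer(M)
  P <- as.integer(P); Q <- as.integer(Q)
  if (length(r) == 1L) r <- rep(as.integer(r), M) else r <- as.integer(r)
  if (any(c(K, S, T, M) < 1L)) stop("K, S, T and M must all be >= 1")
  if (length(r) != M) stop("`r` must have one entry per item (length ", M, ")")
  if (any(r < 2L)) stop("every item must have at least 2 response categories")
  if (P < 0L || Q < 0L) stop("covariate counts P and Q cannot be negative")
  structure(
    list(K = K, S = S, T = T, M = M, r = r, P = P, Q = Q,
         rho_time_invariant = isTRUE(rho_time_invariant)),
    class = "lcpm_spec")
}

#' @export
print.lcpm_spec <- function(x, ...) {
  cat("LCPM specification\n")
  cat(sprintf("  classes (K): %d   profiles (S): %d   times (T): %d\n",
              x$K, x$S, x$T))
  cat(sprintf("  items (M): %d with categories [%s]\n", x$M,
              paste(x$r, collapse = ", ")))
  cat(sprintf("  baseline covariates (P): %d   time-dependent covariates (Q): %d\n",
              x$P, x$Q))
  cat(sprintf("  item-response probabilities time-invariant: %s\n",
              x$rho_time_invariant))
  invisible(x)
}

#' Number of possible response patterns
#'
#' Counts the distinct complete response sequences a subject can produce:
#' \eqn{(\prod_m r_m)^T}. Four binary items observed over three periods, for
#' instance, admit \eqn{16^3 = 4096} patterns.
#'
#' @param spec An [lcpm_spec()].
#' @return A double (counts overflow integer range quickly).
#' @export
n_response_patterns <- function(spec) {
  stopifnot(inherits(spec, "lcpm_spec"))
  prod(as.numeric(spec$r))^spec$T
}

#' Count free parameters of an LCPM or a latent transition model
#'
#' For the LCPM the count covers the item-response probabilities rho
#' (\eqn{\sum_m (r_m - 1) K} per measurement block, times `T` blocks unless
#' time-invariant), the profile-prevalence coefficients beta
#' (\eqn{(S-1)(P+1)} with the baseline profile fixed at zero), and the
#' class-given-profile coefficients alpha (\eqn{(K-1)(Q+1)} per time-profile
#' block, baseline class fixed at zero). Slopes frozen at zero by the
#' boundary-solution rule are excluded when `boundary_flags` is supplied.
#'
#' For the latent transition model (`family = "ltm"`) the count follows the
#' conventional accounting of time-invariant measurement plus unstructured
#' transition matrices: \eqn{\sum_m (r_m - 1) K + (T-1) K^2}. A four-class
#' model on six binary items over six periods counts 6*4 + 5*16 = 104.
#'
#' @param spec An [lcpm_spec()].
#' @param family `"lcpm"` (default) or `"ltm"`.
#' @param boundary_flags Optional logical array `[T, S, K]` marking
#'   class-within-profile cells whose covariate slopes are constrained to 0;
#'   a flagged block contributes only its intercepts.
#' @return Integer count of free parameters.
#' @export
n_parameters <- function(spec, family = c("lcpm", "ltm"), boundary_flags = NULL) {
  stopifnot(inherits(spec, "lcpm_spec"))
  family <- match.arg(family)
  if (family == "ltm") {
    return(as.integer(sum(spec$r - 1L) * spec$K + (spec$T - 1L) * spec$K^2))
  }
  t_blocks <- if (spec$rho_time_invariant) 1L else spec$T
  n_rho <- sum(spec$r - 1L) * spec$K * t_blocks
  n_beta <- (spec$S - 1L) * (spec$P + 1L)
  if (spec$K == 1L) {
    n_alpha <- 0L
  } else if (is.null(boundary_flags)) {
    n_alpha <- spec$T * spec$S * (spec$K - 1L) * (spec$Q + 1L)
  } else {
    stopifnot(identical(dim(boundary_flags), c(spec$T, spec$S, spec$K)))
    n_alpha <- 0L
    for (t in seq_len(spec$T)) for (u in seq_len(spec$S)) {
      block_frozen <- any(boundary_flags[t, u, ])
      per_class <- if (block_frozen) 1L else spec$Q + 1L
      n_alpha <- n_alpha + (spec$K - 1L) * per_class
    }
  }
  as.integer(n_rho + n_beta + n_alpha)
}
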