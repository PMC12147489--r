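#' Assemble a longitudinal categorical panel
#'
#' @param Y Integer array `[N, T, M]` of item responses with categories
#'   `1..r[m]`; `NA` marks item nonresponse.
#' @param X Optional numeric matrix `[N, P]` of baseline covariates.
#' @param Z Optional numeric array `[N, T, Q]` of time-dependent covariates.
#'
#' Covariates must be complete: subjects with missing covariate values are
#' rejected (complete-case requirement; only outcome items may be missing).
#'
#' @return An object of class `"lcpm_data"` with an `observed_mask` field.
#' @export
lcpm_data <- function(Y, X = NULL, Z = NULL) {
  if (length(dim(Y)) != 3L) stop("Y must be an [N, T, M] array")
  N <- dim(Y)[1L]
  storage.mode(Y) <- "integer"
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != N) stop("X must have one row per subject")
    bad <- which(!stats::complete.cases(X) | rowSums(!is.finite(X)) > 0)
    if (length(bad))
      stop("missing or non-finite baseline covariates for subject(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (!is.null(Z)) {
    if (length(dim(Z)) != 3L) stop("Z must be an [N, T, Q] array")
    if (dim(Z)[1L] != N || dim(Z)[2L] != dim(Y)[2L])
      stop("Z must align with Y on subjects and time points")
    bad <- which(apply(!is.finite(Z), 1L, any))
    if (length(bad))
      stop("missing or non-finite time-dependent covariates for subject(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
  }
  structure(list(Y = Y, X = X, Z = Z, observed_mask = !is.na(Y)),
            class = "lcpm_data")
}

#' @export
print.lcpm_data <- function(x, ...) {
  d <- dim(x$Y)
  cat(sprintf("LCPM panel: %d subjects, %d time points, %d items\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  missing outcome cells: %d of %d\n",
              sum(!x$observed_mask), length(x$observed_mask)))
  cat(sprintf("  baseline covariates: %d   time-dependent covariates: %d\n",
              if (is.null(x$X)) 0L else ncol(x$X),
              if (is.null(x$Z)) 0L else dim(x$Z)[3L]))
  invisible(x)
}

# Check that a panel conforms to a model specification.
validate_data <- function(data, spec) {
  stopifnot(inherits(data, "lcpm_data"), inherits(spec, "lcpm_spec"))
  d <- dim(data$Y)
  if (d[2L] != spec$T || d[3L] != spec$M)
    stop("panel dimensions [", d[2L], " times, ", d[3L],
         " items] do not match the specification")
  for (m in seq_len(spec$M)) {
    v <- data$Y[, , m]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < 1L || max(v) > spec$r[m]))
      stop("item ", m, " has responses outside 1..", spec$r[m])
  }
  px <- if (is.null(data$X)) 0L else ncol(data$X)
  pz <- if (is.null(data$Z)) 0L else dim(data$Z)[3L]
  if (px != spec$P) stop("panel has ", px, " baseline covariates; spec expects ", spec$P)
  if (pz != spec$Q) stop("panel has ", pz, " time-dependent covariates; spec expects ", spec$Q)
  invisible(data)
}

# Design matrices with a prepended intercept column.
.design_x <- function(data, N) {
  if (is.null(data$X)) matrix(1, N, 1L) else cbind(1, data$X)
}
.design_z <- function(data, t, N) {
  if (is.null(data$Z)) matrix(1, N, 1L) else cbind(1, matrix(data$Z[, t, ], nrow = N))
}

# Strip covariates from a panel (used by the covariate-free selection step).
strip_covariates <- function(data) {
  lcpm_data(data$Y)
}
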