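# Mapping between the constrained parameter set and an unconstrained free
# parameter vector: rho rows become baseline-category logits (reference =
# last category), beta and alpha keep their raw coefficients with baseline
# rows and boundary-frozen slopes dropped.

# Table describing every free parameter, in packing order.
free_param_table <- function(spec, frozen = NULL) {
  key <- paste(c(spec$K, spec$S, spec$T, spec$M, spec$r, spec$P, spec$Q,
                 spec$rho_time_invariant, as.integer(frozen)), collapse = ",")
  cached <- .pkg_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- .free_param_table_build(spec, frozen)
  .pkg_cache[[key]] <- out
  out
}

.pkg_cache <- new.env(parent = emptyenv())

.free_param_table_build <- function(spec, frozen = NULL) {
  if (is.null(frozen)) frozen <- array(FALSE, dim = c(spec$T, spec$S, spec$K))
  rows <- list()
  t_blocks <- if (spec$rho_time_invariant) 1L else spec$T
  for (m in seq_len(spec$M)) for (c in seq_len(spec$K))
    for (tb in seq_len(t_blocks)) for (k in seq_len(spec$r[m] - 1L)) {
      nm <- if (t_blocks == 1L) sprintf("rho_%d%d|%d", m, k, c)
            else sprintf("rho_%d%d|%d(%d)", m, k, c, tb)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, type = "rho", m = m, k = k, c = c, u = NA, t = tb, q = NA)
    }
  if (spec$S > 1L) for (u in 2L:spec$S) for (p in 0L:spec$P)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("beta_%d|%d", p, u), type = "beta",
      m = NA, k = NA, c = NA, u = u, t = NA, q = p)
  if (spec$K > 1L) for (t in seq_len(spec$T)) for (u in seq_len(spec$S)) {
    block_frozen <- any(frozen[t, u, ])
    for (c in 2L:spec$K) for (q in 0L:spec$Q) {
      if (q > 0L && block_frozen) next
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("alpha_%d%d|%d(%d)", q, c, u, t), type = "alpha",
        m = NA, k = NA, c = c, u = u, t = t, q = q)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Parameter set -> free vector (working scale).
pack_params <- function(params, frozen = NULL) {
  spec <- params$spec
  tab <- free_param_table(spec, frozen)
  out <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    out[i] <- switch(r$type,
      rho = {
        p <- params$rho[r$m, , r$c, r$t]
        log(max(p[r$k], .LOG_FLOOR)) - log(max(p[spec$r[r$m]], .LOG_FLOOR))
      },
      beta = params$beta[r$u, r$q + 1L],
      alpha = params$alpha[r$t, r$u, r$c, r$q + 1L])
  }
  names(out) <- tab$name
  out
}

# Free vector -> parameter set. Frozen slopes and baseline rows are zero.
unpack_params <- function(vec, spec, frozen = NULL) {
  tab <- free_param_table(spec, frozen)
  stopifnot(length(vec) == nrow(tab))
  rmax <- max(spec$r)
  t_blocks <- if (spec$rho_time_invariant) 1L else spec$T
  rho <- array(0, dim = c(spec$M, rmax, spec$K, t_blocks))
  beta <- matrix(0, spec$S, spec$P + 1L)
  alpha <- array(0, dim = c(spec$T, spec$S, spec$K, spec$Q + 1L))
  # rho via softmax of (logits, 0)
  for (m in seq_len(spec$M)) for (c in seq_len(spec$K))
    for (tb in seq_len(t_blocks)) {
      idx <- which(tab$type == "rho" & tab$m == m & tab$c == c & tab$t == tb)
      lg <- c(vec[idx], 0)
      e <- exp(lg - max(lg))
      rho[m, seq_len(spec$r[m]), c, tb] <- e / sum(e)
    }
  ib <- which(tab$type == "beta")
  for (i in ib) beta[tab$u[i], tab$q[i] + 1L] <- vec[i]
  ia <- which(tab$type == "alpha")
  for (i in ia) alpha[tab$t[i], tab$u[i], tab$c[i], tab$q[i] + 1L] <- vec[i]
  lcpm_params(spec, rho, beta, alpha)
}
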