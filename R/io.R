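# Delimited-text input and output for panels and fitted results.

#' Write a panel to delimited text files
#'
#' Outcomes go to a long-format CSV with columns `subject`, `time`, `item`
#' (item name), `response` (empty for missing); baseline covariates to a
#' CSV with `subject` plus one column per covariate; time-dependent
#' covariates to a CSV with `subject`, `time` plus one column per
#' covariate.
#'
#' @param data An [lcpm_data()] panel.
#' @param outcomes_path Path for the long-format outcomes CSV.
#' @param baseline_path,timevarying_path Optional covariate CSV paths
#'   (required when the panel carries the corresponding covariates).
#' @param item_names Optional character vector of item names; defaults to
#'   `item1..itemM`.
#' @return Invisibly, the outcome path.
#' @export
write_panel <- function(data, outcomes_path, baseline_path = NULL,
                        timevarying_path = NULL, item_names = NULL) {
  d <- dim(data$Y)
  N <- d[1L]; T <- d[2L]; M <- d[3L]
  if (is.null(item_names)) item_names <- paste0("item", seq_len(M))
  stopifnot(length(item_names) == M)
  long <- expand.grid(subject = seq_len(N), time = seq_len(T),
                      item_idx = seq_len(M))
  long$item <- item_names[long$item_idx]
  long$response <- data$Y[cbind(long$subject, long$time, long$item_idx)]
  long <- long[order(long$subject, long$time, long$item_idx),
               c("subject", "time", "item", "response")]
  utils::write.csv(long, outcomes_path, row.names = FALSE, na = "")
  if (!is.null(data$X)) {
    if (is.null(baseline_path))
      stop("panel has baseline covariates; supply `baseline_path`")
    bx <- data.frame(subject = seq_len(N), data$X)
    names(bx)[-1L] <- if (!is.null(colnames(data$X))) colnames(data$X)
                      else paste0("x", seq_len(ncol(data$X)))
    utils::write.csv(bx, baseline_path, row.names = FALSE)
  }
  if (!is.null(data$Z)) {
    if (is.null(timevarying_path))
      stop("panel has time-dependent covariates; supply `timevarying_path`")
    Q <- dim(data$Z)[3L]
    zt <- expand.grid(subject = seq_len(N), time = seq_len(T))
    for (q in seq_len(Q))
      zt[[paste0("z", q)]] <- data$Z[cbind(zt$subject, zt$time, q)]
    zt <- zt[order(zt$subject, zt$time), ]
    utils::write.csv(zt, timevarying_path, row.names = FALSE)
  }
  invisible(outcomes_path)
}

#' Read a panel from delimited text files
#'
#' Expects the long outcome format written by [write_panel()]: one row per
#' (subject, time, item) with the response empty or `NA` when missing.
#' Subjects may appear in any order; time indices must be the contiguous
#' sequence `1..T`. Item category counts are inferred from the data unless
#' given in `r`.
#'
#' @param outcomes_path Long-format outcomes CSV.
#' @param baseline_path Optional baseline covariate CSV (`subject` + one
#'   column per covariate).
#' @param timevarying_path Optional time-dependent covariate CSV
#'   (`subject`, `time` + one column per covariate).
#' @param r Optional integer vector of per-item category counts.
#' @param item_names Optional expected item order; defaults to order of
#'   first appearance.
#' @return List with `data` (an [lcpm_data()]), `item_names`, `r`, and
#'   `subjects` (original subject identifiers, in row order).
#' @export
read_panel <- function(outcomes_path, baseline_path = NULL,
                       timevarying_path = NULL, r = NULL, item_names = NULL) {
  long <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
  need <- c("subject", "time", "item", "response")
  if (!all(need %in% names(long)))
    stop("outcomes file must have columns: ", paste(need, collapse = ", "))
  subjects <- sort(unique(long$subject))
  N <- length(subjects)
  times <- sort(unique(long$time))
  if (!identical(as.integer(times), seq_along(times)))
    stop("time indices must be contiguous 1..T; found: ",
         paste(utils::head(times, 10L), collapse = ", "))
  T <- length(times)
  if (is.null(item_names)) item_names <- unique(long$item)
  M <- length(item_names)
  unknown <- setdiff(unique(long$item), item_names)
  if (length(unknown)) stop("unknown item(s): ", paste(unknown, collapse = ", "))
  key <- paste(long$subject, long$time, long$item)
  if (anyDuplicated(key))
    stop("duplicated (subject, time, item) rows, e.g.: ",
         key[which(duplicated(key))[1L]])
  Y <- array(NA_integer_, dim = c(N, T, M))
  i_idx <- match(long$subject, subjects)
  m_idx <- match(long$item, item_names)
  Y[cbind(i_idx, as.integer(long$time), m_idx)] <- as.integer(long$response)
  if (is.null(r)) {
    r <- vapply(seq_len(M), function(m) {
      v <- Y[, , m]
      max(2L, suppressWarnings(max(v, na.rm = TRUE)))
    }, integer(1))
  }
  for (m in seq_len(M)) {
    v <- Y[, , m]; v <- v[!is.na(v)]
    if (length(v) && (min(v) < 1L || max(v) > r[m]))
      stop("item ", item_names[m], " has responses outside 1..", r[m])
  }
  X <- NULL
  if (!is.null(baseline_path)) {
    bx <- utils::read.csv(baseline_path)
    if (!"subject" %in% names(bx)) stop("baseline file needs a `subject` column")
    rows <- match(subjects, bx$subject)
    if (anyNA(rows)) stop("baseline covariates missing for subject(s): ",
                          paste(utils::head(subjects[is.na(rows)], 10L), collapse = ", "))
    X <- as.matrix(bx[rows, setdiff(names(bx), "subject"), drop = FALSE])
  }
  Z <- NULL
  if (!is.null(timevarying_path)) {
    zt <- utils::read.csv(timevarying_path)
    if (!all(c("subject", "time") %in% names(zt)))
      stop("time-varying file needs `subject` and `time` columns")
    zcols <- setdiff(names(zt), c("subject", "time"))
    Q <- length(zcols)
    Z <- array(NA_real_, dim = c(N, T, Q))
    i_idx <- match(zt$subject, subjects)
    for (q in seq_len(Q))
      Z[cbind(i_idx, as.integer(zt$time), q)] <- zt[[zcols[q]]]
    miss <- which(apply(is.na(Z), 1L, any))
    if (length(miss))
      stop("incomplete time-dependent covariates for subject(s): ",
           paste(utils::head(subjects[miss], 10L), collapse = ", "))
  }
  list(data = lcpm_data(Y, X = X, Z = Z), item_names = item_names,
       r = as.integer(r), subjects = subjects)
}
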