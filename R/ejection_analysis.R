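# Ensemble statistics over ejection traces: pathway classification, P_FIFO
# with Wilson intervals, converged ejection fractions, energy-vs-ejection
# landscapes, and the persistence-length estimator.

#' Classify the ejection pathway of a trace
#'
#' FIFO if the first monomer to exit belongs to the first-packaged half of
#' the chain (`i_exit <= n/2`), LIFO otherwise.  Exits away from either chain
#' end are classified by the same rule but flagged anomalous, since the
#' narrow portal should only pass chain ends.
#'
#' @param trace an `ejection_trace`.
#' @param end_margin how close to a chain end `i_exit` must be to avoid the
#'   anomaly flag (default 3 monomers).
#' @return `"FIFO"` or `"LIFO"`, with attribute `anomalous`.
#' @export
classify_pathway <- function(trace, end_margin = 3) {
  stopifnot(inherits(trace, "ejection_trace"))
  if (is.na(trace$i_exit))
    stop("trace has no exit event (pathway '", trace$pathway, "')")
  n <- trace$n_monomers
  cls <- if (trace$i_exit <= n / 2) "FIFO" else "LIFO"
  anomalous <- trace$i_exit > end_margin && trace$i_exit < n - end_margin + 1
  structure(cls, anomalous = anomalous)
}

#' FIFO probability with a Wilson 95% confidence interval
#'
#' @param traces a list of `ejection_trace` objects, or a character vector of
#'   `"FIFO"`/`"LIFO"` labels.  Traces without an exit event are excluded
#'   (and counted).
#' @param conf confidence level.
#' @return list with `estimate`, `lower`, `upper`, `n_fifo`, `n_lifo`,
#'   `n_excluded`.
#' @export
p_fifo <- function(traces, conf = 0.95) {
  if (is.list(traces)) {
    ok <- vapply(traces, function(tr) !is.na(tr$i_exit), logical(1))
    labels <- vapply(traces[ok], function(tr) as.character(classify_pathway(tr)),
                     character(1))
    n_excl <- sum(!ok)
  } else {
    labels <- as.character(traces)
    n_excl <- 0L
  }
  stopifnot(all(labels %in% c("FIFO", "LIFO")))
  n <- length(labels)
  if (n == 0) stop("no classified traces")
  k <- sum(labels == "FIFO")
  ci <- wilson_interval(k, n, conf)
  c(ci, list(n_fifo = k, n_lifo = n - k, n_excluded = n_excl))
}

#' Converged ejection fraction of a trace
#'
#' Mean of the ejection-fraction series over the final `window_frac` of the
#' run.  Non-converged traces error unless `require_converged = FALSE`.
#'
#' @param trace an `ejection_trace`.
#' @param window_frac final fraction of the series to average (default 0.1).
#' @param require_converged error on traces that never reached stationarity.
#' @return `phi_c` in `[0, 1]`.
#' @export
converged_fraction <- function(trace, window_frac = 0.1,
                               require_converged = TRUE) {
  stopifnot(inherits(trace, "ejection_trace"))
  if (require_converged && !isTRUE(trace$converged))
    stop("trace did not converge; pass require_converged = FALSE to override")
  phi <- trace$phi_e_series
  if (length(phi) == 0) stop("trace has no ejection-fraction series")
  m <- length(phi)
  mean(phi[max(1, ceiling((1 - window_frac) * m)):m])
}

#' Mean total energy as a function of ejection fraction, per pathway
#'
#' Each trace's energy series is interpolated onto a common ejection-fraction
#' grid after monotonizing the raw fraction series with a running maximum
#' (retractions make the raw series non-monotone), then averaged per pathway.
#'
#' @param traces list of `ejection_trace` objects.
#' @param grid ejection-fraction grid (default `seq(0, 1, 0.02)`).
#' @return data.frame with columns `phi_e`, `pathway`, `mean_energy`,
#'   `sd_energy`, `n`.
#' @export
energy_vs_fraction <- function(traces, grid = seq(0, 1, by = 0.02)) {
  ok <- vapply(traces, function(tr) !is.na(tr$i_exit) &&
                 length(tr$phi_e_series) > 2, logical(1))
  traces <- traces[ok]
  if (length(traces) == 0) stop("no usable traces")
  rows <- lapply(traces, function(tr) {
    phi <- cummax(tr$phi_e_series)
    e <- tr$energy_series
    keep <- !duplicated(phi)
    if (sum(keep) < 2) return(NULL)
    y <- approx(phi[keep], e[keep], xout = grid, rule = 1)$y
    list(pathway = as.character(classify_pathway(tr)), e = y)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- do.call(rbind, lapply(c("FIFO", "LIFO"), function(pw) {
    es <- do.call(rbind, lapply(Filter(function(r) r$pathway == pw, rows),
                                function(r) r$e))
    if (is.null(es)) return(NULL)
    data.frame(phi_e = grid, pathway = pw,
               mean_energy = colMeans(es, na.rm = TRUE),
               sd_energy = apply(es, 2, sd, na.rm = TRUE),
               n = colSums(!is.na(es)))
  }))
  out[out$n > 0, , drop = FALSE]
}

#' Summarise an ensemble of ejection traces
#'
#' @param traces list of `ejection_trace` objects from one condition.
#' @param condition optional named list describing the condition (taken from
#'   the first trace if omitted).
#' @param grid ejection-fraction grid for the energy curves.
#' @return an `ensemble_summary`: counts, `p_fifo` with CI, per-pathway
#'   `phi_c` mean and sd (converged traces only), non-converged counts, and
#'   the energy curves.
#' @export
ensemble_summary <- function(traces, condition = NULL,
                             grid = seq(0, 1, by = 0.02)) {
  stopifnot(length(traces) >= 1)
  if (is.null(condition)) condition <- traces[[1]]$condition
  has_exit <- vapply(traces, function(tr) !is.na(tr$i_exit), logical(1))
  labels <- rep(NA_character_, length(traces))
  labels[has_exit] <- vapply(traces[has_exit],
                             function(tr) as.character(classify_pathway(tr)),
                             character(1))
  converged <- vapply(traces, function(tr) isTRUE(tr$converged), logical(1))
  pf <- if (any(has_exit)) p_fifo(traces) else NULL
  # phi_c is an operational plateau at matched run length, so all exited
  # traces enter the per-pathway statistics; the stationarity flag is kept in
  # n_nonconverged rather than used as an exclusion
  phi_c_of <- function(pw) {
    sel <- which(labels == pw)
    if (length(sel) == 0) return(c(mean = NA_real_, sd = NA_real_, n = 0))
    v <- vapply(traces[sel], converged_fraction, numeric(1),
                require_converged = FALSE)
    c(mean = mean(v), sd = sd(v), n = length(v))
  }
  structure(list(
    condition = condition,
    n_traj = length(traces),
    n_fifo = sum(labels == "FIFO", na.rm = TRUE),
    n_lifo = sum(labels == "LIFO", na.rm = TRUE),
    n_failed = sum(!has_exit),
    n_nonconverged = sum(has_exit & !converged),
    p_fifo = pf,
    phi_c_fifo = phi_c_of("FIFO"),
    phi_c_lifo = phi_c_of("LIFO"),
    energy_curves = tryCatch(energy_vs_fraction(traces, grid),
                             error = function(e) NULL)
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary>", x$n_traj, "trajectories:",
      x$n_fifo, "FIFO,", x$n_lifo, "LIFO,", x$n_failed, "failed/no-exit\n")
  if (!is.null(x$p_fifo))
    cat(sprintf("  P_FIFO = %.3f [%.3f, %.3f]\n", x$p_fifo$estimate,
                x$p_fifo$lower, x$p_fifo$upper))
  cat(sprintf("  phi_c: FIFO %.3f +- %.3f (n=%d), LIFO %.3f +- %.3f (n=%d)\n",
              x$phi_c_fifo[["mean"]], x$phi_c_fifo[["sd"]], x$phi_c_fifo[["n"]],
              x$phi_c_lifo[["mean"]], x$phi_c_lifo[["sd"]], x$phi_c_lifo[["n"]]))
  invisible(x)
}

#' One-row data frame view of an ensemble summary
#' @param summary an `ensemble_summary`.
#' @return a data.frame suitable for row-binding across conditions.
#' @export
ensemble_summary_row <- function(summary) {
  stopifnot(inherits(summary, "ensemble_summary"))
  cond <- summary$condition
  data.frame(
    packing_fraction = cond$packing_fraction, K_F = cond$K_F, K_L = cond$K_L,
    tau_rest = cond$tau_rest, f_r = cond$f_r,
    n_traj = summary$n_traj, n_fifo = summary$n_fifo, n_lifo = summary$n_lifo,
    n_failed = summary$n_failed, n_nonconverged = summary$n_nonconverged,
    p_fifo = if (is.null(summary$p_fifo)) NA_real_ else summary$p_fifo$estimate,
    p_fifo_lower = if (is.null(summary$p_fifo)) NA_real_ else summary$p_fifo$lower,
    p_fifo_upper = if (is.null(summary$p_fifo)) NA_real_ else summary$p_fifo$upper,
    phi_c_fifo = summary$phi_c_fifo[["mean"]],
    phi_c_fifo_sd = summary$phi_c_fifo[["sd"]],
    phi_c_lifo = summary$phi_c_lifo[["mean"]],
    phi_c_lifo_sd = summary$phi_c_lifo[["sd"]]
  )
}

#' Persistence length from bond-vector correlations
#'
#' Fits `<cos phi(s)> = exp(-s b / l_p)` over bond separations
#' `s = 1..s_max` by log-linear regression, where `phi(s)` is the angle
#' between bond vectors `s` bonds apart and `b` the mean bond length; returns
#' `l_p` in sigma units.
#'
#' @param frames list of n x 3 coordinate matrices (equilibrated snapshots).
#' @param s_max largest bond separation used in the fit (default 10).
#' @return list with `lp_sigma`, `bond_length`, `correlations` (per `s`), and
#'   `rigid` (`TRUE` when correlations never decay and the estimate is
#'   `Inf`).
#' @export
persistence_length_estimate <- function(frames, s_max = 10) {
  stopifnot(length(frames) >= 2)
  n <- nrow(frames[[1]])
  if (n - 1 <= s_max) stop("chain too short for s_max")
  sums <- numeric(s_max)
  counts <- numeric(s_max)
  blen <- 0
  for (fr in frames) {
    b <- diff(fr)
    nb <- sqrt(rowSums(b^2))
    u <- b / nb
    blen <- blen + mean(nb)
    for (s in seq_len(s_max)) {
      m <- nrow(u) - s
      sums[s] <- sums[s] + sum(u[1:m, ] * u[(s + 1):(s + m), ])
      counts[s] <- counts[s] + m
    }
  }
  corr <- sums / counts
  blen <- blen / length(frames)
  if (all(corr > 0.99))
    return(list(lp_sigma = Inf, bond_length = blen, correlations = corr,
                rigid = TRUE))
  pos <- corr > 0
  if (sum(pos) < 2) stop("too few positive correlations for a stable fit")
  fit <- lm(log(corr[pos]) ~ seq_len(s_max)[pos])
  slope <- coef(fit)[[2]]
  if (slope >= 0)
    return(list(lp_sigma = Inf, bond_length = blen, correlations = corr,
                rigid = TRUE))
  list(lp_sigma = -blen / slope, bond_length = blen, correlations = corr,
       rigid = FALSE)
}
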