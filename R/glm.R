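#' Build an event-wise GLM design matrix for one run
#'
#' One regressor per sound event (its boxcar convolved with the hemodynamic
#' response kernel, computed on a 16-fold oversampled grid and sampled at
#' the repetition time), plus an intercept and optional orthogonal-polynomial
#' drift columns.
#'
#' @param schedule_run Schedule rows of a single run (sound trials only are
#'   used; null events contribute no regressor).
#' @param hrf Hemodynamic response kernel, a function of time in seconds.
#' @param tr_s Repetition time, seconds.
#' @param n_timepoints Number of volumes in the run.
#' @param drift_order Order of the polynomial drift terms (0 = none).
#' @return A numeric matrix with `n_timepoints` rows, columns
#'   `event_<i>` ... `drift_<k>`, `intercept`; attribute `event_cols` gives
#'   the event column indices. An error is raised if any event extends past
#'   the run or the matrix is rank deficient.
#' @export
build_design <- function(schedule_run, hrf = hrf_double_gamma, tr_s = 2.0,
                         n_timepoints, drift_order = 0) {
  ev <- schedule_run[schedule_run$kind == "sound", , drop = FALSE]
  n_ev <- nrow(ev)
  run_end <- n_timepoints * tr_s
  if (n_ev > 0 && any(ev$onset_s + ev$duration_s > run_end))
    stop("event(s) extend past the end of the run (",
         run_end, " s with ", n_timepoints, " volumes)")

  oversample <- 16L
  dt <- tr_s / oversample
  n_hi <- n_timepoints * oversample
  t_hi <- (seq_len(n_hi) - 1) * dt
  kern <- hrf(t_hi)

  X <- matrix(0, n_timepoints, n_ev)
  samp <- (seq_len(n_timepoints) - 1L) * oversample + 1L
  if (n_ev > 0) {
    for (i in seq_len(n_ev)) {
      box <- as.numeric(t_hi >= ev$onset_s[i] &
                          t_hi < ev$onset_s[i] + ev$duration_s[i])
      reg <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_hi)] * dt
      X[, i] <- reg[samp]
    }
    colnames(X) <- sprintf("event_%03d", seq_len(n_ev))
  }

  if (drift_order > 0) {
    D <- stats::poly(seq_len(n_timepoints), degree = drift_order)
    colnames(D) <- sprintf("drift_%d", seq_len(drift_order))
    X <- cbind(X, D)
  }
  X <- cbind(X, intercept = 1)

  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dropped, collapse = ", "))
  }
  attr(X, "event_cols") <- seq_len(n_ev)
  X
}

#' Estimate event betas by ordinary least squares
#'
#' Fits the full design in a single least-squares-all model (one regressor
#' per event alongside the nuisance columns) and returns the event betas
#' only.
#'
#' @param timeseries Timepoint x voxel numeric matrix.
#' @param design Design matrix from [build_design()] (rows must match
#'   `timeseries`).
#' @return Event x voxel matrix of beta estimates (zero rows if the design
#'   has no event columns).
#' @export
estimate_betas <- function(timeseries, design) {
  timeseries <- as.matrix(timeseries)
  if (nrow(design) != nrow(timeseries))
    stop("design has ", nrow(design), " rows but timeseries has ",
         nrow(timeseries), " timepoints")
  qr_X <- qr(design)
  if (qr_X$rank < ncol(design)) {
    dropped <- colnames(design)[qr_X$pivot[(qr_X$rank + 1):ncol(design)]]
    stop("normal equations singular; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  B <- qr.coef(qr_X, timeseries)
  ev <- attr(design, "event_cols")
  if (is.null(ev)) ev <- grep("^event_", colnames(design))
  B[ev, , drop = FALSE]
}

#' Estimate betas for a whole simulated cohort
#'
#' Convenience wrapper: runs [build_design()] and [estimate_betas()] for
#' every participant x run of a time-series tibble and reassembles the
#' labeled event-pattern tibble the decoding pipeline consumes.
#'
#' @param ts_tbl Output of [simulate_timeseries()].
#' @param schedule The trial schedule.
#' @param tree The taxonomy (for trial labels).
#' @inheritParams build_design
#' @return A tibble shaped like [simulate_event_patterns()] output.
#' @export
estimate_betas_dataset <- function(ts_tbl, schedule, tree,
                                   hrf = hrf_double_gamma, tr_s = 2.0,
                                   drift_order = 0) {
  validate_taxonomy(tree)
  out <- purrr::pmap(ts_tbl, function(participant, run, n_timepoints,
                                      timeseries, ...) {
    run_sched <- schedule[schedule$kind == "sound" & schedule$run == run, ,
                          drop = FALSE]
    X <- build_design(run_sched, hrf = hrf, tr_s = tr_s,
                      n_timepoints = n_timepoints, drift_order = drift_order)
    B <- estimate_betas(timeseries, X)
    res <- tibble::tibble(participant = participant, run = run,
                          trial = run_sched$trial,
                          exemplar = run_sched$exemplar)
    lut <- function(col) stats::setNames(tree[[col]], tree$exemplar)
    res$subordinate <- unname(lut("subordinate")[res$exemplar])
    res$intermediate <- unname(lut("intermediate")[res$exemplar])
    res$superordinate <- unname(lut("superordinate")[res$exemplar])
    res$beta <- unname(B)
    res
  })
  dplyr::bind_rows(out)
}
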