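#' On/Off cycling design of one fMRI run
#'
#' Describes the block timing of a DBS cycling run: the device alternates
#' between Off and On in blocks of `cycle_s` seconds, each block beginning
#' with a `ramp_s`-second amplitude ramp (up at the start of On, down at the
#' start of Off). Runs start at the beginning of an Off block.
#'
#' @param tr_s Repetition time, seconds.
#' @param n_frames Number of acquired volumes.
#' @param cycle_s Block length, seconds (default 60: one-minute intervals).
#' @param ramp_s Ramp duration at the start of each block, seconds.
#' @param start_state Block state at t = 0; only "off" is supported (runs are
#'   timed to begin at the start of the Off cycle).
#' @return An object of class `cycling_design`.
#' @export
cycling_design <- function(tr_s = 2, n_frames = 180, cycle_s = 60, ramp_s = 8,
                           start_state = "off") {
  stopifnot(tr_s > 0, n_frames >= 2, cycle_s > 0, ramp_s >= 0,
            ramp_s < cycle_s)
  start_state <- match.arg(start_state, "off")
  run_s <- n_frames * tr_s
  if (abs(run_s %% (2 * cycle_s)) > 1e-9) {
    stop("run length (", run_s, " s) must cover whole On/Off cycles of ",
         2 * cycle_s, " s", call. = FALSE)
  }
  structure(list(tr_s = tr_s, n_frames = n_frames, cycle_s = cycle_s,
                 ramp_s = ramp_s, start_state = start_state),
            class = "cycling_design")
}

#' @export
print.cycling_design <- function(x, ...) {
  cat(sprintf(
    "<cycling_design> %d frames @ TR %gs; %gs Off/On blocks, %gs ramps, start Off\n",
    x$n_frames, x$tr_s, x$cycle_s, x$ramp_s))
  invisible(x)
}

#' Frame-wise stimulus regressors for a cycling design
#'
#' Returns the pre-convolution On and Off box regressors sampled at frame
#' onsets. With `ramp_mode = "excluded"` (default) both boxes are 1 only
#' during their plateau (the `ramp_s` seconds at the start of each block are
#' zero in both, which also keeps On + Off from being constant and hence
#' collinear with the drift intercept). With `ramp_mode = "linear"` the On
#' regressor additionally carries the linearly interpolated stimulation level
#' during the up and down ramps; the Off regressor is plateau-only in both
#' modes.
#'
#' @param design A [cycling_design()].
#' @param ramp_mode `"excluded"` or `"linear"`.
#' @return List with numeric vectors `on` and `off` of length `n_frames`.
#' @export
stimulus_boxcars <- function(design, ramp_mode = c("excluded", "linear")) {
  ramp_mode <- match.arg(ramp_mode)
  t_s <- (seq_len(design$n_frames) - 1) * design$tr_s
  k <- floor(t_s / design$cycle_s)
  on_block <- (k %% 2) == 1             # blocks 0,2,4,.. are Off (start Off)
  phase <- t_s - k * design$cycle_s
  plateau <- phase >= design$ramp_s
  on <- as.numeric(on_block & plateau)
  off <- as.numeric(!on_block & plateau)
  if (ramp_mode == "linear" && design$ramp_s > 0) {
    frac <- phase / design$ramp_s
    on[on_block & !plateau] <- frac[on_block & !plateau]          # ramp up
    # ramp down at the start of every Off block that follows an On block
    down <- !on_block & !plateau & k > 0
    on[down] <- 1 - frac[down]
  }
  list(on = on, off = off)
}

#' Build the run-level GLM design matrix
#'
#' Columns are the On and Off boxcars convolved with the canonical HRF
#' sampled at TR, followed by Legendre drift polynomials of orders
#' 0..`drift_order` over the full run. Censored frames are recorded and
#' deleted at fit time (row deletion, not spike regressors).
#'
#' @param design A [cycling_design()].
#' @param hrf_params Named list overriding [hrf_kernel()] arguments
#'   (`peak`, `undershoot`, `ratio`, `duration_s`).
#' @param drift_order Highest Legendre drift order (default 3: constant plus
#'   three drift terms).
#' @param censor Logical vector of frames to drop, or `NULL`.
#' @param ramp_mode Ramp handling for the boxcars, see [stimulus_boxcars()].
#' @param collinearity_r2 Maximum tolerated multiple correlation (R^2) of a
#'   condition column on the remaining columns after censoring; designs above
#'   it (e.g. `ramp_s = 0`, where On + Off is constant) are rejected.
#' @return An object of class `design_matrix`: list with the numeric matrix
#'   `X` (named columns `on`, `off`, `poly0`..), `censor`, and the settings.
#' @export
build_design_matrix <- function(design, hrf_params = list(), drift_order = 3,
                                censor = NULL,
                                ramp_mode = c("excluded", "linear"),
                                collinearity_r2 = 0.9) {
  ramp_mode <- match.arg(ramp_mode)
  stopifnot(inherits(design, "cycling_design"),
            drift_order >= 0, drift_order <= 3)
  n <- design$n_frames
  if (is.null(censor)) censor <- rep(FALSE, n)
  stopifnot(is.logical(censor), length(censor) == n)

  kern <- do.call(hrf_kernel, c(list(tr_s = design$tr_s), hrf_params))
  box <- stimulus_boxcars(design, ramp_mode)
  X <- cbind(on = convolve_regressor(box$on, kern),
             off = convolve_regressor(box$off, kern),
             legendre_basis(n, drift_order))
  colnames(X) <- c("on", "off", paste0("poly", 0:drift_order))

  Xk <- X[!censor, , drop = FALSE]
  if (nrow(Xk) <= ncol(Xk)) {
    stop("fewer uncensored frames (", nrow(Xk), ") than design columns (",
         ncol(Xk), ")", call. = FALSE)
  }
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    bad <- colnames(Xk)[qrX$pivot[(qrX$rank + 1):ncol(Xk)]]
    stop("design matrix is rank deficient after censoring; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (j in c("on", "off")) {
    r2 <- .multiple_r2(Xk[, j], Xk[, colnames(Xk) != j, drop = FALSE])
    if (r2 > collinearity_r2) {
      stop("design matrix is near-collinear: column '", j, "' has R^2 = ",
           signif(r2, 4), " on the remaining columns (limit ",
           collinearity_r2, "); with ramp_s = 0 the On and Off boxes sum to ",
           "a constant and duplicate poly0", call. = FALSE)
    }
  }
  structure(list(X = X, censor = censor, design = design,
                 drift_order = drift_order, ramp_mode = ramp_mode),
            class = "design_matrix")
}

.multiple_r2 <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(fit$residuals^2) / tss
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d frames x %d regressors (%s), %d censored\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", "),
              sum(x$censor)))
  invisible(x)
}

#' Write a design matrix as TSV for inspection
#'
#' @param dm A [build_design_matrix()] result.
#' @param path Output TSV path.
#' @export
write_design_matrix <- function(dm, path) {
  df <- as.data.frame(dm$X)
  df$censor <- as.integer(dm$censor)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
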