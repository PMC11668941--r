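#' Scale voxel time series to a mean of 100
#'
#' Each voxel's time series is multiplied by `100 / mean` so that regression
#' coefficients on unit-peak regressors read directly as percent signal
#' change. Voxels with zero or negative mean (outside any sensible BOLD
#' range) are masked out: their series are set to `NA` with a warning and
#' downstream fits return `NA` there.
#'
#' @param bold 4D array (x, y, z, t).
#' @param mask Optional logical 3D array restricting the operation; voxels
#'   outside it are left untouched.
#' @return 4D array of the same shape; attribute `bad_voxels` holds the
#'   linear indices that were masked out.
#' @export
scale_to_mean_100 <- function(bold, mask = NULL) {
  stopifnot(length(dim(bold)) == 4)
  dims <- dim(bold)
  Y <- matrix(bold, prod(dims[1:3]), dims[4])
  sel <- if (is.null(mask)) rep(TRUE, nrow(Y)) else as.vector(mask)
  mu <- rowMeans(Y[sel, , drop = FALSE])
  bad <- which(sel)[mu <= 0]
  ok <- which(sel)[mu > 0]
  Y[ok, ] <- Y[ok, , drop = FALSE] * (100 / mu[mu > 0])
  if (length(bad) > 0) {
    warning(length(bad), " voxel(s) with non-positive mean masked out")
    Y[bad, ] <- NA_real_
  }
  out <- array(Y, dims)
  attr(out, "bad_voxels") <- bad
  out
}

#' Fit the run-level OLS model at every voxel
#'
#' Ordinary least squares of each voxel time series on the design matrix,
#' with censored frames removed by row deletion. Returns the full beta
#' array; combine with [on_off_contrast()] for the On-Off effect volume.
#'
#' @param bold 4D array, typically from [scale_to_mean_100()].
#' @param dm A [build_design_matrix()] result.
#' @return Object of class `run_glm_fit`: list with `betas` (4D array
#'   x,y,z,regressor), `sigma2` (3D residual variance), `regressors`,
#'   `df_residual`, and `dm`.
#' @export
fit_run_glm <- function(bold, dm) {
  stopifnot(inherits(dm, "design_matrix"), length(dim(bold)) == 4)
  dims <- dim(bold)
  if (dims[4] != nrow(dm$X)) {
    stop("BOLD has ", dims[4], " frames but the design matrix has ",
         nrow(dm$X), " rows", call. = FALSE)
  }
  keep <- !dm$censor
  X <- dm$X[keep, , drop = FALSE]
  if (nrow(X) <= ncol(X)) {
    stop("fewer uncensored frames than regressors", call. = FALSE)
  }
  Y <- t(matrix(bold, prod(dims[1:3]), dims[4]))[keep, , drop = FALSE]
  ok <- colSums(is.na(Y)) == 0
  qrX <- qr(X)
  B <- matrix(NA_real_, ncol(X), ncol(Y))
  S2 <- rep(NA_real_, ncol(Y))
  if (any(ok)) {
    Bok <- qr.coef(qrX, Y[, ok, drop = FALSE])
    res <- Y[, ok, drop = FALSE] - X %*% Bok
    B[, ok] <- Bok
    S2[ok] <- colSums(res^2) / (nrow(X) - ncol(X))
  }
  structure(list(betas = array(t(B), c(dims[1:3], ncol(X))),
                 sigma2 = array(S2, dims[1:3]),
                 regressors = colnames(dm$X),
                 df_residual = nrow(X) - ncol(X), dm = dm),
            class = "run_glm_fit")
}

#' On-Off contrast map from a run fit
#'
#' `beta_on - beta_off` per voxel, in percent-signal units, with run
#' metadata attached.
#'
#' @param fit A [fit_run_glm()] result.
#' @param meta Named list of run metadata (subject, run id, configuration,
#'   therapeutic/responder flags, ...).
#' @return Object of class `contrast_map`: list with 3D `data` and `meta`.
#' @export
on_off_contrast <- function(fit, meta = list()) {
  stopifnot(inherits(fit, "run_glm_fit"),
            all(c("on", "off") %in% fit$regressors))
  i_on <- match("on", fit$regressors)
  i_off <- match("off", fit$regressors)
  nd <- length(dim(fit$betas))
  vol <- .slice_last(fit$betas, i_on) - .slice_last(fit$betas, i_off)
  structure(list(data = vol, meta = meta), class = "contrast_map")
}

.slice_last <- function(arr, i) {
  d <- dim(arr)
  array(arr[, , , i], d[1:3])
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map> grid %s; meta: %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(names(x$meta), unlist(lapply(x$meta, format)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Run the full per-run contrast pipeline
#'
#' Convenience wrapper: confounds + censoring, mean-100 scaling, design
#' construction, OLS fit and On-Off contrast for one run.
#'
#' @param bold Raw 4D BOLD array.
#' @param motion Motion-parameter table.
#' @param design A [cycling_design()].
#' @param qc A [qc_config()].
#' @param meta Run metadata list for the contrast map.
#' @param mask Optional brain mask.
#' @param drift_order,ramp_mode Passed to [build_design_matrix()].
#' @return List with `contrast` (a `contrast_map`), `confounds`, `fit`, `dm`.
#' @export
run_contrast_pipeline <- function(bold, motion, design, qc = qc_config(),
                                  meta = list(), mask = NULL,
                                  drift_order = 3,
                                  ramp_mode = c("excluded", "linear")) {
  ramp_mode <- match.arg(ramp_mode)
  confounds <- compute_confounds(bold, motion, qc, mask)
  scaled <- suppressWarnings(scale_to_mean_100(bold, mask))
  dm <- build_design_matrix(design, drift_order = drift_order,
                            censor = confounds$censor, ramp_mode = ramp_mode)
  fit <- fit_run_glm(scaled, dm)
  list(contrast = on_off_contrast(fit, meta), confounds = confounds,
       fit = fit, dm = dm)
}
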