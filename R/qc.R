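#' Quality-control thresholds for frame censoring
#'
#' @param fd_thresh Framewise-displacement censoring threshold, mm
#'   (default 0.5; frames with FD strictly above it are censored).
#' @param dvars_thresh Standardized DVARS censoring threshold (default 1.5).
#' @param head_radius_mm Sphere radius used to convert rotation deltas to an
#'   arc-length displacement, mm (default 50, the Power convention).
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(fd_thresh = 0.5, dvars_thresh = 1.5,
                      head_radius_mm = 50) {
  stopifnot(fd_thresh > 0, dvars_thresh > 0, head_radius_mm > 0)
  structure(list(fd_thresh = fd_thresh, dvars_thresh = dvars_thresh,
                 head_radius_mm = head_radius_mm), class = "qc_config")
}

#' Framewise displacement (absolute sum of relative motions)
#'
#' `FD_t = sum_i |delta trans_i| + r * sum_j |delta rot_j|`: the sum of the
#' absolute frame-to-frame changes of the three translations (mm) plus the
#' three rotations (radians) converted to arc length on a sphere of radius
#' `head_radius_mm`. The first frame has no predecessor and gets FD = 0.
#'
#' @param motion Data frame or matrix with columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z` (mm, radians), one row
#'   per frame.
#' @param head_radius_mm Rotation-to-mm conversion radius.
#' @return Numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  m <- as.matrix(motion)
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!is.null(colnames(m))) {
    if (!all(cols %in% colnames(m))) {
      stop("motion parameters must have columns ",
           paste(cols, collapse = ", "), call. = FALSE)
    }
    m <- m[, cols, drop = FALSE]
  } else if (ncol(m) != 6) {
    stop("motion parameters must have 6 columns (3 translations mm, ",
         "3 rotations rad)", call. = FALSE)
  }
  stopifnot(nrow(m) >= 1, all(is.finite(m)), head_radius_mm > 0)
  if (nrow(m) == 1) return(0)
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Standardized DVARS of a BOLD run
#'
#' Raw DVARS at frame t is the root-mean-square over in-mask voxels of the
#' intensity difference between frames t and t-1. It is standardized by
#' dividing by the within-run median of the raw values (so a stationary run
#' has median standardized DVARS 1 and the conventional censoring threshold
#' of 1.5 is meaningful); frame 1 is set to 0. A run with zero raw DVARS
#' everywhere (constant time series) returns all zeros.
#'
#' @param bold 4D array (x, y, z, t).
#' @param mask Logical 3D array of in-brain voxels; `NULL` uses all voxels.
#' @return Numeric vector of per-frame standardized DVARS.
#' @export
std_dvars <- function(bold, mask = NULL) {
  stopifnot(length(dim(bold)) == 4, dim(bold)[4] >= 2)
  dims <- dim(bold)
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  stopifnot(identical(dim(mask), dims[1:3]))
  if (!any(mask)) stop("empty brain mask", call. = FALSE)
  Y <- matrix(bold, prod(dims[1:3]), dims[4])[as.vector(mask), , drop = FALSE]
  raw <- c(0, sqrt(colMeans((Y[, -1, drop = FALSE] -
                               Y[, -dims[4], drop = FALSE])^2)))
  med <- stats::median(raw[-1])
  if (med == 0) return(numeric(dims[4]))
  out <- raw / med
  out[1] <- 0
  out
}

#' Censoring mask from a confounds table
#'
#' A frame is censored iff FD strictly exceeds `fd_thresh` or standardized
#' DVARS strictly exceeds `dvars_thresh`.
#'
#' @param confounds Data frame with columns `framewise_displacement` and
#'   `std_dvars` (as produced by [compute_confounds()]).
#' @param qc A [qc_config()].
#' @return Logical vector, `TRUE` = censor.
#' @export
censor_frames <- function(confounds, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"),
            all(c("framewise_displacement", "std_dvars") %in%
                  names(confounds)))
  fd <- confounds$framewise_displacement
  dv <- confounds$std_dvars
  stopifnot(all(fd >= 0), all(dv >= 0))
  fd > qc$fd_thresh | dv > qc$dvars_thresh
}

#' Full confounds table for one run
#'
#' Combines the motion parameters with FD, standardized DVARS and the censor
#' flag into one BIDS-style table.
#'
#' @param bold 4D BOLD array.
#' @param motion Motion-parameter table (see [framewise_displacement()]).
#' @param qc A [qc_config()].
#' @param mask Optional brain mask for DVARS.
#' @return Data frame with columns `trans_*`, `rot_*`,
#'   `framewise_displacement`, `std_dvars`, `censor`.
#' @export
compute_confounds <- function(bold, motion, qc = qc_config(), mask = NULL) {
  stopifnot(nrow(motion) == dim(bold)[4])
  out <- as.data.frame(motion)[c("trans_x", "trans_y", "trans_z",
                                 "rot_x", "rot_y", "rot_z")]
  out$framewise_displacement <-
    framewise_displacement(motion, qc$head_radius_mm)
  out$std_dvars <- std_dvars(bold, mask)
  out$censor <- censor_frames(out, qc)
  out
}

#' Write/read a confounds table as TSV
#'
#' @param confounds Data frame from [compute_confounds()].
#' @param path TSV path.
#' @export
write_confounds <- function(confounds, path) {
  df <- confounds
  df$censor <- as.integer(df$censor)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confounds
#' @export
read_confounds <- function(path) {
  df <- utils::read.delim(path)
  if ("censor" %in% names(df)) df$censor <- as.logical(df$censor)
  df
}
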