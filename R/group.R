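#' Group design for the run-level contrasts
#'
#' One row per run: which subject it belongs to and whether the stimulation
#' configuration was therapeutic and the subject a treatment responder. The
#' group model treats therapeutic and responder as fixed effects and subject
#' as a random intercept. Therapeutic runs occur only in responders, so the
#' two fixed effects are partially confounded; the default keeps both and
#' reports the therapeutic coefficient, `reduced = TRUE` drops responder.
#'
#' @param subject Character/factor subject id per run.
#' @param therapeutic Logical per run.
#' @param responder Logical per run (constant within subject).
#' @return Object of class `group_design` (a data frame).
#' @export
group_design <- function(subject, therapeutic, responder) {
  stopifnot(length(subject) == length(therapeutic),
            length(subject) == length(responder),
            is.logical(therapeutic), is.logical(responder))
  df <- data.frame(subject = as.character(subject),
                   therapeutic = therapeutic, responder = responder,
                   stringsAsFactors = FALSE)
  if (length(unique(df$subject)) < 2) {
    stop("group inference needs at least 2 subjects", call. = FALSE)
  }
  if (length(unique(df$therapeutic)) < 2) {
    stop("both therapeutic and non-therapeutic runs are required",
         call. = FALSE)
  }
  for (s in unique(df$subject)) {
    if (length(unique(df$responder[df$subject == s])) != 1) {
      stop("responder flag must be constant within subject ", s,
           call. = FALSE)
    }
  }
  class(df) <- c("group_design", "data.frame")
  df
}

#' Unit-wise linear mixed-effects comparison
#'
#' For each unit (parcel or voxel), fits the REML mixed model
#' `y ~ therapeutic + responder + (1 | subject)` to the run-level values and
#' reports the therapeutic fixed effect with its Satterthwaite test. When
#' the random-intercept variance estimate degenerates to the boundary
#' (singular fit) the model falls back to OLS on the fixed effects with a
#' logged note in the `method` column; units where even that fails return
#' `NA`.
#'
#' @param Y Numeric matrix, runs x units (run-level parcel means or voxel
#'   values).
#' @param design A [group_design()] with one row per run, aligned to the
#'   rows of `Y`.
#' @param reduced If `TRUE`, drop the responder fixed effect.
#' @return Data frame (one row per unit): `estimate`, `se`, `stat`, `df`,
#'   `p`, `method` ("lme" or "ols").
#' @export
fit_parcelwise_lme <- function(Y, design, reduced = FALSE) {
  stopifnot(inherits(design, "group_design"))
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(design))
  fixed <- if (reduced) "therapeutic" else "therapeutic + responder"
  # responder is constant within subject; with few subjects it can be
  # aliased after the random intercept absorbs subject means — lmerTest
  # handles the rank-deficient case by dropping, which we detect below.
  fml <- stats::as.formula(paste("y ~", fixed, "+ (1 | subject)"))
  fml_ols <- stats::as.formula(paste("y ~", fixed))
  out <- data.frame(estimate = rep(NA_real_, ncol(Y)), se = NA_real_,
                    stat = NA_real_, df = NA_real_, p = NA_real_,
                    method = NA_character_)
  for (j in seq_len(ncol(Y))) {
    dat <- data.frame(y = Y[, j], design)
    if (anyNA(dat$y)) next
    res <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(fml, data = dat, REML = TRUE)))
      if (lme4::isSingular(fit, tol = 1e-4)) {
        .ols_row(fml_ols, dat)
      } else {
        co <- stats::coef(summary(fit))
        r <- co["therapeuticTRUE", ]
        list(estimate = r[["Estimate"]], se = r[["Std. Error"]],
             stat = r[["t value"]], df = r[["df"]], p = r[["Pr(>|t|)"]],
             method = "lme")
      }
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$estimate[j] <- res$estimate; out$se[j] <- res$se
      out$stat[j] <- res$stat; out$df[j] <- res$df; out$p[j] <- res$p
      out$method[j] <- res$method
    }
  }
  out
}

.ols_row <- function(fml_ols, dat) {
  fit <- stats::lm(fml_ols, data = dat)
  co <- stats::coef(summary(fit))
  r <- co["therapeuticTRUE", ]
  list(estimate = r[["Estimate"]], se = r[["Std. Error"]],
       stat = r[["t value"]], df = fit$df.residual,
       p = r[["Pr(>|t|)"]], method = "ols")
}

#' Parcel-wise group comparison of contrast maps
#'
#' Aggregates each run's contrast map to parcel means and runs
#' [fit_parcelwise_lme()].
#'
#' @param contrasts List of `contrast_map` objects.
#' @param design A [group_design()] aligned to `contrasts`.
#' @param atlas A `parcel_atlas`.
#' @param reduced Drop the responder fixed effect.
#' @return Data frame with one row per parcel (plus column `parcel`).
#' @export
group_parcel_lme <- function(contrasts, design, atlas, reduced = FALSE) {
  stopifnot(length(contrasts) == nrow(design))
  Y <- t(vapply(contrasts, parcel_means, numeric(n_parcels(atlas)),
                atlas = atlas))
  out <- fit_parcelwise_lme(Y, design, reduced)
  cbind(parcel = seq_len(ncol(Y)), out)
}

#' Connected components of a thresholded statistic map
#'
#' Labels the suprathreshold voxels of a 3D map into connected clusters
#' under the chosen neighbourhood: `nn = 1` faces (6 neighbours), `nn = 2`
#' faces + edges (18), `nn = 3` faces + edges + corners (26).
#'
#' @param stat_map Numeric 3D array, or logical array of suprathreshold
#'   voxels (then `threshold` is ignored).
#' @param threshold Voxels with `abs(stat_map) > threshold` form the
#'   suprathreshold set (two-sided by magnitude).
#' @param nn Neighbourhood order, 1, 2 or 3.
#' @return List with `labels` (integer 3D array, 0 = background) and `sizes`
#'   (integer vector per cluster, decreasing).
#' @export
cluster_components <- function(stat_map, threshold = NULL, nn = 1) {
  stopifnot(length(dim(stat_map)) == 3, nn %in% 1:3)
  supra <- if (is.logical(stat_map)) stat_map else {
    stopifnot(!is.null(threshold))
    !is.na(stat_map) & abs(stat_map) > threshold
  }
  dims <- dim(supra)
  labels <- array(0L, dims)
  idx <- which(supra)
  if (length(idx) == 0) {
    return(list(labels = labels, sizes = integer(0)))
  }
  offs <- .neighbour_offsets(nn)
  lab <- 0L
  remaining <- array(FALSE, dims)
  remaining[idx] <- TRUE
  for (start in idx) {
    if (!remaining[start]) next
    lab <- lab + 1L
    queue <- start
    remaining[start] <- FALSE
    labels[start] <- lab
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      arr <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- sweep(arr, 2, offs[r, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
          (nb[ok, 3] - 1L) * dims[1] * dims[2]
        hit <- lin[remaining[lin]]
        if (length(hit) > 0) {
          remaining[hit] <- FALSE
          labels[hit] <- lab
          queue <- c(queue, hit)
        }
      }
    }
  }
  sizes <- sort(tabulate(labels[labels > 0L], nbins = lab),
                decreasing = TRUE)
  list(labels = labels, sizes = sizes)
}

.neighbour_offsets <- function(nn) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(g))
  g[ord > 0 & ord <= nn, , drop = FALSE]
}

#' Cluster-extent configuration
#'
#' @param voxel_p Two-sided voxel-level threshold p (default 0.05).
#' @param alpha Cluster-level family-wise alpha (default 0.05).
#' @param nn Cluster-forming neighbourhood (1 = faces).
#' @param n_iter Monte-Carlo iterations for the null (>= 1000 recommended
#'   for stable quantiles; fewer triggers a warning).
#' @return Object of class `cluster_config`.
#' @export
cluster_config <- function(voxel_p = 0.05, alpha = 0.05, nn = 1,
                           n_iter = 1000) {
  stopifnot(voxel_p > 0, voxel_p < 1, alpha > 0, alpha <= 1, nn %in% 1:3,
            n_iter >= 1)
  if (n_iter < 1000) {
    warning("n_iter < 1000 gives unstable cluster-threshold quantiles")
  }
  structure(list(voxel_p = voxel_p, alpha = alpha, nn = nn,
                 n_iter = n_iter), class = "cluster_config")
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates Gaussian noise fields on the analysis grid, smooths them to the
#' requested FWHM, thresholds voxelwise at `voxel_p` (two-sided), and
#' records the largest cluster per iteration; the returned threshold is the
#' smallest cluster size `c` whose family-wise chance probability
#' `P(max cluster >= c)` is at most `alpha` (so with `alpha = 1` any
#' cluster, i.e. size 1, passes).
#'
#' @param grid_shape Length-3 voxel grid.
#' @param smoothness_fwhm Noise smoothness, FWHM in voxels (0 = white
#'   noise).
#' @param cfg A [cluster_config()].
#' @param seed Integer seed.
#' @return Integer voxel count; attribute `max_sizes` holds the simulated
#'   null distribution.
#' @export
cluster_size_threshold <- function(grid_shape, smoothness_fwhm = 0,
                                   cfg = cluster_config(), seed = 1) {
  stopifnot(length(grid_shape) == 3, smoothness_fwhm >= 0,
            inherits(cfg, "cluster_config"))
  zthr <- stats::qnorm(1 - cfg$voxel_p / 2)
  max_sizes <- withr::with_seed(seed, vapply(seq_len(cfg$n_iter), function(i) {
    field <- array(stats::rnorm(prod(grid_shape)), grid_shape)
    if (smoothness_fwhm > 0) {
      field <- gaussian_smooth_3d(field, smoothness_fwhm)
      field <- field / stats::sd(field)
    }
    cl <- cluster_components(abs(field) > zthr, nn = cfg$nn)
    if (length(cl$sizes) == 0) 0L else cl$sizes[1]
  }, integer(1)))
  thr <- 1L
  while (mean(max_sizes >= thr) > cfg$alpha) thr <- thr + 1L
  attr(thr, "max_sizes") <- max_sizes
  thr
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr Numeric 3D array.
#' @param fwhm_vox Kernel FWHM in voxels.
#' @return Smoothed array (truncated-kernel convolution, renormalised at the
#'   edges).
#' @export
gaussian_smooth_3d <- function(arr, fwhm_vox) {
  stopifnot(length(dim(arr)) == 3, fwhm_vox > 0)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, ax) {
    d <- dim(a)
    K <- .band_matrix(d[ax], k, half)
    if (ax == 1) {
      array(K %*% matrix(a, d[1], d[2] * d[3]), d)
    } else if (ax == 2) {
      p <- aperm(a, c(2, 1, 3))
      aperm(array(K %*% matrix(p, d[2], d[1] * d[3]), dim(p)), c(2, 1, 3))
    } else {
      p <- aperm(a, c(3, 1, 2))
      aperm(array(K %*% matrix(p, d[3], d[1] * d[2]), dim(p)), c(2, 3, 1))
    }
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

.band_matrix <- function(n, k, half) {
  K <- matrix(0, n, n)
  for (o in -half:half) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[o + half + 1]
  }
  K / rowSums(K)   # renormalise truncated rows at the edges
}

#' Cluster table for a statistic map
#'
#' @param stat_map Numeric 3D array.
#' @param threshold Voxel-level magnitude threshold.
#' @param size_threshold Minimum cluster extent (e.g. from
#'   [cluster_size_threshold()]).
#' @param nn Neighbourhood order.
#' @return Data frame: `cluster`, `size`, `peak` value, `peak_x/y/z` and
#'   centroid voxel indices; only clusters at or above `size_threshold`.
#' @export
cluster_table <- function(stat_map, threshold, size_threshold = 1, nn = 1) {
  cl <- cluster_components(stat_map, threshold, nn)
  if (length(cl$sizes) == 0) {
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0)))
  }
  labs <- sort(unique(cl$labels[cl$labels > 0]))
  rows <- lapply(labs, function(l) {
    idx <- which(cl$labels == l)
    if (length(idx) < size_threshold) return(NULL)
    vals <- stat_map[idx]
    pk <- idx[which.max(abs(vals))]
    pkc <- arrayInd(pk, dim(stat_map))
    ctr <- colMeans(arrayInd(idx, dim(stat_map)))
    data.frame(cluster = l, size = length(idx), peak = stat_map[pk],
               peak_x = pkc[1], peak_y = pkc[2], peak_z = pkc[3],
               cx = ctr[1], cy = ctr[2], cz = ctr[3])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- cluster_table(stat_map, Inf)  # empty frame
  out[order(-out$size), , drop = FALSE]
}
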