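#' DBS electrode model
#'
#' Ordered contact centre coordinates of one lead in world mm. Contacts must
#' be (approximately) collinear, as on a physical lead.
#'
#' @param contacts Numeric matrix, one row per contact, columns x/y/z mm,
#'   ordered along the lead.
#' @param lead_id Lead identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @param collinear_tol_mm Maximum allowed contact distance from the lead
#'   axis, mm.
#' @return Object of class `electrode_model`.
#' @export
electrode_model <- function(contacts, lead_id = "lead", hemisphere = "left",
                            collinear_tol_mm = 0.5) {
  contacts <- as.matrix(contacts)
  stopifnot(ncol(contacts) == 3, nrow(contacts) >= 2,
            all(is.finite(contacts)))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  if (nrow(contacts) > 2) {
    axis <- contacts[nrow(contacts), ] - contacts[1, ]
    axis <- axis / sqrt(sum(axis^2))
    rel <- sweep(contacts, 2, contacts[1, ])
    perp <- rel - outer(as.numeric(rel %*% axis), axis)
    if (max(sqrt(rowSums(perp^2))) > collinear_tol_mm) {
      stop("electrode contacts are not collinear within ", collinear_tol_mm,
           " mm", call. = FALSE)
    }
  }
  structure(list(contacts = contacts, lead_id = lead_id,
                 hemisphere = hemisphere), class = "electrode_model")
}

#' Bipolar stimulation configuration
#'
#' @param lead_id Lead the configuration runs on.
#' @param anode,cathode Contact indices (1-based along the lead); must be
#'   adjacent unless `allow_nonadjacent`.
#' @param amplitude_mA Stimulation amplitude, mA (> 0; 5-6 mA typical for
#'   the cycling paradigm).
#' @param therapeutic Logical flag.
#' @param allow_nonadjacent Override the adjacency requirement.
#' @return Object of class `stimulation_config`.
#' @export
stimulation_config <- function(lead_id, anode, cathode, amplitude_mA = 5,
                               therapeutic = FALSE,
                               allow_nonadjacent = FALSE) {
  stopifnot(anode != cathode, amplitude_mA > 0)
  if (abs(anode - cathode) != 1 && !allow_nonadjacent) {
    stop("bipolar pair must use adjacent contacts (anode ", anode,
         ", cathode ", cathode, "); set allow_nonadjacent to override",
         call. = FALSE)
  }
  structure(list(lead_id = lead_id, anode = anode, cathode = cathode,
                 amplitude_mA = amplitude_mA, therapeutic = therapeutic),
            class = "stimulation_config")
}

#' Estimate the volume of activated tissue (VAT)
#'
#' Paired-sphere stimulation-field model: the VAT is the union of two
#' spheres centred on the active (anode and cathode) contact centres with a
#' common radius given by `radius_model(amplitude_mA)`, by default
#' `r_mm = k * sqrt(amplitude_mA)` with `k = 1.8`. This is a declared
#' geometric surrogate for a volume-conductor field model; every downstream
#' statistic is agnostic to how the VAT was produced, and an externally
#' computed binary mask can be used instead via [vat_from_mask()].
#'
#' @param electrode An [electrode_model()].
#' @param cfg A [stimulation_config()] on that lead.
#' @param k Radius scale, mm per sqrt(mA).
#' @param radius_model Optional function `amplitude_mA -> radius_mm`
#'   overriding the square-root law.
#' @return Object of class `vat`: `centers` (2 x 3 mm), `radius_mm`, and
#'   the configuration.
#' @export
estimate_vat <- function(electrode, cfg, k = 1.8, radius_model = NULL) {
  stopifnot(inherits(electrode, "electrode_model"),
            inherits(cfg, "stimulation_config"),
            cfg$anode <= nrow(electrode$contacts),
            cfg$cathode <= nrow(electrode$contacts))
  r <- if (is.null(radius_model)) k * sqrt(cfg$amplitude_mA) else
    radius_model(cfg$amplitude_mA)
  stopifnot(r > 0, is.finite(r))
  structure(list(centers = electrode$contacts[c(cfg$anode, cfg$cathode), ,
                                              drop = FALSE],
                 radius_mm = r, config = cfg), class = "vat")
}

#' VAT from an external binary mask
#'
#' Wraps an externally computed stimulation-field mask (e.g. from a
#' volume-conductor model) so it can be used wherever a sphere-model VAT is.
#' Streamline tests are performed against the voxel centres of the mask,
#' each treated as a sphere of half the voxel diagonal.
#'
#' @param mask Logical 3D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Object of class `vat_mask`.
#' @export
vat_from_mask <- function(mask, affine) {
  stopifnot(length(dim(mask)) == 3, any(mask))
  idx <- which(mask)
  ijk <- arrayInd(idx, dim(mask))
  xyz <- t(affine %*% rbind(t(ijk - 1), 1))[, 1:3, drop = FALSE]
  vox <- sqrt(sum((affine[1:3, 1:3] %*% c(1, 1, 1))^2)) / 2
  structure(list(centers = xyz, radius_mm = vox), class = "vat_mask")
}

#' VAT centroid in world mm
#' @param vat A `vat` or `vat_mask`.
#' @return Length-3 numeric.
#' @export
vat_centroid <- function(vat) colMeans(vat$centers)

#' Rasterise a sphere-model VAT onto a reference grid
#'
#' @param vat A `vat`.
#' @param atlas A `parcel_atlas` providing grid and affine (or any list
#'   with `labels` and `affine`).
#' @return Logical 3D array; write with [write_volume_nifti()].
#' @export
vat_mask_on_grid <- function(vat, atlas) {
  dims <- dim(atlas$labels)
  ijk <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  xyz <- t(atlas$affine %*% rbind(t(ijk - 1), 1))[, 1:3, drop = FALSE]
  inside <- rep(FALSE, nrow(xyz))
  for (c_i in seq_len(nrow(vat$centers))) {
    d2 <- (xyz[, 1] - vat$centers[c_i, 1])^2 +
      (xyz[, 2] - vat$centers[c_i, 2])^2 +
      (xyz[, 3] - vat$centers[c_i, 3])^2
    inside <- inside | d2 <= vat$radius_mm^2
  }
  array(inside, dims)
}

#' Export a volume with an affine as NIfTI
#' @param arr 3D array (logical converted to integer).
#' @param affine 4x4 voxel-to-world matrix.
#' @param path Output path.
#' @export
write_volume_nifti <- function(arr, affine, path) {
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  write_volume(arr, affine, path)
}

# Minimum distance from point p to segment a-b (all length-3).
.point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sum((p - a)^2))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sum((p - a - t * ab)^2)
}

# TRUE if a polyline (n x 3) intersects any sphere of `centers` with radius
# r: a vertex inside or a segment passing through counts.
.polyline_hits_spheres <- function(pts, centers, r) {
  r2 <- r^2
  for (c_i in seq_len(nrow(centers))) {
    ctr <- centers[c_i, ]
    d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
      (pts[, 3] - ctr[3])^2
    if (any(d2 <= r2)) return(TRUE)
    if (nrow(pts) >= 2) {
      for (s in seq_len(nrow(pts) - 1)) {
        if (.point_segment_dist2(ctr, pts[s, ], pts[s + 1, ]) <= r2) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

#' Filter streamlines passing through a VAT
#'
#' Keeps a streamline iff any vertex lies inside the VAT or any segment
#' intersects it (exact segment-sphere test, so a segment crossing a sphere
#' between two outside vertices is kept). Order is preserved.
#'
#' @param streams A `streamline_set` (see [streamline_set()]).
#' @param vat A `vat` or `vat_mask` in the same mm space.
#' @return The filtered `streamline_set`; attribute `kept` holds the
#'   original indices.
#' @export
streamlines_through_vat <- function(streams, vat) {
  stopifnot(inherits(streams, "streamline_set"),
            inherits(vat, c("vat", "vat_mask")))
  keep <- vapply(streams$lines, .polyline_hits_spheres, logical(1),
                 centers = vat$centers, r = vat$radius_mm)
  out <- streamline_set(streams$lines[keep])
  attr(out, "kept") <- which(keep)
  out
}

#' Per-network streamline fractions of a VAT-filtered tractogram
#'
#' Each streamline is assigned to a parcel by the endpoint farther from the
#' VAT centroid (the "distal" termination); endpoints landing in background
#' or outside the grid count as "unassigned". Fractions are per network over
#' the total number of filtered streamlines, so network fractions plus the
#' unassigned fraction sum to 1. `mode = "traversal"` instead credits every
#' parcel any vertex of the streamline visits (one count per streamline and
#' parcel). `denominator = "cortical"` restricts the denominator to
#' streamlines that reached any parcel.
#'
#' @param filtered A `streamline_set` (typically from
#'   [streamlines_through_vat()]).
#' @param atlas A `parcel_atlas` in the same mm space.
#' @param vat The `vat` used for filtering (for the centroid); or pass
#'   `centroid` directly.
#' @param centroid Optional length-3 override.
#' @param mode `"endpoint"` (default) or `"traversal"`.
#' @param denominator `"all"` (default) or `"cortical"`.
#' @return Object of class `connectivity_profile`: `total`, `parcel_counts`
#'   (length `n_parcels`), `network_fractions` (named, plus `unassigned`),
#'   `mode`, `denominator`.
#' @export
network_streamline_fractions <- function(filtered, atlas, vat = NULL,
                                         centroid = NULL,
                                         mode = c("endpoint", "traversal"),
                                         denominator = c("all", "cortical")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  stopifnot(inherits(filtered, "streamline_set"),
            inherits(atlas, "parcel_atlas"))
  if (is.null(centroid)) {
    stopifnot(!is.null(vat))
    centroid <- vat_centroid(vat)
  }
  P <- n_parcels(atlas)
  counts <- integer(P)
  unassigned <- 0L
  for (pts in filtered$lines) {
    if (mode == "endpoint") {
      ends <- pts[c(1, nrow(pts)), , drop = FALSE]
      d2 <- rowSums(sweep(ends, 2, centroid)^2)
      tip <- ends[which.max(d2), , drop = FALSE]
      lab <- world_to_parcel(atlas, tip)
      if (lab > 0) counts[lab] <- counts[lab] + 1L else
        unassigned <- unassigned + 1L
    } else {
      labs <- unique(world_to_parcel(atlas, pts))
      labs <- labs[labs > 0]
      if (length(labs) == 0) unassigned <- unassigned + 1L else
        counts[labs] <- counts[labs] + 1L
    }
  }
  total <- length(filtered$lines)
  denom <- if (denominator == "all") total else total - unassigned
  K <- max(atlas$assignment)
  net_counts <- as.numeric(rowsum(counts,
                                  factor(atlas$assignment,
                                         levels = seq_len(K))))
  fr <- if (denom > 0) net_counts / denom else rep(NaN, K)
  names(fr) <- atlas$network_names
  structure(list(total = total, parcel_counts = counts,
                 network_fractions = c(fr, unassigned =
                                         if (denom > 0 &&
                                             denominator == "all")
                                           unassigned / denom else 0),
                 mode = mode, denominator = denominator),
            class = "connectivity_profile")
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat(sprintf("<connectivity_profile> %d streamlines (%s endpoints, %s denominator)\n",
              x$total, x$mode, x$denominator))
  print(round(x$network_fractions, 4))
  invisible(x)
}

#' Write a connectivity profile as CSV
#' @param x A `connectivity_profile`.
#' @param path CSV path.
#' @export
write_connectivity_profile <- function(x, path) {
  df <- data.frame(network = names(x$network_fractions),
                   fraction = as.numeric(x$network_fractions),
                   total_streamlines = x$total)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
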