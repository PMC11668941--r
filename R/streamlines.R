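#' Streamline set container
#'
#' A tractogram: a list of polylines, each an `n_i x 3` numeric matrix of
#' vertices in world mm.
#'
#' @param lines List of numeric matrices with 3 columns.
#' @return Object of class `streamline_set`.
#' @export
streamline_set <- function(lines = list()) {
  stopifnot(all(vapply(lines, function(m)
    is.matrix(m) && ncol(m) == 3 && nrow(m) >= 1 && all(is.finite(m)),
    logical(1))))
  structure(list(lines = lines), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines\n", length(x$lines)))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$lines)

#' Write streamlines in MRtrix TCK format
#'
#' Minimal TCK writer: text header (`mrtrix tracks`, datatype Float32LE,
#' count, file offset) followed by little-endian float32 vertex triplets,
#' streamlines separated by NaN triplets and terminated by an Inf triplet.
#'
#' @param streams A `streamline_set` in world mm.
#' @param path Output `.tck` path.
#' @export
write_tck <- function(streams, path) {
  stopifnot(inherits(streams, "streamline_set"))
  header <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                   length(streams$lines), "\n")
  # the 'file: . N' line length feeds back into the offset; fix by padding
  off <- nchar(header, type = "bytes") +
    nchar(sprintf("file: . %06d\nEND\n", 0L), type = "bytes")
  header <- paste0(header, sprintf("file: . %06d\nEND\n", off))
  stopifnot(nchar(header, type = "bytes") == off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (m in streams$lines) {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read streamlines from MRtrix TCK format
#'
#' @param path `.tck` path (Float32LE datatype only).
#' @return A `streamline_set`.
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  end_tag <- charToRaw("\nEND\n")
  hdr_end <- NA_integer_
  for (i in seq_len(min(length(raw) - 4L, 4096L))) {
    if (identical(raw[i:(i + 4L)], end_tag)) { hdr_end <- i + 4L; break }
  }
  if (is.na(hdr_end)) stop("not a TCK file: no END marker", call. = FALSE)
  header <- rawToChar(raw[seq_len(hdr_end)])
  if (!grepl("^mrtrix tracks", header)) {
    stop("not a TCK file", call. = FALSE)
  }
  if (!grepl("Float32LE", header)) {
    stop("only Float32LE TCK data supported", call. = FALSE)
  }
  off <- as.integer(sub(".*file: \\. ([0-9]+).*", "\\1", header))
  vals <- readBin(raw[(off + 1L):length(raw)], "numeric",
                  n = (length(raw) - off) / 4L, size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  lines <- list()
  cur <- integer(0)
  for (r in seq_len(nrow(pts))) {
    if (any(is.infinite(pts[r, ]))) break
    if (any(is.nan(pts[r, ]))) {
      if (length(cur) > 0) {
        lines[[length(lines) + 1]] <- pts[cur, , drop = FALSE]
      }
      cur <- integer(0)
    } else {
      cur <- c(cur, r)
    }
  }
  if (length(cur) > 0) lines[[length(lines) + 1]] <- pts[cur, , drop = FALSE]
  streamline_set(lines)
}

#' Simulate a whole-brain tractogram relative to a stimulation field
#'
#' Draws each streamline's destination from `network_weights`: a named
#' probability vector over the atlas networks plus an `"elsewhere"` bucket.
#' Network streamlines start inside the VAT and terminate exactly at a
#' random voxel centre of a random parcel of the drawn network (so the
#' VAT-filtered per-network fractions recover the weights up to binomial
#' error); `"elsewhere"` streamlines are placed beyond the atlas bounding
#' box and never intersect the VAT. Intermediate vertices are jittered so
#' streamlines are polylines, not straight segments.
#'
#' @param n_streamlines Number of streamlines (the real-data scale is
#'   200,000; scale down freely).
#' @param atlas A `parcel_atlas`.
#' @param vat A `vat` (non-empty).
#' @param network_weights Named numeric probabilities over
#'   `atlas$network_names` plus optionally `"elsewhere"`; must sum to 1.
#' @param seed Integer seed.
#' @param n_vertices Vertices per streamline.
#' @return A `streamline_set`; attribute `destination` holds the drawn
#'   bucket per streamline.
#' @export
simulate_streamlines <- function(n_streamlines, atlas, vat, network_weights,
                                 seed = 1, n_vertices = 8) {
  stopifnot(inherits(atlas, "parcel_atlas"), inherits(vat, "vat"),
            n_streamlines >= 1, n_vertices >= 2)
  if (nrow(vat$centers) == 0 || vat$radius_mm <= 0) {
    stop("empty VAT", call. = FALSE)
  }
  nm <- names(network_weights)
  stopifnot(!is.null(nm),
            all(nm %in% c(atlas$network_names, "elsewhere")),
            abs(sum(network_weights) - 1) < 1e-8,
            all(network_weights >= 0))
  K <- length(atlas$network_names)
  parcels_by_net <- split(seq_along(atlas$assignment), atlas$assignment)

  # a corner far outside both the atlas and the VAT for 'elsewhere' lines
  dims <- dim(atlas$labels)
  far0 <- as.numeric(atlas$affine %*% c(dims, 1))[1:3] +
    10 * vat$radius_mm + 50

  withr::with_seed(seed, {
    dest <- sample(nm, n_streamlines, replace = TRUE,
                   prob = network_weights)
    lines <- vector("list", n_streamlines)
    for (i in seq_len(n_streamlines)) {
      if (dest[i] == "elsewhere") {
        a <- far0 + stats::runif(3, 0, 30)
        b <- a + stats::rnorm(3, 0, 10)
        lines[[i]] <- .jitter_polyline(a, b, n_vertices, jitter_sd = 1,
                                       fix_start = FALSE)
      } else {
        net <- match(dest[i], atlas$network_names)
        parcel <- .resample(parcels_by_net[[net]], 1)
        vox <- parcel_voxel_world(atlas, parcel)
        tip <- vox[sample.int(nrow(vox), 1), ]
        ctr <- vat$centers[sample.int(nrow(vat$centers), 1), ]
        start <- ctr + .runif_ball(vat$radius_mm * 0.8)
        lines[[i]] <- .jitter_polyline(start, tip, n_vertices,
                                       jitter_sd = 1, fix_start = TRUE)
      }
    }
    out <- streamline_set(lines)
    attr(out, "destination") <- dest
    out
  })
}

.resample <- function(x, n) x[sample.int(length(x), n)]

.runif_ball <- function(r) {
  repeat {
    p <- stats::runif(3, -r, r)
    if (sum(p^2) <= r^2) return(p)
  }
}

# Polyline from a to b with jittered interior vertices; endpoints exact.
.jitter_polyline <- function(a, b, n_vertices, jitter_sd, fix_start) {
  t <- seq(0, 1, length.out = n_vertices)
  pts <- outer(1 - t, a) + outer(t, b)
  if (n_vertices > 2) {
    mid <- 2:(n_vertices - 1)
    pts[mid, ] <- pts[mid, ] +
      matrix(stats::rnorm(length(mid) * 3, 0, jitter_sd), length(mid), 3)
  }
  pts
}
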