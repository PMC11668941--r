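#' Synthetic labeled parcel/network atlas
#'
#' Builds a parcellated "brain" (a centred ellipsoid inside the voxel grid)
#' by seeded region growing: `n_parcels` seed voxels are drawn at random and
#' grown outward one face-neighbour layer at a time until the brain mask is
#' filled, then parcels are assigned to networks in blocks of
#' `network_sizes`. The default mimics a 100-parcel, 7-network cortical
#' parcellation; spatial realism is irrelevant for the permutation
#' statistics, which depend only on the parcel-to-network labels.
#'
#' @param n_parcels Number of parcels (labels 1..n_parcels; 0 = background).
#' @param network_sizes Integer vector of parcels per network, summing to
#'   `n_parcels`.
#' @param grid_shape Length-3 voxel grid dimensions.
#' @param voxel_size_mm Isotropic voxel edge length, mm.
#' @param seed Integer RNG seed; the atlas is a pure function of the
#'   arguments.
#' @param network_names Optional character names, one per network.
#' @return An object of class `parcel_atlas`: list with integer 3D array
#'   `labels`, 4x4 `affine` (voxel index - 1 to world mm), integer
#'   `assignment` (parcel to network), `network_names`, `voxel_size_mm`.
#' @export
make_atlas <- function(n_parcels = 100,
                       network_sizes = c(17, 13, 12, 13, 12, 13, 20),
                       grid_shape = c(24, 24, 24), voxel_size_mm = 4,
                       seed = 1, network_names = NULL) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2),
            n_parcels >= length(network_sizes), length(network_sizes) >= 2,
            sum(network_sizes) == n_parcels, voxel_size_mm > 0)
  if (is.null(network_names)) {
    canonical <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic",
                   "Cont", "Default")
    network_names <- if (length(network_sizes) == 7) canonical else
      paste0("Net", seq_along(network_sizes))
  }
  stopifnot(length(network_names) == length(network_sizes))

  mask <- .ellipsoid_mask(grid_shape)
  n_in <- sum(mask)
  if (n_in < n_parcels) {
    stop("grid too small: brain mask has ", n_in, " voxels for ", n_parcels,
         " parcels", call. = FALSE)
  }
  labels <- withr::with_seed(seed, .grow_parcels(mask, n_parcels))
  assignment <- rep(seq_along(network_sizes), network_sizes)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  structure(list(labels = labels, affine = affine,
                 assignment = as.integer(assignment),
                 network_names = network_names,
                 voxel_size_mm = voxel_size_mm),
            class = "parcel_atlas")
}

.ellipsoid_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  semi <- grid_shape / 2 - 0.5
  ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  d2 <- ((ijk[, 1] - ctr[1]) / semi[1])^2 + ((ijk[, 2] - ctr[2]) / semi[2])^2 +
    ((ijk[, 3] - ctr[3]) / semi[3])^2
  array(d2 <= 1, dim = grid_shape)
}

# Multi-source breadth-first region growing over the face (6-) neighbourhood.
.grow_parcels <- function(mask, n_parcels) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  in_idx <- which(mask)
  seeds <- sample(in_idx, n_parcels)
  labels[seeds] <- seq_len(n_parcels)
  frontier <- seeds
  while (length(frontier) > 0) {
    nb <- .face_neighbours(frontier, dims)
    cand <- nb$to[mask[nb$to] & labels[nb$to] == 0L]
    src <- nb$from[mask[nb$to] & labels[nb$to] == 0L]
    if (length(cand) == 0) break
    # a voxel reachable from several parcels gets one picked at random
    ord <- sample.int(length(cand))
    cand <- cand[ord]; src <- src[ord]
    keep <- !duplicated(cand)
    labels[cand[keep]] <- labels[src[keep]]
    frontier <- cand[keep]
  }
  labels
}

# Linear-index face neighbours with edge guards; returns from/to pairs.
.face_neighbours <- function(idx, dims) {
  arr <- arrayInd(idx, dims)
  from <- integer(0); to <- integer(0)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- arr
      nb[, ax] <- nb[, ax] + s
      ok <- nb[, ax] >= 1L & nb[, ax] <= dims[ax]
      if (any(ok)) {
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
          (nb[ok, 3] - 1L) * dims[1] * dims[2]
        from <- c(from, idx[ok]); to <- c(to, lin)
      }
    }
  }
  list(from = from, to = to)
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat(sprintf("<parcel_atlas> %d parcels, %d networks, grid %s, voxel %g mm\n",
              length(x$assignment), length(x$network_names),
              paste(dim(x$labels), collapse = "x"), x$voxel_size_mm))
  invisible(x)
}

#' Number of parcels in an atlas
#' @param atlas A `parcel_atlas`.
#' @return Integer count.
#' @export
n_parcels <- function(atlas) length(atlas$assignment)

#' Write an atlas as NIfTI plus a parcel lookup TSV
#'
#' @param atlas A `parcel_atlas`.
#' @param nifti_path Output `.nii`/`.nii.gz` path for the label volume.
#' @param tsv_path Output TSV with columns `parcel`, `network_id`, `network`.
#' @export
write_atlas <- function(atlas, nifti_path, tsv_path) {
  write_volume(atlas$labels, atlas$affine, nifti_path)
  lut <- data.frame(parcel = seq_along(atlas$assignment),
                    network_id = atlas$assignment,
                    network = atlas$network_names[atlas$assignment])
  utils::write.table(lut, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(atlas)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param nifti_path Label volume path.
#' @param tsv_path Lookup TSV path.
#' @return A `parcel_atlas`.
#' @export
read_atlas <- function(nifti_path, tsv_path) {
  img <- RNifti::readNifti(nifti_path)
  lut <- utils::read.delim(tsv_path)
  labels <- array(as.integer(round(img)), dim = dim(img))
  nets <- lut$network[!duplicated(lut$network_id)]
  nets <- nets[order(unique(lut$network_id))]
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  vox <- RNifti::pixdim(img)[1]
  structure(list(labels = labels, affine = affine,
                 assignment = as.integer(lut$network_id),
                 network_names = as.character(nets), voxel_size_mm = vox),
            class = "parcel_atlas")
}

# Shared NIfTI volume writer: stores the affine as sform (code 2).
write_volume <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# World-mm coordinates of the centre of every voxel of each parcel.
parcel_voxel_world <- function(atlas, parcel) {
  idx <- which(atlas$labels == parcel)
  ijk <- arrayInd(idx, dim(atlas$labels))
  t(atlas$affine %*% rbind(t(ijk - 1), 1))[, 1:3, drop = FALSE]
}

# Map world-mm points (n x 3) to parcel labels (0 outside grid/background).
world_to_parcel <- function(atlas, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  vox <- t(solve(atlas$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
  ijk <- round(vox) + 1
  dims <- dim(atlas$labels)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  out <- integer(nrow(ijk))
  if (any(ok)) {
    lin <- ijk[ok, 1] + (ijk[ok, 2] - 1) * dims[1] +
      (ijk[ok, 3] - 1) * dims[1] * dims[2]
    out[ok] <- atlas$labels[lin]
  }
  out
}
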