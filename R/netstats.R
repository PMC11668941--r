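#' Per-parcel means of a contrast volume
#'
#' Unweighted mean of the in-parcel voxel values for every parcel of the
#' atlas. Empty parcels (or parcels whose voxels are all `NA`) yield `NaN`
#' with a warning.
#'
#' @param contrast A `contrast_map` or a bare 3D array on the atlas grid.
#' @param atlas A `parcel_atlas`.
#' @return Numeric vector of length `n_parcels(atlas)`.
#' @export
parcel_means <- function(contrast, atlas) {
  vol <- if (inherits(contrast, "contrast_map")) contrast$data else contrast
  stopifnot(identical(dim(vol), dim(atlas$labels)))
  P <- n_parcels(atlas)
  lab <- as.vector(atlas$labels)
  val <- as.vector(vol)
  inb <- lab > 0 & !is.na(val)
  sums <- rowsum(val[inb], factor(lab[inb], levels = seq_len(P)))
  cnts <- tabulate(lab[inb], nbins = P)
  out <- as.numeric(sums) / cnts
  if (any(cnts == 0)) {
    warning(sum(cnts == 0), " empty parcel(s); mean set to NaN")
    out[cnts == 0] <- NaN
  }
  out
}

#' Per-network means of a parcel vector
#'
#' Unweighted mean over member parcels per network; the negated mean is
#' reported alongside as "suppression" (positive = BOLD decrease with
#' stimulation On).
#'
#' @param v Numeric parcel vector.
#' @param assignment Integer parcel-to-network assignment.
#' @param network_names Optional network names.
#' @return Data frame with columns `network`, `mean`, `suppression`.
#' @export
network_means <- function(v, assignment, network_names = NULL) {
  stopifnot(length(v) == length(assignment))
  K <- max(assignment)
  m <- as.numeric(rowsum(v, factor(assignment, levels = seq_len(K)))) /
    tabulate(assignment, nbins = K)
  if (is.null(network_names)) network_names <- paste0("Net", seq_len(K))
  data.frame(network = network_names, mean = m, suppression = -m)
}

# Surrogate network means under random permutation of the parcel-to-network
# assignment: returns an n_perm x K matrix. Permuting the assignment over
# parcels is equivalent to permuting v; network sizes are preserved.
.surrogate_network_means <- function(v, assignment, n_perm, seed) {
  P <- length(v)
  K <- max(assignment)
  sizes <- tabulate(assignment, nbins = K)
  M <- matrix(0, P, K)
  M[cbind(seq_len(P), assignment)] <- 1
  M <- sweep(M, 2, sizes, "/")
  withr::with_seed(seed, {
    Vp <- matrix(0, n_perm, P)
    for (b in seq_len(n_perm)) Vp[b, ] <- v[sample.int(P)]
    Vp %*% M
  })
}

# Tie guard: comparisons use a tolerance so a surrogate that differs from
# the observed value only by floating-point summation order is treated as a
# tie. Ties count as exceedances (the conservative permutation convention):
# a constant vector yields p = 1, while an unbeatable observed statistic
# still reports 1/n_perm because no random surrogate reproduces it.
.tie_tol <- function(obs) sqrt(.Machine$double.eps) * pmax(1, abs(obs))

.perm_result <- function(observed_mean, observed_stat, surrogate_stat,
                         n_perm, seed, sidedness, network_names,
                         stat_name) {
  K <- length(observed_stat)
  tol <- .tie_tol(observed_stat)
  b <- integer(K)
  for (k in seq_len(K)) {
    b[k] <- sum(surrogate_stat[, k] >= observed_stat[k] - tol[k])
  }
  p_unc <- pmax(b, 1) / n_perm          # floor at the test's resolution
  tab <- data.frame(network = network_names,
                    observed_mean = observed_mean,
                    observed_stat = observed_stat,
                    n_exceed = b,
                    p_uncorrected = p_unc,
                    p_bonferroni = bonferroni_adjust(p_unc, K))
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 sidedness = sidedness, stat = stat_name,
                 surrogate_summary = data.frame(
                   network = network_names,
                   mean = colMeans(surrogate_stat),
                   sd = apply(surrogate_stat, 2, stats::sd),
                   min = apply(surrogate_stat, 2, min),
                   max = apply(surrogate_stat, 2, max))),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s, %s; n_perm = %d, seed = %d\n",
              x$stat, x$sidedness, x$n_perm, x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' One-sided spatial permutation test for network suppression
#'
#' Tests, per network, whether the observed average suppression (negated
#' parcel mean) across member parcels exceeds what random parcel-to-network
#' assignments produce. Surrogates are drawn by uniformly permuting the
#' assignment vector over parcels (network sizes preserved, identity not
#' excluded); the one-tailed p-value is the proportion of surrogates whose
#' suppression reaches the observed value (ties count, the conservative
#' permutation convention), floored at `1/n_perm` (with 10,000 surrogates
#' an unbeatable observed suppression reports p = 1.0e-4). Bonferroni
#' correction across the networks is applied.
#'
#' @param v Numeric parcel vector (mean On-Off contrast per parcel, percent
#'   signal; negative = suppression).
#' @param assignment Integer parcel-to-network assignment.
#' @param n_perm Number of surrogates (default 10000).
#' @param seed Integer RNG seed.
#' @param network_names Optional network names.
#' @return A `permutation_result`; `$table` has observed means,
#'   suppressions, uncorrected and Bonferroni p-values.
#' @export
one_sided_suppression_test <- function(v, assignment, n_perm = 10000,
                                       seed = 1, network_names = NULL) {
  stopifnot(length(v) == length(assignment), all(is.finite(v)), n_perm >= 1)
  nm <- network_means(v, assignment, network_names)
  surr <- -.surrogate_network_means(v, assignment, n_perm, seed)
  .perm_result(nm$mean, nm$suppression, surr, n_perm, seed,
               "one-sided (greater suppression)", nm$network, "suppression")
}

#' Two-sided permutation test for a network difference
#'
#' Tests, per network, whether the absolute mean of `v_a - v_b` across
#' member parcels is larger than under random parcel-to-network assignment.
#' Surrogates permute the assignment over the fixed difference vector; as in
#' the one-sided test, ties count as exceedances. Bonferroni-corrected
#' across networks.
#'
#' @param v_a,v_b Aligned numeric parcel vectors (e.g. therapeutic and
#'   non-therapeutic mean contrasts).
#' @inheritParams one_sided_suppression_test
#' @return A `permutation_result`.
#' @export
two_sided_difference_test <- function(v_a, v_b, assignment, n_perm = 10000,
                                      seed = 1, network_names = NULL) {
  stopifnot(length(v_a) == length(v_b),
            length(v_a) == length(assignment), n_perm >= 1)
  d <- v_a - v_b
  stopifnot(all(is.finite(d)))
  nm <- network_means(d, assignment, network_names)
  surr <- abs(.surrogate_network_means(d, assignment, n_perm, seed))
  .perm_result(nm$mean, abs(nm$mean), surr, n_perm, seed,
               "two-sided (absolute difference)", nm$network,
               "abs difference")
}

#' One-sided permutation test for increased network connectivity
#'
#' Same surrogate machinery as [one_sided_suppression_test()] but with the
#' statistic "mean member-parcel streamline count, larger = more connected":
#' tests whether a network receives more streamlines than random
#' parcel-to-network assignments would give it.
#'
#' @param counts Non-negative per-parcel streamline counts (or fractions).
#' @inheritParams one_sided_suppression_test
#' @return A `permutation_result`.
#' @export
connectivity_permutation_test <- function(counts, assignment, n_perm = 10000,
                                          seed = 1, network_names = NULL) {
  stopifnot(length(counts) == length(assignment), all(counts >= 0),
            n_perm >= 1)
  nm <- network_means(counts, assignment, network_names)
  surr <- .surrogate_network_means(counts, assignment, n_perm, seed)
  .perm_result(nm$mean, nm$mean, surr, n_perm, seed,
               "one-sided (greater connectivity)", nm$network,
               "mean streamline count")
}

#' Bonferroni adjustment over networks
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (default: `length(p)`, i.e. the seven
#'   networks in the standard analysis).
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Write a permutation result as CSV
#'
#' @param x A `permutation_result`.
#' @param path CSV path.
#' @export
write_permutation_result <- function(x, path) {
  tab <- x$table
  tab$n_perm <- x$n_perm
  tab$seed <- x$seed
  tab$sidedness <- x$sidedness
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
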