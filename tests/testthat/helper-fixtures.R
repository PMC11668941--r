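# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive, direct implementations so they never share code with the package
# paths they check.

tiny_atlas <- function(seed = 1) {
  make_atlas(n_parcels = 6, network_sizes = c(3, 3), grid_shape = c(6, 6, 6),
             voxel_size_mm = 2, seed = seed)
}

small_atlas <- function(seed = 3, n_parcels = 30,
                        sizes = c(5, 4, 4, 4, 4, 4, 5),
                        grid = c(12, 12, 12)) {
  make_atlas(n_parcels, sizes, grid, voxel_size_mm = 4, seed = seed)
}

quiet_noise <- function() {
  noise_spec(sd = 0, ar1 = 0, drift_coefs = c(0, 0, 0, 0), spike_prob = 0)
}

# Brute-force framewise displacement straight from the formula, frame by
# frame.
oracle_fd <- function(motion, radius = 50) {
  m <- as.matrix(motion[c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")])
  fd <- numeric(nrow(m))
  for (t in 2:nrow(m)) {
    s <- 0
    for (j in 1:3) s <- s + abs(m[t, j] - m[t - 1, j])
    for (j in 4:6) s <- s + radius * abs(m[t, j] - m[t - 1, j])
    fd[t] <- s
  }
  fd
}

# Exhaustive permutation-test p-values on a tiny two-network atlas: iterate
# over every distinct member set of network 1 (network 2 is the complement).
# Ties count as exceedances, matching the conservative convention.
oracle_exhaustive_one_sided <- function(v, assignment) {
  P <- length(v)
  members1 <- utils::combn(P, sum(assignment == 1), simplify = FALSE)
  obs <- c(-mean(v[assignment == 1]), -mean(v[assignment == 2]))
  count <- c(0, 0)
  for (m1 in members1) {
    s <- c(-mean(v[m1]), -mean(v[setdiff(seq_len(P), m1)]))
    for (k in 1:2) if (s[k] >= obs[k] - 1e-12) count[k] <- count[k] + 1
  }
  count / length(members1)
}

oracle_exhaustive_two_sided <- function(d, assignment) {
  P <- length(d)
  members1 <- utils::combn(P, sum(assignment == 1), simplify = FALSE)
  obs <- c(abs(mean(d[assignment == 1])), abs(mean(d[assignment == 2])))
  count <- c(0, 0)
  for (m1 in members1) {
    s <- c(abs(mean(d[m1])), abs(mean(d[setdiff(seq_len(P), m1)])))
    for (k in 1:2) if (s[k] >= obs[k] - 1e-12) count[k] <- count[k] + 1
  }
  count / length(members1)
}

# Recursive flood fill over an arbitrary neighbourhood, the slow way.
oracle_components <- function(supra, nn) {
  dims <- dim(supra)
  lab <- array(0L, dims)
  cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & rowSums(abs(offs)) <= nn, ,
               drop = FALSE]
  for (i0 in which(supra)) {
    if (lab[i0] != 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(i0, dims)[1, ])
    lab[i0] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > dims)) next
        li <- q[1] + (q[2] - 1) * dims[1] + (q[3] - 1) * dims[1] * dims[2]
        if (supra[li] && lab[li] == 0L) {
          lab[li] <- cur
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  sort(tabulate(lab[lab > 0L], nbins = cur), decreasing = TRUE)
}

# Dense-resampling membership oracle for the segment/sphere streamline test:
# walk the polyline in 0.1 mm steps and check point-in-sphere.
oracle_hits_sphere <- function(pts, center, r, step = 0.1) {
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    L <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(L / step) + 1))
    for (t in ts) {
      p <- a + t * (b - a)
      if (sum((p - center)^2) <= r^2) return(TRUE)
    }
  }
  FALSE
}

# Simulate run-level parcel data under the group model (used for the
# mixed-effects calibration and recovery checks without touching volumes).
simulate_group_parcels <- function(n_parcels, effect, subj_sd = 0.1,
                                   run_sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    subject <- rep(sprintf("s%d", 1:5), c(5, 5, 5, 4, 4))
    therapeutic <- c(rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 3),
                     rep(FALSE, 8))
    responder <- subject %in% c("s1", "s2", "s3")
    b_subj <- rnorm(5, 0, subj_sd)
    Y <- matrix(rnorm(23 * n_parcels, 0, run_sd), 23, n_parcels) +
      b_subj[as.integer(factor(subject))] +
      outer(therapeutic, rep(effect, n_parcels))
    list(Y = Y, design = group_design(subject, therapeutic, responder))
  })
}
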