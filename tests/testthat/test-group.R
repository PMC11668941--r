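test_that("group design validates its structure", {
  expect_error(group_design("s1", TRUE, TRUE), "2 subjects")
  expect_error(group_design(c("s1", "s2"), c(TRUE, TRUE), c(TRUE, TRUE)),
               "non-therapeutic")
  expect_error(group_design(c("s1", "s1", "s2"), c(TRUE, FALSE, FALSE),
                            c(TRUE, FALSE, FALSE)), "constant within")
  gd <- group_design(c("s1", "s1", "s2", "s2"),
                     c(TRUE, FALSE, FALSE, FALSE),
                     c(TRUE, TRUE, FALSE, FALSE))
  expect_s3_class(gd, "group_design")
})

test_that("mixed model recovers a known therapeutic effect", {
  ests <- vapply(1:50, function(s) {
    sim <- simulate_group_parcels(3, effect = -0.3, seed = s)
    mean(fit_parcelwise_lme(sim$Y, sim$design)$estimate)
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) + 0.3), 3 * se)
})

test_that("LME reduces to OLS difference of means without subject variance", {
  sim <- simulate_group_parcels(20, effect = -0.25, subj_sd = 0, seed = 2)
  fit <- fit_parcelwise_lme(sim$Y, sim$design, reduced = TRUE)
  ther <- sim$design$therapeutic
  dom <- unname(colMeans(sim$Y[ther, , drop = FALSE]) -
                  colMeans(sim$Y[!ther, , drop = FALSE]))
  # most fits hit the variance boundary and fall back to OLS ...
  ols <- fit$method == "ols"
  expect_gt(mean(ols), 0.5)
  # ... where the therapeutic estimate IS the difference of means
  expect_equal(fit$estimate[ols], dom[ols], tolerance = 1e-8)
  # the remaining near-boundary mixed fits agree closely
  expect_lt(max(abs(fit$estimate - dom)), 0.05)
})

test_that("group_parcel_lme aggregates contrast maps per parcel", {
  a <- small_atlas(grid = c(8, 8, 8), n_parcels = 7, sizes = rep(1, 7))
  mk <- function(val, subject, ther, resp) {
    vol <- array(val, dim(a$labels))
    structure(list(data = vol,
                   meta = list(subject = subject, therapeutic = ther,
                               responder = resp)),
              class = "contrast_map")
  }
  vals_t <- c(-0.4, -0.38, -0.42, -0.4)
  vals_n <- c(0.01, -0.01, 0.02, -0.02, 0, 0.01)
  contrasts <- c(
    mapply(mk, vals_t, c("s1", "s1", "s2", "s2"), TRUE, TRUE,
           SIMPLIFY = FALSE),
    mapply(mk, vals_n, c("s1", "s1", "s2", "s2", "s3", "s3"), FALSE,
           c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), SIMPLIFY = FALSE))
  gd <- group_design(vapply(contrasts, function(x) x$meta$subject, ""),
                     vapply(contrasts, function(x) x$meta$therapeutic, TRUE),
                     vapply(contrasts, function(x) x$meta$responder, TRUE))
  out <- group_parcel_lme(contrasts, gd, a)
  expect_equal(nrow(out), 7)
  expect_true(all(abs(out$estimate - (mean(vals_t) - mean(vals_n))) < 0.05))
})

test_that("connected components match the hand-constructed map", {
  m <- array(0, c(3, 3, 3))
  m[1, 1, 1] <- 1; m[2, 1, 1] <- 1   # face-adjacent pair
  m[3, 2, 2] <- 1                    # corner-adjacent to (2,1,1) only
  expect_equal(cluster_components(m, 0.5, nn = 1)$sizes, c(2, 1))
  expect_equal(cluster_components(m, 0.5, nn = 3)$sizes, 3)
  empty <- cluster_components(array(0, c(3, 3, 3)), 0.5)
  expect_equal(empty$sizes, integer(0))
})

test_that("component labelling agrees with a flood-fill oracle", {
  for (s in 1:60) {
    supra <- withr::with_seed(s, array(runif(8^3) < 0.25, c(8, 8, 8)))
    for (nn in c(1, 3)) {
      expect_equal(cluster_components(supra, nn = nn)$sizes,
                   oracle_components(supra, nn))
    }
  }
})

test_that("cluster tables report size-thresholded clusters with peaks", {
  m <- array(0, c(5, 5, 5))
  m[1:2, 1, 1] <- c(3, 4)          # size-2 cluster, peak 4
  m[5, 5, 5] <- -6                 # size-1 cluster (negative peak)
  tab <- cluster_table(m, threshold = 2, size_threshold = 1, nn = 1)
  expect_equal(tab$size, c(2, 1))
  expect_equal(tab$peak, c(4, -6))
  expect_equal(unlist(tab[1, c("peak_x", "peak_y", "peak_z")]),
               c(peak_x = 2, peak_y = 1, peak_z = 1))
  tab2 <- cluster_table(m, threshold = 2, size_threshold = 2)
  expect_equal(tab2$size, 2)
  expect_equal(nrow(cluster_table(m, threshold = 10)), 0)
})

test_that("cluster-extent threshold behaves across alpha and smoothness", {
  cfg <- suppressWarnings(cluster_config(n_iter = 150))
  t_white <- cluster_size_threshold(c(14, 14, 14), 0, cfg, seed = 4)
  t_smooth <- cluster_size_threshold(c(14, 14, 14), 3, cfg, seed = 4)
  expect_lt(t_white, t_smooth)
  # lower voxel_p prunes more voxels: threshold cannot increase
  cfg_strict <- suppressWarnings(cluster_config(voxel_p = 0.005,
                                                n_iter = 150))
  t_strict <- cluster_size_threshold(c(14, 14, 14), 0, cfg_strict, seed = 4)
  expect_lte(t_strict, t_white)
  cfg_all <- suppressWarnings(cluster_config(alpha = 1, n_iter = 50))
  expect_equal(as.integer(cluster_size_threshold(c(8, 8, 8), 0, cfg_all,
                                                 seed = 1)), 1L)
  expect_identical(
    as.integer(cluster_size_threshold(c(10, 10, 10), 2, cfg, seed = 9)),
    as.integer(cluster_size_threshold(c(10, 10, 10), 2, cfg, seed = 9)))
})
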