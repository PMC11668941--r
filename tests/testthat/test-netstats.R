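test_that("parcel and network means follow hand arithmetic", {
  a <- tiny_atlas()
  const <- array(2.5, dim(a$labels))
  expect_equal(parcel_means(const, a), rep(2.5, 6))
  idmap <- array(0, dim(a$labels))
  idmap[] <- a$labels
  expect_equal(parcel_means(idmap, a), as.numeric(1:6))

  # hand map: parcel 1 voxels set to -1 and -3, expect mean -2
  vol <- array(0, dim(a$labels))
  vox1 <- which(a$labels == 1)
  vol[vox1[1]] <- -1
  vol[vox1[2]] <- -3
  vol[setdiff(vox1, vox1[1:2])] <- -2
  expect_equal(parcel_means(vol, a)[1], -2)

  nm <- network_means(c(-1, -1, -1, 1, 1, 1), c(1, 1, 1, 2, 2, 2),
                      c("A", "B"))
  expect_equal(nm$mean, c(-1, 1))
  expect_equal(nm$suppression, c(1, -1))

  one <- network_means(c(4, 8, 3), c(1, 1, 1))
  expect_equal(one$mean, 5)

  # permuting parcels together with the assignment leaves means unchanged
  v <- withr::with_seed(1, rnorm(10))
  asg <- rep(1:2, 5)
  p <- withr::with_seed(2, sample(10))
  expect_equal(network_means(v[p], asg[p])$mean,
               network_means(v, asg)$mean)
})

test_that("the one-sided test floors at 1/n_perm for an unbeatable network", {
  asg <- rep(1:7, c(17, 13, 12, 13, 12, 13, 20))
  v <- ifelse(asg == 7, -1, 0)
  res <- one_sided_suppression_test(v, asg, n_perm = 10000, seed = 7)
  expect_equal(res$table$p_uncorrected[7], 1e-4)
  expect_equal(res$table$p_bonferroni[7], 7e-4)
})

test_that("tied surrogates give p = 1 on a constant vector", {
  asg <- rep(1:2, each = 3)
  res <- one_sided_suppression_test(rep(0.7, 6), asg, n_perm = 500, seed = 1)
  expect_equal(res$table$p_uncorrected, c(1, 1))
  # identical result on re-run with the same seed
  res2 <- one_sided_suppression_test(rep(0.7, 6), asg, n_perm = 500, seed = 1)
  expect_identical(res$table, res2$table)
})

test_that("Monte-Carlo p matches exhaustive enumeration on the tiny atlas", {
  v <- c(-2, -1, -3, 0, 1, 2)
  asg <- rep(1:2, each = 3)
  exh <- oracle_exhaustive_one_sided(v, asg)
  mc <- one_sided_suppression_test(v, asg, n_perm = 10000, seed = 3)
  for (k in 1:2) {
    se <- sqrt(exh[k] * (1 - exh[k]) / 10000)
    expect_lt(abs(mc$table$p_uncorrected[k] - exh[k]), 2 * se + 1e-9)
  }
  d <- c(0.5, -1.2, 2, 0.3, -0.7, 1.1)
  exh2 <- oracle_exhaustive_two_sided(d, asg)
  mc2 <- two_sided_difference_test(d, rep(0, 6), asg, n_perm = 10000,
                                   seed = 4)
  for (k in 1:2) {
    se <- sqrt(exh2[k] * (1 - exh2[k]) / 10000)
    expect_lt(abs(mc2$table$p_uncorrected[k] - exh2[k]), 2 * se + 1e-9)
  }
})

test_that("the two-sided test is symmetric and null at equality", {
  v <- withr::with_seed(5, rnorm(20))
  asg <- rep(1:4, 5)
  same <- two_sided_difference_test(v, v, asg, n_perm = 200, seed = 1)
  expect_equal(same$table$p_uncorrected, rep(1, 4))

  w <- withr::with_seed(6, rnorm(20))
  a_res <- two_sided_difference_test(v, w, asg, n_perm = 1000, seed = 2)
  b_res <- two_sided_difference_test(w, v, asg, n_perm = 1000, seed = 2)
  expect_equal(a_res$table$p_uncorrected, b_res$table$p_uncorrected)

  # shift invariance: adding a constant to the difference's inputs jointly
  c_res <- two_sided_difference_test(v + 3, w + 3, asg, n_perm = 1000,
                                     seed = 2)
  expect_equal(a_res$table$p_uncorrected, c_res$table$p_uncorrected)
})

test_that("Bonferroni adjustment caps at 1", {
  expect_equal(bonferroni_adjust(0.01, 7), 0.07)
  expect_equal(bonferroni_adjust(0.5, 7), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.9), 1), c(0.2, 0.9))
  asg <- rep(1:7, 3)
  res <- one_sided_suppression_test(withr::with_seed(1, rnorm(21)), asg,
                                    n_perm = 200, seed = 1)
  expect_equal(res$table$p_bonferroni,
               pmin(1, 7 * res$table$p_uncorrected))
})

test_that("permutation results serialise to CSV with their provenance", {
  asg <- rep(1:2, each = 3)
  res <- one_sided_suppression_test(c(-1, -1, -1, 0, 0, 0), asg,
                                    n_perm = 100, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_permutation_result(res, f)
  back <- read.csv(f)
  expect_equal(back$p_uncorrected, res$table$p_uncorrected)
  expect_equal(unique(back$n_perm), 100)
  expect_equal(unique(back$seed), 9)
})

test_that("connectivity permutation test favours the loaded network", {
  asg <- rep(1:7, c(17, 13, 12, 13, 12, 13, 20))
  flat <- connectivity_permutation_test(rep(4, 100), asg, n_perm = 300,
                                        seed = 1)
  expect_equal(flat$table$p_uncorrected, rep(1, 7))
  loaded <- ifelse(asg == 3, 50, 0)
  res <- connectivity_permutation_test(loaded, asg, n_perm = 2000, seed = 2)
  expect_equal(res$table$p_uncorrected[3], 1 / 2000)
  expect_true(all(res$table$p_uncorrected[-3] > 0.5))
})
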