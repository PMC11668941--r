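mot <- function(n = 4) {
  data.frame(trans_x = numeric(n), trans_y = numeric(n),
             trans_z = numeric(n), rot_x = numeric(n),
             rot_y = numeric(n), rot_z = numeric(n))
}

test_that("framewise displacement follows the absolute-sum formula", {
  m <- mot(3)
  expect_equal(framewise_displacement(m), c(0, 0, 0))

  m2 <- mot(2)
  m2[2, c("trans_x", "trans_y", "trans_z")] <- c(0.1, 0.2, 0.2)
  fd <- framewise_displacement(m2)
  expect_equal(fd, c(0, 0.5))
  # exactly at threshold: NOT censored (strict >)
  conf <- data.frame(framewise_displacement = fd, std_dvars = c(0, 0))
  expect_equal(censor_frames(conf), c(FALSE, FALSE))

  m3 <- mot(2)
  m3[2, c("rot_x", "rot_y", "rot_z")] <- 0.01
  fd3 <- framewise_displacement(m3, head_radius_mm = 50)
  expect_equal(fd3, c(0, 3 * 0.01 * 50))
  conf3 <- data.frame(framewise_displacement = fd3, std_dvars = c(0, 0))
  expect_equal(censor_frames(conf3), c(FALSE, TRUE))

  expect_error(framewise_displacement(matrix(0, 3, 4)), "6 columns")
})

test_that("FD matches a brute-force recomputation and ignores constant shifts", {
  for (s in 1:5) {
    m <- withr::with_seed(s, as.data.frame(matrix(rnorm(60, 0, 0.2), 10, 6)))
    names(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    expect_equal(framewise_displacement(m), oracle_fd(m))
    shifted <- m
    shifted$trans_y <- shifted$trans_y + 3.7
    shifted$rot_z <- shifted$rot_z + 0.5
    expect_equal(framewise_displacement(shifted),
                 framewise_displacement(m))
  }
})

test_that("standardized DVARS has median 1 under stationary noise", {
  bold <- withr::with_seed(1, array(100 + rnorm(5 * 5 * 5 * 60), c(5, 5, 5, 60)))
  dv <- std_dvars(bold)
  expect_equal(dv[1], 0)
  expect_equal(median(dv[-1]), 1)

  const <- array(7, c(3, 3, 3, 10))
  expect_equal(std_dvars(const), numeric(10))

  spiked <- bold
  spiked[, , , 30] <- spiked[, , , 30] + 10
  dvs <- std_dvars(spiked)
  # a global spike at frame 30 dominates both transitions it touches
  expect_true(which.max(dvs) %in% c(30, 31))
  expect_true(all(sort(dvs, decreasing = TRUE)[1:2] == sort(dvs[30:31],
                                                            decreasing = TRUE)))
  expect_error(std_dvars(bold, array(FALSE, c(5, 5, 5))), "empty")
})

test_that("censoring applies the strict FD/DVARS OR rule", {
  conf <- data.frame(framewise_displacement = c(0, 0.6, 0.5),
                     std_dvars = c(0, 0, 1.6))
  expect_equal(censor_frames(conf), c(FALSE, TRUE, TRUE))
  expect_equal(censor_frames(data.frame(framewise_displacement = rep(0, 5),
                                        std_dvars = rep(0, 5))),
               rep(FALSE, 5))
  loose <- qc_config(fd_thresh = 1e9, dvars_thresh = 1e9)
  expect_equal(censor_frames(conf, loose), rep(FALSE, 3))
})

test_that("censoring is monotone in the thresholds", {
  conf <- withr::with_seed(2, data.frame(
    framewise_displacement = c(0, runif(29, 0, 1.2)),
    std_dvars = c(0, runif(29, 0, 2.5))))
  for (fd_t in c(0.3, 0.5, 0.8)) {
    for (dv_t in c(1, 1.5, 2)) {
      base <- censor_frames(conf, qc_config(fd_t, dv_t))
      lower <- censor_frames(conf, qc_config(fd_t / 2, dv_t / 2))
      expect_true(all(lower[base]))   # lowering never un-censors
    }
  }
})

test_that("confounds tables round-trip through TSV", {
  a <- small_atlas(grid = c(8, 8, 8), n_parcels = 7, sizes = rep(1, 7))
  sim <- simulate_run(cycling_design(), a, network_effect_profile(),
                      noise_spec(spike_prob = 0.05), seed = 3)
  conf <- compute_confounds(sim$bold, sim$motion)
  expect_true(all(conf$framewise_displacement >= 0))
  expect_true(all(conf$std_dvars >= 0))
  expect_equal(conf$censor,
               conf$framewise_displacement > 0.5 | conf$std_dvars > 1.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_confounds(conf, f)
  back <- read_confounds(f)
  expect_equal(back$censor, conf$censor)
  expect_equal(back$framewise_displacement, conf$framewise_displacement,
               tolerance = 1e-9)
})
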