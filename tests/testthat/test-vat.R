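lead4 <- function() electrode_model(cbind(20, 20, 10 + (0:3) * 2))

test_that("electrode and stimulation configuration validation", {
  expect_error(electrode_model(matrix(1:3, 1, 3)), "2")
  bent <- rbind(c(0, 0, 0), c(0, 0, 2), c(3, 0, 4))
  expect_error(electrode_model(bent), "collinear")
  expect_error(stimulation_config("lead", 1, 3), "adjacent")
  expect_s3_class(stimulation_config("lead", 1, 3,
                                     allow_nonadjacent = TRUE),
                  "stimulation_config")
  expect_error(stimulation_config("lead", 2, 2), "anode")
})

test_that("the paired-sphere VAT follows its radius law", {
  e <- lead4()
  v5 <- estimate_vat(e, stimulation_config("lead", 2, 3, 5))
  expect_equal(v5$radius_mm, 1.8 * sqrt(5))
  v_small <- estimate_vat(e, stimulation_config("lead", 2, 3, 1e-6))
  expect_lt(v_small$radius_mm, 0.002)      # volume -> 0 with amplitude
  v_custom <- estimate_vat(e, stimulation_config("lead", 2, 3, 4),
                           radius_model = function(mA) mA / 2)
  expect_equal(v_custom$radius_mm, 2)
  # sphere volume scales with r^3: doubling r multiplies volume by 8
  vol <- function(r) 4 / 3 * pi * r^3
  expect_equal(vol(2 * v5$radius_mm) / vol(v5$radius_mm), 8)
  # configurations sharing a contact overlap there
  v23 <- estimate_vat(e, stimulation_config("lead", 2, 3, 5))
  v34 <- estimate_vat(e, stimulation_config("lead", 3, 4, 5))
  shared <- e$contacts[3, ]
  expect_true(sqrt(sum((shared - v23$centers[2, ])^2)) < v23$radius_mm)
  expect_true(sqrt(sum((shared - v34$centers[1, ])^2)) < v34$radius_mm)
})

test_that("streamline filtering keeps exactly the VAT-intersecting lines", {
  e <- lead4()
  vat <- estimate_vat(e, stimulation_config("lead", 2, 3, 5))
  far <- matrix(c(100, 100, 100, 120, 100, 100), 2, 3, byrow = TRUE)
  at_center <- rbind(vat$centers[1, ], c(50, 50, 50))
  # segment crossing the sphere between two distant endpoints
  ctr <- vat$centers[1, ]
  crossing <- rbind(ctr + c(-30, 0.5, 0), ctr + c(30, -0.5, 0))
  st <- streamline_set(list(far, at_center, crossing))
  filt <- streamlines_through_vat(st, vat)
  expect_equal(attr(filt, "kept"), c(2L, 3L))
})

test_that("segment-sphere filtering matches the dense-resampling oracle", {
  hits_impl <- logical(300)
  hits_orac <- logical(300)
  withr::with_seed(11, {
    for (i in 1:300) {
      ctr <- runif(3, -5, 5)
      r <- runif(1, 0.5, 4)
      pts <- matrix(rnorm(9, 0, 6), 3, 3)
      vat <- structure(list(centers = matrix(ctr, 1, 3), radius_mm = r),
                       class = "vat")
      st <- streamline_set(list(pts))
      hits_impl[i] <- length(streamlines_through_vat(st, vat)) == 1
      hits_orac[i] <- oracle_hits_sphere(pts, ctr, r, step = 0.05)
    }
  })
  # the analytic test can only disagree with a 0.05 mm walk on grazing
  # tangencies; require at least near-perfect agreement and both classes
  expect_gte(mean(hits_impl == hits_orac), 0.995)
  expect_gt(sum(hits_impl), 0)
  expect_gt(sum(!hits_impl), 0)
})

test_that("filtering is monotone in the VAT radius", {
  e <- lead4()
  a <- small_atlas()
  vat_small <- estimate_vat(e, stimulation_config("lead", 2, 3, 2))
  vat_big <- estimate_vat(e, stimulation_config("lead", 2, 3, 8))
  w <- c(Vis = 0.2, SomMot = 0, DorsAttn = 0, SalVentAttn = 0,
         Limbic = 0.2, Cont = 0, Default = 0.3, elsewhere = 0.3)
  st <- simulate_streamlines(400, a, vat_small, w, seed = 6)
  kept_small <- attr(streamlines_through_vat(st, vat_small), "kept")
  kept_big <- attr(streamlines_through_vat(st, vat_big), "kept")
  expect_true(all(kept_small %in% kept_big))
})

test_that("endpoint parcel assignment and fractions behave as documented", {
  a <- small_atlas()
  ctr <- c(24, 24, 24)
  vat <- structure(list(centers = matrix(ctr, 1, 3), radius_mm = 3,
                        config = NULL), class = "vat")
  # streamline from the VAT centre to a known parcel voxel centre
  target_parcel <- 5L
  vox <- stimcycle:::parcel_voxel_world(a, target_parcel)
  tip <- vox[which.max(rowSums(sweep(vox, 2, ctr)^2)), ]
  inside <- rbind(ctr, tip)
  outside_tip <- rbind(ctr, c(300, 300, 300))    # ends in background
  pr <- network_streamline_fractions(streamline_set(list(inside)), a, vat)
  net <- a$assignment[target_parcel]
  expect_equal(unname(pr$network_fractions[net]), 1)
  expect_equal(sum(pr$parcel_counts), 1)
  expect_equal(pr$parcel_counts[target_parcel], 1L)

  pr2 <- network_streamline_fractions(
    streamline_set(list(inside, outside_tip)), a, vat)
  expect_equal(unname(pr2$network_fractions["unassigned"]), 0.5)
  expect_equal(sum(pr2$network_fractions), 1)   # networks + unassigned
  pr3 <- network_streamline_fractions(
    streamline_set(list(inside, outside_tip)), a, vat,
    denominator = "cortical")
  expect_equal(unname(pr3$network_fractions[net]), 1)
})

test_that("fractions are invariant to streamline order and rigid shifts", {
  a <- small_atlas()
  e <- electrode_model(cbind(24, 24, 18 + (0:3) * 2))
  vat <- estimate_vat(e, stimulation_config("lead", 2, 3, 5))
  w <- c(Vis = 0, SomMot = 0.3, DorsAttn = 0, SalVentAttn = 0,
         Limbic = 0, Cont = 0.3, Default = 0.4)
  st <- simulate_streamlines(600, a, vat, w, seed = 12)
  pr <- network_streamline_fractions(streamlines_through_vat(st, vat),
                                     a, vat)
  perm <- withr::with_seed(1, sample(length(st$lines)))
  st_perm <- streamline_set(st$lines[perm])
  pr_perm <- network_streamline_fractions(
    streamlines_through_vat(st_perm, vat), a, vat)
  expect_equal(pr_perm$network_fractions, pr$network_fractions)

  shift <- c(5, -3, 2)
  a2 <- a
  a2$affine[1:3, 4] <- a2$affine[1:3, 4] + shift
  vat2 <- vat
  vat2$centers <- sweep(vat2$centers, 2, -shift)
  st2 <- streamline_set(lapply(st$lines, function(m) sweep(m, 2, -shift)))
  pr2 <- network_streamline_fractions(streamlines_through_vat(st2, vat2),
                                      a2, vat2)
  expect_equal(pr2$network_fractions, pr$network_fractions)
})

test_that("rasterised and external-mask VATs agree with the sphere model", {
  a <- small_atlas()
  e <- electrode_model(cbind(24, 24, 18 + (0:3) * 2))
  vat <- estimate_vat(e, stimulation_config("lead", 2, 3, 5))
  mask <- vat_mask_on_grid(vat, a)
  expect_gt(sum(mask), 0)
  # voxel centres flagged by the mask are inside a sphere
  idx <- which(mask)
  ijk <- arrayInd(idx[1], dim(a$labels))
  xyz <- (ijk - 1) * a$voxel_size_mm
  d <- min(sqrt(rowSums(sweep(vat$centers, 2, as.numeric(xyz))^2)))
  expect_lte(d, vat$radius_mm + 1e-9)

  vm <- vat_from_mask(mask, a$affine)
  w <- c(Vis = 0.3, SomMot = 0, DorsAttn = 0, SalVentAttn = 0,
         Limbic = 0, Cont = 0, Default = 0.5, elsewhere = 0.2)
  st <- simulate_streamlines(200, a, vat, w, seed = 4)
  kept_sphere <- attr(streamlines_through_vat(st, vat), "kept")
  kept_mask <- attr(streamlines_through_vat(st, vm), "kept")
  # the voxelised field is a coarse cover of the spheres: near-identical
  expect_gt(length(intersect(kept_sphere, kept_mask)) /
              length(union(kept_sphere, kept_mask)), 0.9)

  f <- withr::local_tempfile(fileext = ".csv")
  pr <- network_streamline_fractions(streamlines_through_vat(st, vat),
                                     a, vat)
  write_connectivity_profile(pr, f)
  back <- read.csv(f)
  expect_equal(back$fraction, as.numeric(pr$network_fractions))
})

test_that("TCK files round-trip", {
  st <- streamline_set(list(matrix(rnorm(9), 3, 3),
                            matrix(rnorm(6, 10), 2, 3)))
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(st, f)
  back <- read_tck(f)
  expect_equal(length(back), 2)
  for (i in 1:2) {
    expect_equal(back$lines[[i]], st$lines[[i]], tolerance = 1e-5)
  }
})
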