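test_that("atlas construction satisfies its invariants and is deterministic", {
  a <- make_atlas(100, c(17, 13, 12, 13, 12, 13, 20), c(24, 24, 24), seed = 2)
  expect_equal(n_parcels(a), 100)
  expect_true(all(tabulate(a$labels[a$labels > 0], 100) > 0))
  expect_equal(length(unique(a$assignment)), 7)
  expect_equal(tabulate(a$assignment), c(17, 13, 12, 13, 12, 13, 20))
  expect_identical(a$labels,
                   make_atlas(100, c(17, 13, 12, 13, 12, 13, 20),
                              c(24, 24, 24), seed = 2)$labels)
  expect_false(identical(a$labels,
                         make_atlas(100, c(17, 13, 12, 13, 12, 13, 20),
                                    c(24, 24, 24), seed = 3)$labels))

  tiny <- tiny_atlas()
  expect_equal(sort(unique(as.vector(tiny$labels[tiny$labels > 0]))), 1:6)
  expect_error(make_atlas(500, c(250, 250), c(6, 6, 6)), "too small")
})

test_that("atlas round-trips through NIfTI + TSV", {
  a <- small_atlas()
  d <- withr::local_tempdir()
  write_atlas(a, file.path(d, "atlas.nii.gz"), file.path(d, "parcels.tsv"))
  b <- read_atlas(file.path(d, "atlas.nii.gz"), file.path(d, "parcels.tsv"))
  expect_identical(b$labels, a$labels)
  expect_equal(b$assignment, a$assignment)
  expect_equal(b$affine, a$affine)
  expect_equal(b$network_names, a$network_names)
})

test_that("simulated runs have the cycling structure and exact noiseless form", {
  a <- small_atlas()
  d <- cycling_design()
  expect_equal(d$n_frames, 180)
  box <- stimulus_boxcars(d)
  expect_equal(box$off[1], 0)   # frame 1 is inside the Off ramp-down
  expect_equal(box$on[1], 0)
  # frame at t = 20 s is on the Off plateau, t = 90 s on the On plateau
  expect_equal(box$off[11], 1)
  expect_equal(box$on[46], 1)

  sim <- simulate_run(d, a, network_effect_profile(therapeutic = rep(0, 7)),
                      quiet_noise(), seed = 4)
  expect_equal(dim(sim$bold), c(12, 12, 12, 180))
  # zero effects, zero noise, zero drift: constant 100 everywhere
  expect_equal(max(abs(sim$bold - 100)), 0, tolerance = 1e-12)

  ns <- noise_spec(sd = 0, ar1 = 0, drift_coefs = c(0, 0.5, 0, 0),
                   spike_prob = 0)
  sim2 <- simulate_run(d, a, network_effect_profile(therapeutic = rep(0, 7)),
                       ns, seed = 4)
  ts <- sim2$bold[6, 6, 6, ]
  # linear drift of 0.5% amplitude, mean-centred around 100
  expect_equal(mean(ts), 100, tolerance = 1e-9)
  expect_equal(max(ts) - min(ts), 2 * 0.5, tolerance = 1e-6)

  sim3 <- simulate_run(d, a, network_effect_profile(), noise_spec(),
                       seed = 11)
  sim4 <- simulate_run(d, a, network_effect_profile(), noise_spec(),
                       seed = 11)
  expect_identical(sim3$bold, sim4$bold)
  expect_identical(sim3$motion, sim4$motion)
})

test_that("streamline generator hits the requested network mix", {
  a <- small_atlas()
  elec <- electrode_model(cbind(24, 24, 18 + (0:3) * 2))
  vat <- estimate_vat(elec, stimulation_config("lead", 2, 3, 5))
  w <- c(Vis = 0, SomMot = 0, DorsAttn = 0, SalVentAttn = 0, Limbic = 0,
         Cont = 0, Default = 1)
  st <- simulate_streamlines(500, a, vat, w, seed = 2)
  filt <- streamlines_through_vat(st, vat)
  pr <- network_streamline_fractions(filt, a, vat)
  expect_equal(unname(pr$network_fractions["Default"]), 1)

  w2 <- c(Vis = 0, SomMot = 0, DorsAttn = 0, SalVentAttn = 0,
          Limbic = 0.4, Cont = 0, Default = 0.6)
  st2 <- simulate_streamlines(10000, a, vat, w2, seed = 3)
  pr2 <- network_streamline_fractions(streamlines_through_vat(st2, vat),
                                      a, vat)
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(pr2$network_fractions["Default"] - 0.6), 3 * se + 1e-9)
  expect_lt(abs(pr2$network_fractions["Limbic"] - 0.4), 3 * se + 1e-9)

  st3 <- simulate_streamlines(50, a, vat, w, seed = 9)
  st4 <- simulate_streamlines(50, a, vat, w, seed = 9)
  expect_identical(st3$lines, st4$lines)
  expect_error(simulate_streamlines(10, a, structure(
    list(centers = matrix(numeric(0), 0, 3), radius_mm = 1,
         config = NULL), class = "vat"), w), "empty VAT")
})

test_that("the default study design matches the cycling experiment layout", {
  cfg <- study_config()
  tab <- study_run_table(cfg)
  expect_equal(nrow(tab), 23)
  expect_equal(sum(tab$therapeutic), 6)
  expect_equal(length(unique(tab$subject[tab$therapeutic])), 3)
  expect_equal(sum(!tab$therapeutic), 17)
  expect_equal(length(unique(tab$subject)), 5)
  expect_true(all(tab$responder[tab$therapeutic]))
  expect_equal(cfg$run_length_s / cfg$tr_s, 180)
  expect_equal(cfg$cycle_s, 60)
  expect_equal(cfg$ramp_s, 8)
})

test_that("generate_study writes a complete, reproducible layout", {
  cfg <- study_config(n_subjects = 2, responder_flags = c(TRUE, FALSE),
                      therapeutic_runs = c(1, 0),
                      nontherapeutic_runs = c(1, 1),
                      grid_shape = c(10, 10, 10), n_parcels = 14,
                      network_sizes = c(2, 2, 2, 2, 2, 2, 2),
                      n_streamlines = 200, seed = 5)
  d1 <- withr::local_tempdir()
  man1 <- generate_study(cfg, d1)
  expect_equal(sum(grepl("_bold\\.nii\\.gz$", man1$file)), 3)
  expect_equal(sum(grepl("_tracks\\.tck$", man1$file)), 2)
  expect_true("atlas/parcels.tsv" %in% man1$file)
  expect_equal(nrow(validate_inputs(d1)), 0)

  d2 <- withr::local_tempdir()
  man2 <- generate_study(cfg, d2)
  expect_identical(man1$md5, man2$md5)   # byte-identical regeneration

  # single subject / single run smoke fixture
  cfg1 <- study_config(n_subjects = 1, responder_flags = TRUE,
                       therapeutic_runs = 1, nontherapeutic_runs = 0,
                       grid_shape = c(8, 8, 8), n_parcels = 7,
                       network_sizes = rep(1, 7), n_streamlines = 20,
                       seed = 2)
  d3 <- withr::local_tempdir()
  man3 <- generate_study(cfg1, d3)
  expect_equal(sum(grepl("_bold", man3$file)), 1)
})
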