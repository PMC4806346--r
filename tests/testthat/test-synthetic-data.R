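test_that("generators are deterministic given a seed and leave the RNG alone", {
  set.seed(99); before <- .Random.seed
  a <- gen_ohmic_iv(1e9, noise_sd = 1e-11, seed = 7)
  b <- gen_ohmic_iv(1e9, noise_sd = 1e-11, seed = 7)
  expect_identical(a, b)
  expect_identical(before, .Random.seed)

  f1 <- gen_fiber(jitter_sd = 0.2, n_frames = 3, seed = 5)
  f2 <- gen_fiber(jitter_sd = 0.2, n_frames = 3, seed = 5)
  expect_identical(f1, f2)
  s1 <- gen_stm_iv(gap_width = 0.3, n_sweeps = 4, noise_sd = 1e-12, seed = 2)
  s2 <- gen_stm_iv(gap_width = 0.3, n_sweeps = 4, noise_sd = 1e-12, seed = 2)
  expect_identical(s1, s2)
  # different seeds give different noise
  expect_false(identical(gen_ohmic_iv(1e9, noise_sd = 1e-11, seed = 1),
                         gen_ohmic_iv(1e9, noise_sd = 1e-11, seed = 2)))
  # byte-level determinism on disk
  p1 <- tempfile(); p2 <- tempfile()
  write_iv_csv(gen_ohmic_iv(1e9, noise_sd = 1e-11, seed = 3), p1)
  write_iv_csv(gen_ohmic_iv(1e9, noise_sd = 1e-11, seed = 3), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("noiseless ohmic sweep is the exact line I = V/R", {
  c0 <- gen_ohmic_iv(R = 1e9, v_range = 1, n_points = 201, noise_sd = 0)
  expect_equal(c0$current, c0$voltage / 1e9)
  expect_error(gen_ohmic_iv(R = -5), "positive")
  expect_error(gen_ohmic_iv(R = 1e9, n_points = 3), ">= 5")
})

test_that("seeded ohmic round-trip recovers R within 1%", {
  cv <- gen_ohmic_iv(R = 7.3e8, noise_sd = 5e-12, seed = 1)
  fit <- fit_ohmic_resistance(cv)
  expect_lt(abs(fit$R - 7.3e8) / 7.3e8, 0.01)
})

test_that("noise calibrated via iv_noise_for_r2 lands fits in the R^2 = 0.98-0.99 band", {
  ns <- iv_noise_for_r2(7.3e8, r2 = 0.985)
  r2 <- vapply(1:40, function(s)
    fit_ohmic_resistance(gen_ohmic_iv(7.3e8, noise_sd = ns, seed = s))$r_squared,
    numeric(1))
  expect_gt(mean(r2), 0.98)
  expect_lt(mean(r2), 0.99)
})

test_that("SCLT generator is continuous at V_C with the exact scale factor", {
  # alpha = V_C^(1-b)/R = 0.5^-1 / 1e9 = 2e-9 A/V^2
  cv <- gen_sclt_iv(R_ohmic = 1e9, V_C = 0.5, b = 2, noise_sd = 0)
  expect_equal(cv$meta$truth$alpha, 2e-9)
  v <- cv$voltage; i <- cv$current
  above <- abs(v) > 0.5
  expect_equal(i[above], sign(v[above]) * 2e-9 * v[above]^2)
  expect_equal(i[!above], v[!above] / 1e9)
  # continuity: both branches agree at V_C
  expect_equal(0.5 / 1e9, 2e-9 * 0.5^2)
  # antisymmetric
  expect_equal(i, -rev(i))
  expect_error(gen_sclt_iv(1e9, V_C = 1.5, b = 2, v_max = 1), "V_C")
})

test_that("distance-series generator matches closed-form values and exact regression", {
  # linear: 30 MOhm + 0.73 MOhm/nm * 1000 nm = 760 MOhm
  s <- gen_distance_series("linear", 7.3e5, 3e7,
                           distances = c(100, 500, 1000), noise_sd = 0)
  expect_equal(s$R_ohm[3], 7.6e8)
  fit <- regress_distance(s)
  expect_equal(fit$model, "linear")
  expect_equal(fit$slope, 7.3e5)
  expect_equal(fit$intercept, 3e7)
  # mutant-like exponential series reaching ~4 GOhm at 1 um
  rate <- log(4e9 / 3e7) / 1000
  sm <- gen_distance_series("exponential", rate, 3e7,
                            distances = seq(100, 1000, by = 100),
                            noise_sd = 0)
  expect_equal(sm$R_ohm[10], 4e9, tolerance = 1e-10)
  expect_error(gen_distance_series("linear", 1, 1, distances = c(10, 20)),
               "3 points")
})

test_that("fiber generator plants exact ring geometry and emits readable PDB", {
  fib <- stacked_fiber(n_subunits = 3, rise = 4.5)
  # 3 subunits x 1 TYR x 6 ring carbons
  expect_equal(nrow(fib$atoms), 18)
  expect_true(all(fib$atoms$resname == "TYR"))
  # stacked rings: planted min C-C distance between adjacent subunits = rise
  tr <- read_trajectory(paste(fiber_pdb_text(fib), collapse = "\n"))
  expect_equal(dim(tr$coords)[3], 1)
  d <- min_carbon_distance(tr, list(chain = "A", resno = 1),
                           list(chain = "B", resno = 1))
  expect_equal(d, 4.5, tolerance = 1e-3)
  # multi-frame round-trip preserves the roster
  fib5 <- gen_fiber(n_frames = 5, jitter_sd = 0.1, seed = 3)
  tr5 <- read_trajectory(paste(fiber_pdb_text(fib5), collapse = "\n"))
  expect_equal(dim(tr5$coords)[3], 5)
  expect_equal(nrow(tr5$atoms), nrow(fib5$atoms))
  expect_equal(tr5$atoms$chain, fib5$atoms$chain)
  # coordinates survive to PDB precision (0.001 A)
  expect_equal(tr5$coords, fib5$coords, tolerance = 1e-3)
  expect_error(gen_fiber(remove_ring_at = 9), "remove_ring_at")
})

test_that("ring removal turns the residue into a lone beta-carbon and never adds contacts", {
  wt <- stacked_fiber(n_subunits = 4, rise = 4.5, two_residues = TRUE,
                      n_frames = 2, jitter_sd = 0.05, seed = 8)
  mut <- stacked_fiber(n_subunits = 4, rise = 4.5, two_residues = TRUE,
                       n_frames = 2, jitter_sd = 0.05, seed = 8,
                       remove_ring_at = 1)
  expect_true(all(mut$atoms$resname[mut$atoms$resno == 1] == "ALA"))
  expect_true(all(mut$atoms$name[mut$atoms$resno == 1] == "CB"))
  cw <- contact_census(wt); cm <- contact_census(mut)
  expect_lte(sum(cm$records$contact), sum(cw$records$contact))
  expect_lte(cm$stats$mean_contacts_per_subunit,
             cw$stats$mean_contacts_per_subunit)
})

test_that("STM generator: gapless sweeps have strictly positive slope, gapped sweeps a flat interval", {
  g0 <- gen_stm_iv(gap_width = 0, conduct_scale = 1e-9, curvature = 1)[[1]]
  slopes <- diff(g0$current) / diff(g0$voltage)
  expect_true(all(slopes > 0))
  gg <- gen_stm_iv(gap_width = 0.4, gap_center = 0)[[1]]
  inside <- abs(gg$voltage) <= 0.19
  expect_true(all(gg$current[inside] == 0))
  expect_length(gen_stm_iv(gap_width = 0.2, n_sweeps = 7), 7)
})

test_that("topography generator validates resolvability and plants sinusoids", {
  expect_error(gen_topography(periods = 0.8, sampling = 0.5), "periods")
  flat <- gen_topography(length = 150, sampling = 0.5)
  expect_true(all(flat$height_nm == 0))
  one <- gen_topography(periods = 14, amplitudes = 1, length = 200,
                        sampling = 0.5)
  expect_equal(max(one$height_nm), 1, tolerance = 1e-3)
})

test_that("optical generator builds Gaussian mixtures and validates inputs", {
  sp <- gen_optical(list(c(270, 10, 1)), range = c(200, 700))
  expect_equal(sp$wavelength_nm[which.max(sp$signal)], 270, tolerance = 1)
  expect_error(gen_optical(list(c(900, 10, 1)), range = c(200, 700)),
               "within")
  flat <- gen_optical(list())
  expect_true(all(flat$signal == 0))
  expect_error(gen_elemental(data.frame(element = "Ca", ppm = -1)), "ppm")
  tab <- gen_elemental(list(list("Ca", 0.104), list("Fe", 0)))
  expect_equal(tab$element, c("Ca", "Fe"))
})
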