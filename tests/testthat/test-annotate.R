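# Noise estimation, peak picking, charge inference, species matching,
# chain assignment and isomer ratios.

test_that("noise estimate is the scaled MAD and is robust to a stray peak", {
  flat <- mass_spectrum(seq(600, 700, 0.01), rep(5, 10001))
  expect_identical(estimate_noise(flat, list(c(630, 688))), 0)
  set.seed(21)
  mz <- seq(600, 700, 0.01)
  y <- rnorm(length(mz), 0, 2.5)
  s <- mass_spectrum(mz, y)
  expect_equal(estimate_noise(s, list(c(600, 700))), 2.5, tolerance = 0.1)
  # a peak occupying part of the window inflates the estimate < 2x
  y2 <- y + 500 * exp(-(mz - 650)^2 / (2 * 0.05^2))
  s2 <- mass_spectrum(mz, y2)
  expect_lt(estimate_noise(s2, list(c(600, 700))) /
              estimate_noise(s, list(c(600, 700))), 2)
  expect_error(estimate_noise(s, list()), "window")
  expect_error(estimate_noise(s, list(c(900, 950))), "no samples")
})

test_that("peak picking centroids a noiseless Gaussian to within 1 ppm", {
  mu <- 727.51013684
  mz <- seq(727.2, 727.8, 727.5 / 280000)
  fwhm <- mu / 70000
  y <- 1000 * exp(-(mz - mu)^2 / (2 * (fwhm / 2.3548)^2))
  cen <- pick_peaks(mass_spectrum(mz, y), noise_level = 1)
  expect_identical(nrow(cen), 1L)
  expect_lt(abs(ppm_error(cen$mz, mu)), 1)
  # flat spectrum yields nothing
  expect_identical(nrow(pick_peaks(mass_spectrum(mz, numeric(length(mz))),
                                   noise_level = 1)), 0L)
  expect_error(pick_peaks(mass_spectrum(mz, y), noise_level = 0), "> 0")
})

test_that("two peaks separated by the doubly-charged isotopologue spacing
           are resolved at R = 70,000", {
  mu <- 727.51013684
  mz <- seq(727.2, 728.4, 727.5 / 280000)
  fwhm <- mu / 70000
  g <- function(m, h) h * exp(-(mz - m)^2 / (2 * (fwhm / 2.3548)^2))
  y <- g(mu, 1000) + g(mu + 0.50168, 800)
  cen <- pick_peaks(mass_spectrum(mz, y), noise_level = 1)
  expect_identical(nrow(cen), 2L)
  expect_equal(diff(cen$mz), 0.50168, tolerance = 2e-3)
})

test_that("charge is inferred from isotopologue spacing, trying compact
           spacings first", {
  # doubly charged envelope: spacing ~0.5017, with M+2 at ~1.0034
  cen2 <- data.frame(mz = 727.51 + (0:3) * 1.0033548 / 2,
                     intensity = c(1000, 890, 430, 150), index = 1:4)
  expect_identical(assign_charge(cen2, 727.51), 2L)
  # singly charged envelope
  cen1 <- data.frame(mz = 786.6 + (0:2) * 1.0033548,
                     intensity = c(1000, 500, 150), index = 1:3)
  expect_identical(assign_charge(cen1, 786.6), 1L)
  # isolated singleton: undetermined
  expect_identical(assign_charge(data.frame(mz = 700, intensity = 1,
                                            index = 1), 700), NA_integer_)
})

test_that("species matching honours the ppm gate and reports signed error", {
  space <- default_species_space()
  cen <- data.frame(mz = c(727.509, 727.509 + 1.0033548 / 2),
                    intensity = c(900, 800), index = 1:2)
  ann <- match_species(cen, space, noise_level = 1)
  hit <- ann[ann$species == "CL(72:4)", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$ppm, -1.5626, tolerance = 1e-2)
  expect_identical(hit$charge, 2L)
  expect_true(hit$detected)
  # tighter tolerance rejects the same centroid
  ann1 <- match_species(cen, space, noise_level = 1, tol_ppm = 1)
  expect_false("CL(72:4)" %in% ann1$species)
  # unsorted space is rejected
  expect_error(match_species(cen, space[rev(seq_len(nrow(space))), ],
                             noise_level = 1), "sorted")
})

test_that("a full synthetic normal-cortex spectrum yields the complete panel
           with high recall and precision", {
  cfg <- small_config(rows = 1, cols = 1, baseline_sd = 1e-6)
  prof <- build_profile("NL_grey")
  set.seed(8)
  s <- render_spectrum(prof, cfg)
  ann <- annotate_spectrum(s, default_species_space())
  det <- ann[ann$detected, ]
  # recall: every panel species is detected
  expect_true(all(prof$species$species %in% det$species))
  # precision: every detected species is in the panel
  expect_true(all(det$species %in% prof$species$species))
  expect_lt(max(abs(det$ppm)), 5)
  # species whose higher-unsaturation neighbour is absent from the panel are
  # free of isotopologue interference and land within 1 ppm
  clean <- c("CL(68:6)", "CL(70:8)", "CL(72:12)", "MLCL(52:3)")
  expect_lt(max(abs(det$ppm[det$species %in% clean])), 1)
})

test_that("detection is monotone in the S/N threshold", {
  cfg <- small_config(rows = 1, cols = 1)
  set.seed(12)
  s <- render_spectrum(build_profile("GBM"), cfg)
  space <- default_species_space()
  dets <- lapply(c(3, 30, 300, 1e9), function(thr) {
    ann <- annotate_spectrum(s, space, snr_threshold = thr)
    ann$species[ann$detected]
  })
  for (i in 2:4) expect_true(all(dets[[i]] %in% dets[[i - 1]]))
  expect_identical(length(dets[[4]]), 0L)
})

test_that("chain assignment filters candidates by fragment evidence and is a
           subset of the combination space", {
  cl724 <- lipid_species("CL", 72, 4)
  ms2 <- data.frame(mz = 281.2486, intensity = 5000)
  ranked <- assign_chains(ms2, cl724)
  expect_identical(ranked$chains[1], "18:1_18:1_18:1_18:1")
  all_combos <- vapply(fa_combinations(72, 4, n_chains = 4), attr,
                       character(1), "label")
  expect_true(all(ranked$chains %in% all_combos))

  cl704 <- lipid_species("CL", 70, 4)
  ms2b <- data.frame(mz = c(255.2330, 281.2486, 279.2330),
                     intensity = c(900, 2700, 900))
  rb <- assign_chains(ms2b, cl704)
  expect_true("18:2_18:1_18:1_16:0" %in% rb$chains)

  expect_identical(nrow(assign_chains(data.frame(mz = numeric(),
                                                 intensity = numeric()),
                                      cl724)), 0L)
})

test_that("isomer ratio is scale-invariant and guards its preconditions", {
  pl <- generate_uvpd_peaklist(2.5, noise_cv = 0.05, seed = 4)
  ions <- attr(pl, "ions")
  r1 <- dbond_ratio(pl, ions$delta9, ions$delta11)
  pl2 <- pl; pl2$intensity <- pl2$intensity * 1e4
  expect_equal(dbond_ratio(pl2, ions$delta9, ions$delta11), r1,
               tolerance = 1e-12)
  expect_error(dbond_ratio(pl, ions$delta9, ions$delta9), "overlap")
  only9 <- pl[pl$mz %in% ions$delta9, ]
  expect_error(dbond_ratio(only9, ions$delta9, ions$delta11), "denominator")
  expect_error(dbond_ratio(pl, numeric(), ions$delta11), "non-empty")
})
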