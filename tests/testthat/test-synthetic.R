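# Tissue profiles, spectrum rendering, imaging generation, UVPD peak lists.

test_that("normal grey matter carries 46 CL and 12 MLCL species in six
           unimodal carbon clusters", {
  p <- build_profile("NL_grey")
  expect_identical(sum(p$species$lipid_class == "CL"), 46L)
  expect_identical(sum(p$species$lipid_class == "MLCL"), 12L)
  expect_equal(sum(p$abundance), 1, tolerance = 1e-12)
  cl <- p$species$lipid_class == "CL"
  expect_identical(sort(unique(p$species$total_carbons[cl])),
                   as.integer(seq(68, 78, 2)))
  # modal species is CL(74:8); within-cluster abundances are unimodal
  expect_identical(p$species$species[cl][which.max(p$abundance[cl])],
                   "CL(74:8)")
  # X = 78 is excluded: its centre species CL(78:12) is the ratio-calibrated
  # abundance and may sit below its cluster neighbours
  for (X in seq(68, 76, 2)) {
    ab <- p$abundance[cl & p$species$total_carbons == X]
    ab <- ab[order(p$species$total_double_bonds[cl & p$species$total_carbons == X])]
    signs <- sign(diff(ab))
    expect_lte(sum(diff(signs[signs != 0]) != 0), 1)  # at most one turning point
  }
})

test_that("tumor profiles lose long-chain species and white matter has no CL", {
  g <- build_profile("GBM")
  expect_false("CL(78:12)" %in% g$species$species)
  expect_false("CL(76:10)" %in% g$species$species)
  cl <- g$species$lipid_class == "CL"
  expect_identical(g$species$species[cl][which.max(g$abundance[cl])],
                   "CL(72:6)")
  w <- build_profile("NL_white")
  expect_identical(length(w$abundance), 0L)
  expect_identical(w$attenuation, 0)
  n <- build_profile("necrotic")
  expect_equal(n$attenuation / g$attenuation, 0.2, tolerance = 1e-12)
  expect_error(build_profile("cerebellum"))
})

test_that("profiles are calibrated so the analytic expected chain ratio
           equals the class target", {
  targets <- c(NL_grey = 0.48, AST1 = 0.05, AST2 = 0.10, GBM = 0)
  for (cl in names(targets)) {
    p <- build_profile(cl)
    expect_equal(p$expected_ratio, unname(targets[cl]), tolerance = 1e-12)
    expect_equal(expected_chain_ratio(p), unname(targets[cl]),
                 tolerance = 1e-4)
  }
})

test_that("a single rendered species peaks within 5 ppm of its exact m/z", {
  cfg <- small_config(rows = 1, cols = 1)
  prof <- single_species_profile("CL", 72, 4)
  set.seed(99)
  s <- render_spectrum(prof, cfg)
  apex <- s$mz[which.max(s$intensity)]
  expect_lt(abs(ppm_error(apex, 727.51013684)), 5)
  expect_false(is.unsorted(s$mz))
})

test_that("rendering is deterministic under a fixed RNG state and empty
           profiles give noise-only spectra", {
  cfg <- small_config(rows = 1, cols = 1)
  prof <- build_profile("NL_white")
  set.seed(5); s1 <- render_spectrum(prof, cfg)
  set.seed(5); s2 <- render_spectrum(prof, cfg)
  expect_identical(s1$intensity, s2$intensity)
  expect_lt(max(abs(s1$intensity)), 6 * cfg$baseline_sd)
})

test_that("imaging datasets are reproducible and carry coherent truth
           tables", {
  lay <- matrix(rep(c("NL_grey", "GBM"), each = 2), 2, 2)
  cfg <- generator_config(rows = 2, cols = 2, layout = lay,
                          axis_range = c(700, 760), seed = 77)
  a <- generate_imaging_dataset(cfg)
  b <- generate_imaging_dataset(cfg)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$truth, b$truth)
  expect_identical(nrow(a$truth$pixels), 4L)
  expect_setequal(unique(a$truth$abundances$tissue_class), c("NL_grey", "GBM"))
  # row-major pixel labels agree with the layout
  expect_identical(a$truth$pixels$label, as.vector(t(lay)))
  # seed change alters spectra but not truth
  cfg2 <- generator_config(rows = 2, cols = 2, layout = lay,
                           axis_range = c(700, 760), seed = 78)
  c2 <- generate_imaging_dataset(cfg2)
  expect_false(identical(a$dataset$intensities, c2$dataset$intensities))
  expect_identical(a$truth, c2$truth)
  expect_error(generate_imaging_dataset(
    generator_config(rows = 3, cols = 2, layout = lay)), "layout")
})

test_that("abundance jitter renormalizes and vanishes at zero CV", {
  p <- build_profile("NL_grey")
  set.seed(3)
  j <- jitter_profile(p, cv = 0.15)
  expect_equal(sum(j$abundance), 1, tolerance = 1e-12)
  expect_false(identical(j$abundance, p$abundance))
  expect_identical(jitter_profile(p, cv = 0)$abundance, p$abundance)
})

test_that("UVPD peak lists encode the requested isomer ratio", {
  pl <- generate_uvpd_peaklist(1.0, noise_cv = 0, seed = 1)
  ions <- attr(pl, "ions")
  expect_equal(dbond_ratio(pl, ions$delta9, ions$delta11), 1.0,
               tolerance = 1e-12)
  expect_error(generate_uvpd_peaklist(0), "ratio")
  # simulation oracle: the replicate mean recovers the target ratio
  set.seed(11)
  reps <- replicate(200, {
    p <- generate_uvpd_peaklist(2.5, noise_cv = 0.05)
    dbond_ratio(p, attr(p, "ions")$delta9, attr(p, "ions")$delta11)
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 2.5), 4 * se + 0.01)
})
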