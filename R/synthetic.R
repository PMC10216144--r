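# Synthetic DESI-FAIMS-like imaging data generator.
#
# Emulates the statistical structure of negative-ion CL/MLCL imaging profiles
# of normal cortex, astrocytoma and glioblastoma tissue: carbon-number
# clusters of doubly charged species, class-specific chain-length ratios,
# white-matter CL suppression and necrotic attenuation.

.TISSUE_CLASSES <- c("NL_grey", "NL_white", "AST1", "AST2", "GBM",
                     "infiltrating", "necrotic")

# Expected long/short chain-length ratio (CL(78:12) over CL(72:8)) each class
# profile is calibrated to. GBM carries no CL(78:12) at all (the species is
# not detected in glioblastoma), so its expected ratio is 0.
.CLASS_RATIO <- c(NL_grey = 0.48, AST1 = 0.05, AST2 = 0.10, GBM = 0)

# discretized Gaussian weight
.gw <- function(x, center, sd) exp(-(x - center)^2 / (2 * sd^2))

# CL panel description per tissue class: for each carbon-number cluster a
# double-bond range and within-cluster mode. NL grey matter carries 46 CL
# species over six clusters (X = 68..78); GBM loses the two long-chain
# clusters and its modal cluster shifts to CL(72:6).
.cl_panel_def <- function(tissue_class) {
  nl <- list(
    list(X = 68, Y = 2:6,  center = 4),
    list(X = 70, Y = 2:8,  center = 5),
    list(X = 72, Y = 4:12, center = 8),
    list(X = 74, Y = 4:12, center = 8),
    list(X = 76, Y = 6:14, center = 10),
    list(X = 78, Y = 8:14, center = 12)
  )
  gbm <- list(
    list(X = 68, Y = 2:6,  center = 4),
    list(X = 70, Y = 2:8,  center = 5),
    list(X = 72, Y = 4:12, center = 6),
    list(X = 74, Y = 4:12, center = 7)
  )
  switch(tissue_class,
         NL_grey = , AST1 = , AST2 = nl,
         GBM = , necrotic = gbm,
         stop("no CL panel for class ", tissue_class))
}

.mlcl_panel_def <- function() {
  list(
    list(X = 52, Y = 1:3, center = 2),
    list(X = 54, Y = 3:5, center = 4),
    list(X = 56, Y = 4:6, center = 5),
    list(X = 58, Y = 7:9, center = 8)
  )
}

.panel_weights <- function(defs, x_center, x_sd = 4, y_sd = 2) {
  rows <- lapply(defs, function(d) {
    w <- .gw(d$Y, d$center, y_sd) * .gw(d$X, x_center, x_sd)
    data.frame(total_carbons = d$X, total_double_bonds = d$Y, weight = w)
  })
  do.call(rbind, rows)
}

#' Tissue-class CL/MLCL abundance profile
#'
#' Builds the relative-abundance profile a synthetic pixel of the given
#' tissue class is rendered from. Normal grey matter carries 46 CL species in
#' six carbon-number clusters (X = 68..78, unimodal within each cluster, modal
#' species CL(74:8)) plus 12 MLCL species; glioblastoma loses the long-chain
#' clusters (CL(76:10) and CL(78:12) absent) and its mode shifts to CL(72:6);
#' astrocytoma grades 1/2 keep the normal panel at reduced abundance. The
#' abundances of CL(78:12) and CL(72:8) are calibrated so their expected S/N
#' ratio equals the class target (0.48 NL, 0.05 AST1, 0.10 AST2; 0 for GBM,
#' where CL(78:12) is absent). White matter carries no CL signal at all;
#' necrotic tissue is the GBM profile attenuated to 20%.
#'
#' @param tissue_class one of `"NL_grey"`, `"NL_white"`, `"AST1"`, `"AST2"`,
#'   `"GBM"`, `"infiltrating"`, `"necrotic"`.
#' @param resolving_power resolving power the calibration assumes when
#'   accounting for isotopologue overlap between neighbouring species
#'   (default 70,000, the acquisition value).
#' @return Object of class `tissue_profile`: list with `tissue_class`,
#'   `species` (a [enumerate_cl_space()]-style table), `abundance` (relative
#'   abundances summing to 1, or all zero for white matter), `attenuation`
#'   (overall signal multiplier applied after normalization) and
#'   `expected_ratio` (the calibrated long/short target, NA where undefined).
#' @export
build_profile <- function(tissue_class, resolving_power = 70000) {
  tissue_class <- match.arg(tissue_class, .TISSUE_CLASSES)
  atten <- c(NL_grey = 1.0, NL_white = 0, AST1 = 0.55, AST2 = 0.55,
             GBM = 0.35, infiltrating = 0.5, necrotic = 0.35 * 0.2)[[tissue_class]]

  if (tissue_class == "NL_white") {
    sp <- enumerate_cl_space(68, 68, 2, 2, "CL")[0, ]
    return(structure(list(tissue_class = tissue_class, species = sp,
                          abundance = numeric(0), attenuation = 0,
                          expected_ratio = NA_real_),
                     class = "tissue_profile"))
  }
  if (tissue_class == "infiltrating") {
    # mixture of normal-like and pure-tumor profiles: long-chain CL present
    # at higher relative abundance than in pure GBM
    nl <- build_profile("NL_grey"); gb <- build_profile("GBM")
    key <- function(p) p$species$species
    all_sp <- nl$species[order(nl$species$mz), ]
    ab <- 0.5 * nl$abundance[match(all_sp$species, key(nl))]
    gb_ab <- gb$abundance[match(all_sp$species, key(gb))]
    ab <- ab + 0.5 * ifelse(is.na(gb_ab), 0, gb_ab)
    ab <- ab / sum(ab)
    return(structure(list(tissue_class = tissue_class, species = all_sp,
                          abundance = ab, attenuation = atten,
                          expected_ratio = unname(ab[all_sp$species == "CL(78:12)"] /
                                                  ab[all_sp$species == "CL(72:8)"])),
                     class = "tissue_profile"))
  }

  base_class <- if (tissue_class == "necrotic") "GBM" else tissue_class
  x_center <- if (base_class %in% c("GBM")) 72 else 74
  cl_w <- .panel_weights(.cl_panel_def(base_class), x_center = x_center)
  cl_w$lipid_class <- "CL"

  ml_w <- .panel_weights(.mlcl_panel_def(), x_center = 55, x_sd = 3, y_sd = 1.5)
  ml_w$lipid_class <- "MLCL"
  # MLCL carries ~12% of the summed CL abundance
  ml_w$weight <- ml_w$weight * (0.12 * sum(cl_w$weight) / sum(ml_w$weight))

  w <- rbind(cl_w, ml_w)
  target <- .CLASS_RATIO[[base_class]]

  # astrocytoma grades: deplete the long-chain clusters (X >= 76) in
  # proportion to the class ratio target, the profile signature the ratio
  # statistic quantifies
  if (base_class %in% c("AST1", "AST2")) {
    idx <- w$lipid_class == "CL" & w$total_carbons >= 76
    w$weight[idx] <- w$weight[idx] * target / .CLASS_RATIO[["NL_grey"]]
  }

  rows <- lapply(seq_len(nrow(w)), function(i) {
    sp <- lipid_species(w$lipid_class[i], w$total_carbons[i],
                        w$total_double_bonds[i])
    data.frame(lipid_class = sp$lipid_class, total_carbons = sp$total_carbons,
               total_double_bonds = sp$total_double_bonds,
               species = species_label(sp),
               formula = format(sp$neutral_formula),
               neutral_mass = sp$neutral_mass, mz = sp$mz_2minus,
               stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, rows)
  class(sp) <- c("cl_species_table", "data.frame")

  # calibrate the long/short pair to the class ratio target on the expected
  # *measured* peak height: at resolving power 70,000 the M+2 isotopologue of
  # the Y+1 neighbour merges into a species' monoisotopic peak, so the
  # abundance of CL(78:12) is solved from
  #   target = H(78:12) / H(72:8),  H = analytic profile height at the
  # species' exact m/z including all envelope contributions
  i_long <- which(sp$species == "CL(78:12)")
  i_short <- which(sp$species == "CL(72:8)")
  if (length(i_long) == 1 && length(i_short) == 1) {
    # fixed-point solve: the measured height is the apex of the merged local
    # profile, which moves with the species abundance, so iterate
    h_short <- .apex_height(sp, w$weight, sp$mz[i_short], resolving_power)
    w0 <- w$weight; w0[i_long] <- 0
    c_long <- .apex_height(sp, w0, sp$mz[i_long], resolving_power)
    w$weight[i_long] <- max(0, target * h_short - c_long)
    for (it in 1:12) {
      h_long <- .apex_height(sp, w$weight, sp$mz[i_long], resolving_power)
      ratio <- h_long / h_short
      if (ratio <= 0 || abs(ratio / target - 1) < 1e-6) break
      w$weight[i_long] <- max(0, w$weight[i_long] * target / ratio)
    }
  }

  ord <- order(sp$mz)
  sp <- sp[ord, ]; rownames(sp) <- NULL
  ab <- w$weight[ord] / sum(w$weight)

  exp_ratio <- if (length(i_short) == 1) {
    if (length(i_long) == 1) target else 0   # long-chain species absent
  } else NA_real_
  structure(list(tissue_class = tissue_class, species = sp, abundance = ab,
                 attenuation = atten, expected_ratio = exp_ratio),
            class = "tissue_profile")
}

# analytic expected profile height at target_mz: sum of Gaussian peak
# contributions (FWHM = m/z / R) of every isotopologue of every species
.height_at <- function(species_df, weights, target_mz, resolving_power,
                       k = 4) {
  envs <- .profile_envelopes(list(species = species_df), k)
  h <- 0
  for (i in seq_along(weights)) {
    if (weights[i] <= 0) next
    env <- envs[[i]]
    sdv <- (env$mz / resolving_power) / (2 * sqrt(2 * log(2)))
    h <- h + weights[i] *
      sum(env$abundance * exp(-(env$mz - target_mz)^2 / (2 * sdv^2)))
  }
  h
}

# expected apex height near mz0: the local maximum of the noise-free profile
# within +/- 1.5 peak-sigma of the species' exact m/z (what a peak picker
# centroiding the merged local profile reports)
.apex_height <- function(species_df, weights, mz0, resolving_power, k = 4) {
  sdv <- (mz0 / resolving_power) / (2 * sqrt(2 * log(2)))
  grid <- seq(mz0 - 1.5 * sdv, mz0 + 1.5 * sdv, length.out = 61)
  envs <- .profile_envelopes(list(species = species_df), k)
  y <- numeric(length(grid))
  for (i in seq_along(weights)) {
    if (weights[i] <= 0) next
    env <- envs[[i]]
    for (j in seq_len(nrow(env))) {
      if (abs(env$mz[j] - mz0) > 8 * sdv) next
      sj <- (env$mz[j] / resolving_power) / (2 * sqrt(2 * log(2)))
      y <- y + weights[i] * env$abundance[j] *
        exp(-(grid - env$mz[j])^2 / (2 * sj^2))
    }
  }
  max(y)
}

#' Analytic expected chain-length ratio of a profile
#'
#' The noise-free expected ratio of measured peak heights at the long- and
#' short-chain species' exact m/z, including isotope-envelope contributions
#' from every species in the panel (at the given resolving power a
#' neighbouring species' M+2 isotopologue merges into a monoisotopic peak).
#' For a calibrated profile this equals the class target.
#'
#' @param profile a [build_profile()] result.
#' @param resolving_power instrument resolving power (default 70,000).
#' @param long_species,short_species species labels.
#' @return Expected height ratio (0 when the long species and its
#'   interferents are absent).
#' @export
expected_chain_ratio <- function(profile, resolving_power = 70000,
                                 long_species = "CL(78:12)",
                                 short_species = "CL(72:8)") {
  stopifnot(inherits(profile, "tissue_profile"))
  sp <- profile$species
  if (!length(profile$abundance)) return(NA_real_)
  mz_l <- sp$mz[sp$species == long_species]
  mz_s <- sp$mz[sp$species == short_species]
  if (!length(mz_s)) return(NA_real_)
  hs <- .apex_height(sp, profile$abundance, mz_s, resolving_power)
  if (!length(mz_l)) return(0)
  .apex_height(sp, profile$abundance, mz_l, resolving_power) / hs
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("<tissue_profile> %s: %d CL, %d MLCL species, attenuation %.2f\n",
              x$tissue_class, sum(x$species$lipid_class == "CL"),
              sum(x$species$lipid_class == "MLCL"), x$attenuation))
  invisible(x)
}

#' Generator configuration
#'
#' Defaults emulate the acquisition described for the DESI-FAIMS platform:
#' negative mode, resolving power 70,000, instrument range m/z 100-1500.
#' The rendered profile axis covers `axis_range` (default m/z 560-800, the
#' FAIMS-transmitted CL/MLCL window) with `oversampling` samples per peak
#' width; rendering the full instrument range at this resolving power would
#' carry no additional signal.
#'
#' @param rows,cols pixel grid dimensions.
#' @param layout character matrix (`rows` x `cols`) of tissue-class labels
#'   (see [region_layout()]); default all `"NL_grey"`.
#' @param resolving_power peak FWHM is m/z divided by this (default 70,000).
#' @param mz_range instrument acquisition range (metadata and validity
#'   bounds), default `c(100, 1500)`.
#' @param axis_range m/z span of the rendered profile axis.
#' @param oversampling axis samples per peak FWHM (default 4).
#' @param baseline_mean,baseline_sd Gaussian baseline noise parameters.
#' @param amplitude peak height of a species at relative abundance 1 and
#'   attenuation 1, in intensity units (so S/N scales as
#'   `amplitude * abundance / baseline_sd`).
#' @param n_isotopologues isotope envelope peaks rendered per species.
#' @param patient_cv between-patient log-normal coefficient of variation on
#'   species abundances (default 0.15).
#' @param noise_windows list of m/z intervals guaranteed signal-free, used by
#'   noise estimation (default m/z 630-688, between the MLCL and CL regions).
#' @param seed integer; fully determines generator output.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(rows = 20, cols = 20, layout = NULL,
                             resolving_power = 70000,
                             mz_range = c(100, 1500),
                             axis_range = c(560, 800),
                             oversampling = 4,
                             baseline_mean = 0, baseline_sd = 1,
                             amplitude = 20000,
                             n_isotopologues = 4,
                             patient_cv = 0.15,
                             noise_windows = list(c(630, 688)),
                             seed = 1L) {
  if (is.null(layout)) layout <- matrix("NL_grey", rows, cols)
  stopifnot(resolving_power > 0, oversampling >= 3,
            axis_range[1] < axis_range[2],
            mz_range[1] < mz_range[2], baseline_sd >= 0)
  if (!all(dim(layout) == c(rows, cols)))
    stop("layout dimensions must equal (rows, cols)")
  bad <- setdiff(unique(as.vector(layout)), c(.TISSUE_CLASSES, "unassigned"))
  if (length(bad))
    stop("unknown tissue class in layout: ", paste(bad, collapse = ", "))
  structure(list(rows = rows, cols = cols, layout = layout,
                 resolving_power = resolving_power, mz_range = mz_range,
                 axis_range = axis_range, oversampling = oversampling,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 amplitude = amplitude, n_isotopologues = n_isotopologues,
                 patient_cv = patient_cv, noise_windows = noise_windows,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Standard region layouts
#'
#' Pre-built pixel layouts mirroring typical tissue sections: a pure section
#' of one class, a glioblastoma section with pure and infiltrating halves, or
#' a glioblastoma section with viable and necrotic halves.
#'
#' @param type `"pure"`, `"infiltrating"` or `"necrotic"`.
#' @param rows,cols grid dimensions.
#' @param class tissue class for `type = "pure"`.
#' @return Character matrix of labels.
#' @export
region_layout <- function(type = c("pure", "infiltrating", "necrotic"),
                          rows = 20, cols = 20, class = "NL_grey") {
  type <- match.arg(type)
  half <- max(1L, cols %/% 2L)
  m <- matrix("GBM", rows, cols)
  switch(type,
         pure = matrix(class, rows, cols),
         infiltrating = { m[, seq_len(half)] <- "infiltrating"; m },
         necrotic = { m[, seq_len(half)] <- "necrotic"; m })
}

# isotope envelopes for every species of a profile, cached per (species, k)
.envelope_cache <- new.env(parent = emptyenv())
.profile_envelopes <- function(profile, k) {
  lapply(profile$species$formula, function(f) {
    key <- paste0(f, "|", k)
    env <- .envelope_cache[[key]]
    if (is.null(env)) {
      env <- isotope_envelope(parse_formula(f), z = -2L, k = k)
      .envelope_cache[[key]] <- env
    }
    env
  })
}

# shared log-spaced m/z axis: constant relative spacing 1/(oversampling * R)
.build_axis <- function(config) {
  step <- 1 / (config$oversampling * config$resolving_power)
  n <- ceiling(log(config$axis_range[2] / config$axis_range[1]) / log1p(step))
  config$axis_range[1] * (1 + step)^(0:n)
}

#' Render one profile-mode spectrum from a tissue profile
#'
#' Each species contributes its doubly-deprotonated isotope envelope as
#' Gaussian peaks of FWHM = m/z / R; Gaussian baseline noise is added from
#' the configured model. Consumes the current RNG stream, so rendering is
#' reproducible under `set.seed()`.
#'
#' @param profile a [build_profile()] result (optionally abundance-jittered).
#' @param config a [generator_config()].
#' @param axis optional precomputed axis (shared across pixels).
#' @return A profile-mode [mass_spectrum()].
#' @export
render_spectrum <- function(profile, config, axis = NULL) {
  stopifnot(inherits(profile, "tissue_profile"),
            inherits(config, "generator_config"))
  if (is.null(axis)) axis <- .build_axis(config)
  n <- length(axis)
  y <- numeric(n)
  # index arithmetic on the log-spaced axis (axis[i+1] = a0 * (1+step)^i)
  step <- log1p(1 / (config$oversampling * config$resolving_power))
  a0 <- axis[1]
  idx_of <- function(m) log(m / a0) / step + 1
  if (length(profile$abundance)) {
    envs <- .profile_envelopes(profile, config$n_isotopologues)
    scale <- config$amplitude * profile$attenuation
    for (i in seq_along(profile$abundance)) {
      a <- profile$abundance[i]
      if (a <= 0) next
      env <- envs[[i]]
      for (j in seq_len(nrow(env))) {
        mu <- env$mz[j]
        if (mu < axis[1] || mu > axis[n]) next
        sdv <- (mu / config$resolving_power) / (2 * sqrt(2 * log(2)))
        lo <- max(1L, ceiling(idx_of(mu - 6 * sdv)))
        hi <- min(n, floor(idx_of(mu + 6 * sdv)))
        if (hi < lo) next
        idx <- lo:hi
        y[idx] <- y[idx] +
          scale * a * env$abundance[j] * exp(-(axis[idx] - mu)^2 / (2 * sdv^2))
      }
    }
  }
  y <- y + stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  structure(list(mz = axis, intensity = y, mode = "profile"),
            class = "mass_spectrum")
}

#' Generate a synthetic imaging dataset with ground truth
#'
#' One spectrum per pixel, rendered from the pixel's region profile; pixel
#' order is row-major. The RNG is seeded from `config$seed`, so output is
#' fully reproducible. Returns the dataset together with truth tables: the
#' per-pixel region label, per-region species abundances and the calibrated
#' expected chain-length ratios.
#'
#' @param config a [generator_config()].
#' @param profiles optional named list of [build_profile()] results overriding
#'   the defaults (e.g. abundance-jittered patient profiles).
#' @return List of class `msi_truth` with elements `dataset` (an
#'   [msi_dataset()]), `mask` (a character label matrix), `truth` (list of
#'   data frames `pixels`, `abundances`, `expected_ratios`).
#' @export
generate_imaging_dataset <- function(config = generator_config(),
                                     profiles = NULL) {
  stopifnot(inherits(config, "generator_config"))
  labels <- unique(as.vector(config$layout))
  if (is.null(profiles)) profiles <- list()
  for (lb in setdiff(labels, names(profiles)))
    profiles[[lb]] <- build_profile(lb)

  set.seed(config$seed)
  axis <- .build_axis(config)
  npx <- config$rows * config$cols
  ints <- matrix(0, nrow = npx, ncol = length(axis))
  coords <- data.frame(row = rep(0:(config$rows - 1), each = config$cols),
                       col = rep(0:(config$cols - 1), times = config$rows))
  for (p in seq_len(npx)) {
    lb <- config$layout[coords$row[p] + 1L, coords$col[p] + 1L]
    sp <- render_spectrum(profiles[[lb]], config, axis = axis)
    ints[p, ] <- sp$intensity
  }
  ds <- msi_dataset(mz = axis, intensities = ints, rows = config$rows,
                    cols = config$cols,
                    metadata = list(polarity = "negative",
                                    resolving_power = config$resolving_power,
                                    mz_range = config$mz_range))
  ab <- do.call(rbind, lapply(labels, function(lb) {
    pr <- profiles[[lb]]
    if (!length(pr$abundance)) return(NULL)
    data.frame(tissue_class = lb, species = pr$species$species,
               mz = pr$species$mz, abundance = pr$abundance,
               attenuation = pr$attenuation, stringsAsFactors = FALSE)
  }))
  ratios <- data.frame(
    tissue_class = labels,
    expected_ratio = vapply(labels, function(lb) profiles[[lb]]$expected_ratio,
                            numeric(1)),
    stringsAsFactors = FALSE
  )
  truth <- list(
    pixels = data.frame(coords, label = as.vector(t(config$layout)),
                        stringsAsFactors = FALSE),
    abundances = ab,
    expected_ratios = ratios
  )
  structure(list(dataset = ds, mask = config$layout, truth = truth),
            class = "msi_truth")
}

#' Apply between-patient abundance jitter to a profile
#'
#' Multiplies each species abundance by an independent log-normal factor with
#' the configured coefficient of variation, then renormalizes. Consumes the
#' RNG stream.
#'
#' @param profile a [build_profile()] result.
#' @param cv coefficient of variation of the multiplicative jitter.
#' @return A `tissue_profile` with jittered abundances. The calibrated
#'   `expected_ratio` is updated to the jittered value.
#' @export
jitter_profile <- function(profile, cv = 0.15) {
  stopifnot(inherits(profile, "tissue_profile"))
  if (!length(profile$abundance) || cv <= 0) return(profile)
  sdlog <- sqrt(log(1 + cv^2))
  f <- stats::rlnorm(length(profile$abundance), -sdlog^2 / 2, sdlog)
  ab <- profile$abundance * f
  profile$abundance <- ab / sum(ab)
  # expected_ratio keeps the class calibration target: jitter is mean-
  # preserving, so the cohort mean still recovers it
  profile
}

#' Simulate a UVPD diagnostic-ion peak list with known isomer ratio
#'
#' Emits centroids at the diagnostic fragment pairs of FA 18:1 delta-9 and
#' delta-11 with summed intensities in the requested ratio, under
#' multiplicative log-normal noise.
#'
#' @param ratio_delta9_to_delta11 target ratio of summed delta-9 to summed
#'   delta-11 diagnostic intensity (> 0).
#' @param n_ions_per_isomer number of diagnostic ions used per isomer
#'   (1 or 2; default 2, the full flanking pair).
#' @param noise_cv coefficient of variation of multiplicative intensity noise
#'   (0 = noiseless).
#' @param seed optional integer seed (NULL = use current RNG stream).
#' @param base_intensity summed delta-11 intensity before noise.
#' @return Centroid peak list: data.frame with `mz`, `intensity`, and the
#'   attribute `ions` (list with `delta9`, `delta11` diagnostic m/z vectors).
#' @export
generate_uvpd_peaklist <- function(ratio_delta9_to_delta11,
                                   n_ions_per_isomer = 2,
                                   noise_cv = 0.05, seed = NULL,
                                   base_intensity = 1000) {
  if (ratio_delta9_to_delta11 <= 0)
    stop("isomer ratio must be > 0")
  stopifnot(n_ions_per_isomer %in% 1:2)
  if (!is.null(seed)) set.seed(seed)
  d9 <- diagnostic_pair_mz(fatty_acyl(18, 1, db_positions = 9))[seq_len(n_ions_per_isomer)]
  d11 <- diagnostic_pair_mz(fatty_acyl(18, 1, db_positions = 11))[seq_len(n_ions_per_isomer)]
  jit <- function(n) {
    if (noise_cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  i9 <- ratio_delta9_to_delta11 * base_intensity / length(d9) * jit(length(d9))
  i11 <- base_intensity / length(d11) * jit(length(d11))
  out <- data.frame(mz = c(d9, d11), intensity = c(i9, i11))
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  attr(out, "ions") <- list(delta9 = d9, delta11 = d11)
  out
}
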