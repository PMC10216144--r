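# Peak picking, charge inference, ppm matching, chain assignment, isomer
# ratios.

#' Robust noise estimate from signal-free windows
#'
#' 1.4826 times the median absolute deviation of the profile intensities
#' inside the configured windows: a robust estimate of the baseline standard
#' deviation that a stray peak inflates by less than a factor of two.
#'
#' @param spectrum a profile-mode [mass_spectrum()].
#' @param windows list of numeric length-2 m/z intervals known to be
#'   signal-free.
#' @return Noise level (intensity units); 0 for a constant spectrum.
#' @export
estimate_noise <- function(spectrum, windows = list(c(630, 688))) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (!length(windows)) stop("at least one noise window is required")
  idx <- unlist(lapply(windows, function(w) {
    which(spectrum$mz >= w[1] & spectrum$mz <= w[2])
  }))
  if (!length(idx)) stop("noise window(s) contain no samples")
  x <- spectrum$intensity[idx]
  stats::mad(x, constant = 1.4826)
}

#' Pick and centroid peaks from a profile spectrum
#'
#' Local maxima exceeding `k` times the noise level are centroided by a
#' three-point parabolic fit through the log intensities at the apex (exact
#' for a Gaussian peak, valid on a non-uniform axis); if the fitted vertex
#' falls outside the bracketing samples, or a neighbour is non-positive, the
#' apex sample is used as-is.
#'
#' @param spectrum profile-mode [mass_spectrum()].
#' @param noise_level noise estimate, e.g. from [estimate_noise()] (> 0).
#' @param k detection multiple of the noise level (default 3).
#' @return Centroid table sorted by m/z: data.frame with `mz`, `intensity`
#'   (peak height) and `index` (apex sample index).
#' @export
pick_peaks <- function(spectrum, noise_level, k = 3) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (noise_level <= 0) stop("noise_level must be > 0")
  y <- spectrum$intensity; x <- spectrum$mz
  n <- length(y)
  if (n < 3) return(data.frame(mz = numeric(), intensity = numeric(),
                               index = integer()))
  i <- 2:(n - 1)
  apex <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > k * noise_level]
  if (!length(apex)) return(data.frame(mz = numeric(), intensity = numeric(),
                                       index = integer()))
  mzc <- x[apex]; intc <- y[apex]
  ok <- y[apex - 1] > 0 & y[apex + 1] > 0 & y[apex] > 0
  if (any(ok)) {
    a <- apex[ok]
    l <- log(y[a - 1]); c0 <- log(y[a]); r <- log(y[a + 1])
    d12 <- x[a] - x[a - 1]; d23 <- x[a + 1] - x[a]
    den <- (l - c0) * d23 + (r - c0) * d12
    vx <- x[a] + ifelse(abs(den) > 0,
                        0.5 * ((l - c0) * d23^2 - (r - c0) * d12^2) / den, 0)
    inside <- vx >= x[a - 1] & vx <= x[a + 1] & abs(den) > 0
    mzc[ok][inside] <- vx[inside]
    # the apex sample is reported as the height: at >= 3 samples per FWHM it
    # differs negligibly from the fitted vertex and is robust to noise
  }
  out <- data.frame(mz = mzc, intensity = intc, index = apex)
  out[order(out$mz), , drop = FALSE]
}

#' Infer charge state from isotopologue spacing
#'
#' For a seed centroid, looks for a higher-m/z isotopologue partner at the
#' expected carbon-13 spacing 1.0033548/z, trying z = 3, 2, 1 in that order
#' (smallest spacing first, so that a doubly charged envelope is not
#' mis-called singly charged from its M+2 peak). The match tolerance is
#' `tol_ppm` parts per million of the seed m/z. Negative-ion polarity is
#' implied; the magnitude is returned.
#'
#' @param centroids centroid table from [pick_peaks()].
#' @param seed_mz m/z of the centroid whose charge is wanted.
#' @param tol_ppm spacing tolerance in ppm of the seed m/z (default 10).
#' @return Integer charge magnitude (1, 2 or 3), or `NA_integer_` when no
#'   isotopologue partner matches ("undetermined").
#' @export
assign_charge <- function(centroids, seed_mz, tol_ppm = 10) {
  stopifnot(is.data.frame(centroids), length(seed_mz) == 1L)
  tol <- tol_ppm * 1e-6 * seed_mz
  higher <- centroids$mz[centroids$mz > seed_mz + tol]
  if (!length(higher)) return(NA_integer_)
  for (z in c(3L, 2L, 1L)) {
    expect <- seed_mz + 1.0033548 / z
    if (any(abs(higher - expect) <= tol)) return(z)
  }
  NA_integer_
}

# vectorized charge assignment for all centroids at once; same semantics as
# assign_charge() applied to each centroid (z tried in order 3, 2, 1)
.assign_charges <- function(centroids, tol_ppm = 10) {
  mz <- centroids$mz
  n <- length(mz)
  z <- rep(NA_integer_, n)
  if (n < 2) return(z)
  stopifnot(!is.unsorted(mz))
  tol <- tol_ppm * 1e-6 * mz
  for (zc in c(3L, 2L, 1L)) {
    target <- mz + 1.0033548 / zc
    lo <- findInterval(target - tol, mz)
    hi <- findInterval(target + tol, mz)
    hit <- is.na(z) & hi > lo
    z[hit] <- zc
  }
  z
}

#' Match doubly charged centroids to CL/MLCL species
#'
#' Each centroid whose inferred charge is 2 (or whose charge is undetermined)
#' is matched to the species minimizing the absolute ppm error within
#' `tol_ppm`; ties are broken by class priority CL before MLCL, then lower
#' double-bond count. One annotation per species is kept (the highest-S/N
#' centroid wins). A species is `detected` when its S/N reaches
#' `snr_threshold` and the charge-2 signature was confirmed by an
#' isotopologue partner; charge-undetermined matches are annotated but never
#' detected.
#'
#' @param centroids centroid table from [pick_peaks()].
#' @param space species table from [enumerate_cl_space()] (sorted by `mz`).
#' @param noise_level noise estimate used to convert height to S/N.
#' @param tol_ppm m/z match tolerance in ppm (default 5).
#' @param snr_threshold detection threshold on S/N (default 3).
#' @param charge_tol_ppm spacing tolerance for [assign_charge()].
#' @return Annotation table: data.frame with `species`, `lipid_class`,
#'   `total_carbons`, `total_double_bonds`, `exact_mz`, `measured_mz`, `ppm`,
#'   `charge`, `snr`, `detected`.
#' @export
match_species <- function(centroids, space, noise_level, tol_ppm = 5,
                          snr_threshold = 3, charge_tol_ppm = 10) {
  stopifnot(is.data.frame(centroids), inherits(space, "data.frame"))
  if (is.unsorted(space$mz)) stop("species table must be sorted by mz")
  empty <- data.frame(species = character(), lipid_class = character(),
                      total_carbons = integer(), total_double_bonds = integer(),
                      exact_mz = numeric(), measured_mz = numeric(),
                      ppm = numeric(), charge = integer(), snr = numeric(),
                      detected = logical(), stringsAsFactors = FALSE)
  if (!nrow(centroids) || !nrow(space)) return(empty)
  charge <- .assign_charges(centroids, charge_tol_ppm)
  cand <- which(is.na(charge) | charge == 2L)
  if (!length(cand)) return(empty)
  mzc <- centroids$mz[cand]
  # nearest species by |ppm|: compare the two bracketing entries of the
  # sorted species table; ties broken CL before MLCL, then fewer double bonds
  i_lo <- pmax(findInterval(mzc, space$mz), 1L)
  i_hi <- pmin(i_lo + 1L, nrow(space))
  key <- function(i) {
    p <- abs(ppm_error(mzc, space$mz[i]))
    cls <- match(space$lipid_class[i], c("CL", "MLCL"))
    list(p = p, k = p * 1e6 + cls * 1e-3 + space$total_double_bonds[i] * 1e-6)
  }
  klo <- key(i_lo); khi <- key(i_hi)
  s <- ifelse(klo$k <= khi$k, i_lo, i_hi)
  pp <- ppm_error(mzc, space$mz[s])
  keep <- abs(pp) <= tol_ppm
  if (!any(keep)) return(empty)
  s <- s[keep]; ci <- cand[keep]; pp <- pp[keep]
  snr <- centroids$intensity[ci] / noise_level
  out <- data.frame(
    species = space$species[s], lipid_class = space$lipid_class[s],
    total_carbons = space$total_carbons[s],
    total_double_bonds = space$total_double_bonds[s],
    exact_mz = space$mz[s], measured_mz = centroids$mz[ci], ppm = pp,
    charge = charge[ci], snr = snr,
    detected = !is.na(charge[ci]) & charge[ci] == 2L & snr >= snr_threshold,
    stringsAsFactors = FALSE
  )
  # one annotation per species: highest S/N wins
  out <- out[order(out$species, -out$snr), ]
  out <- out[!duplicated(out$species), ]
  out <- out[order(out$exact_mz), ]
  rownames(out) <- NULL
  out
}

#' Annotate one profile spectrum end to end
#'
#' Noise estimation, peak picking, charge inference and ppm matching in one
#' call.
#'
#' @param spectrum profile-mode [mass_spectrum()].
#' @param space species table from [enumerate_cl_space()].
#' @param noise_windows signal-free windows for [estimate_noise()].
#' @param ... passed to [match_species()] (`tol_ppm`, `snr_threshold`,
#'   `charge_tol_ppm`).
#' @return Annotation table (see [match_species()]).
#' @export
annotate_spectrum <- function(spectrum, space,
                              noise_windows = list(c(630, 688)), ...) {
  noise <- estimate_noise(spectrum, noise_windows)
  if (noise <= 0) stop("noise estimate is not positive; cannot form S/N")
  cen <- pick_peaks(spectrum, noise)
  match_species(cen, space, noise_level = noise, ...)
}

#' Rank acyl-chain combinations against MS2 fragment evidence
#'
#' Candidate chain multisets from [fa_combinations()] are filtered to those
#' whose every fatty acid carboxylate anion m/z matches an MS2 centroid
#' within `tol_ppm`, then ranked by the summed intensity of the matched
#' fragments (counting chain multiplicity).
#'
#' @param ms2_centroids centroid peak list: data.frame with `mz`, `intensity`.
#' @param species a [lipid_species()] identified at the MS1 level.
#' @param pool candidate [fatty_acyl()] list (default [default_fa_pool()]).
#' @param tol_ppm fragment match tolerance in ppm (default 10).
#' @return data.frame with `chains` (label such as `"18:1_18:1_18:1_18:1"`)
#'   and `score` (summed matched intensity), ranked by decreasing score.
#'   Zero rows when no candidate is fully supported.
#' @export
assign_chains <- function(ms2_centroids, species, pool = default_fa_pool(),
                          tol_ppm = 10) {
  stopifnot(inherits(species, "lipid_species"))
  n_chains <- if (species$lipid_class == "CL") 4L else 3L
  combos <- fa_combinations(species$total_carbons, species$total_double_bonds,
                            pool = pool, n_chains = n_chains)
  empty <- data.frame(chains = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(combos) || !nrow(ms2_centroids)) return(empty)
  rows <- lapply(combos, function(chains) {
    mzs <- vapply(chains, fa_anion_mz, numeric(1))
    score <- 0
    for (m in mzs) {
      d <- abs(ms2_centroids$mz - m)
      j <- which.min(d)
      if (d[j] > tol_ppm * 1e-6 * m) return(NULL)
      score <- score + ms2_centroids$intensity[j]
    }
    data.frame(chains = attr(chains, "label"), score = score,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$chains), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Double-bond isomer ratio from diagnostic ions
#'
#' Ratio of the summed centroid intensities matched to the isomer-A
#' diagnostic ions over those matched to isomer B (e.g. FA 18:1 delta-9 over
#' delta-11). Scale-invariant in the peak list intensities.
#'
#' @param uvpd_centroids centroid peak list: data.frame with `mz`,
#'   `intensity`.
#' @param isomer_a_ions,isomer_b_ions diagnostic m/z vectors, e.g. from
#'   [diagnostic_pair_mz()]; must be non-empty and disjoint.
#' @param tol_ppm match tolerance in ppm (default 10).
#' @return The intensity ratio (numerator a, denominator b).
#' @export
dbond_ratio <- function(uvpd_centroids, isomer_a_ions, isomer_b_ions,
                        tol_ppm = 10) {
  if (!length(isomer_a_ions) || !length(isomer_b_ions))
    stop("both diagnostic ion sets must be non-empty")
  for (a in isomer_a_ions)
    if (any(abs(isomer_b_ions - a) <= tol_ppm * 1e-6 * a))
      stop("diagnostic ion sets overlap within tolerance")
  summed <- function(ions) {
    s <- 0
    for (m in ions) {
      j <- which(abs(uvpd_centroids$mz - m) <= tol_ppm * 1e-6 * m)
      s <- s + sum(uvpd_centroids$intensity[j])
    }
    s
  }
  den <- summed(isomer_b_ions)
  if (den <= 0) stop("no intensity matched to the denominator isomer ions")
  summed(isomer_a_ions) / den
}
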