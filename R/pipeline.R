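# Reproducible end-to-end entry points: generate / annotate / profile.

#' Default CL + MLCL annotation search space
#'
#' CL over X = 68..80 (even), Y = 2..14 and MLCL over X = 52..58 (even),
#' Y = 1..9, sorted by doubly-deprotonated m/z.
#'
#' @return A `cl_species_table` (see [enumerate_cl_space()]).
#' @export
default_species_space <- function() {
  out <- rbind(enumerate_cl_space(68, 80, 2, 14, "CL"),
               enumerate_cl_space(52, 58, 1, 9, "MLCL"))
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("cl_species_table", "data.frame")
  out
}

#' Annotate every pixel of an imaging dataset
#'
#' @param dataset an [msi_dataset()].
#' @param space species table (default [default_species_space()]).
#' @param noise_windows,... passed to [annotate_spectrum()].
#' @return Long annotation table with `row`, `col` plus the
#'   [match_species()] columns.
#' @export
annotate_dataset <- function(dataset, space = default_species_space(),
                             noise_windows = list(c(630, 688)), ...) {
  mask <- matrix("all", dataset$rows, dataset$cols)
  out <- extract_region_snr(dataset, mask, "all", space,
                            noise_windows = noise_windows, ...)
  out
}

#' Aggregate a per-pixel annotation table by species
#'
#' A species is called detected at the dataset level when it passes the
#' per-pixel detection criteria (S/N threshold plus confirmed charge-2
#' signature) in at least `min_fraction` of the pixels. The fraction guards
#' the dataset-level call against sporadic single-pixel matches from noise
#' peaks or isotopologue interference; genuinely present species pass the
#' per-pixel criteria in nearly every pixel.
#'
#' @param annotations long table from [annotate_dataset()].
#' @param space species table used for annotation.
#' @param min_fraction minimum fraction of pixels with a per-pixel detection
#'   (default 0.05).
#' @param n_pixels total pixel count (default: the `n_pixels` attribute of
#'   `annotations`, else the number of distinct pixels seen).
#' @return One row per species: `n_pixels_annotated`, `n_pixels_detected`,
#'   `median_snr`, `mean_measured_mz` and `mean_ppm` (over detected pixels),
#'   `exact_mz`, `formula`, `detected`.
#' @export
aggregate_annotations <- function(annotations, space = default_species_space(),
                                  min_fraction = 0.05, n_pixels = NULL) {
  if (is.null(n_pixels)) n_pixels <- attr(annotations, "n_pixels")
  if (is.null(n_pixels))
    n_pixels <- nrow(unique(annotations[, c("row", "col")]))
  min_px <- max(1L, ceiling(min_fraction * n_pixels))
  rows <- lapply(seq_len(nrow(space)), function(i) {
    sp <- space$species[i]
    sub <- annotations[annotations$species == sp, , drop = FALSE]
    det <- sub[sub$detected, , drop = FALSE]
    data.frame(
      species = sp, lipid_class = space$lipid_class[i],
      exact_mz = space$mz[i], formula = space$formula[i],
      n_pixels_annotated = nrow(sub), n_pixels_detected = nrow(det),
      median_snr = if (nrow(sub)) stats::median(sub$snr) else 0,
      mean_measured_mz = if (nrow(det)) mean(det$measured_mz) else NA_real_,
      mean_ppm = if (nrow(det)) mean(det$ppm) else NA_real_,
      detected = nrow(det) >= min_px,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Export a species table as tab-separated text
#'
#' Column layout mirrors published CL identification tables: measured m/z,
#' attribution, FA composition (when chain assignments are supplied), exact
#' m/z, ppm error, proposed formula.
#'
#' @param aggregated result of [aggregate_annotations()].
#' @param path output TSV path.
#' @param chains optional named character vector: species label to FA
#'   composition string.
#' @return `path`, invisibly.
#' @export
export_species_table <- function(aggregated, path, chains = NULL) {
  tab <- data.frame(
    measured_mz = round(aggregated$mean_measured_mz, 3),
    attribution = paste0("[", aggregated$species, "-2H]2-"),
    fa_composition = if (is.null(chains)) "" else
      ifelse(is.na(chains[aggregated$species]), "",
             chains[aggregated$species]),
    exact_mz = round_printed(aggregated$exact_mz, 3),
    ppm = round(abs(aggregated$mean_ppm), 1),
    formula = aggregated$formula,
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' One nested configuration drives all pipeline commands. Every tolerance and
#' threshold defaults to its documented value (5 ppm identification
#' tolerance, S/N >= 3 detection, charge spacing tolerance 10 ppm).
#'
#' @return Nested list of class `run_config`.
#' @export
cl_default_config <- function() {
  structure(list(
    generator = list(
      rows = 20, cols = 20, layout_type = "pure", layout_class = "NL_grey",
      resolving_power = 70000, mz_min = 100, mz_max = 1500,
      axis_min = 560, axis_max = 800, oversampling = 4,
      baseline_mean = 0, baseline_sd = 1, amplitude = 20000,
      n_isotopologues = 4, seed = 1
    ),
    annotation = list(
      tol_ppm = 5, snr_threshold = 3, charge_tol_ppm = 10,
      noise_window_min = 630, noise_window_max = 688
    ),
    cohort = list(
      n_patients = 25, patient_rows = 4, patient_cols = 4, patient_cv = 0.15
    ),
    stats = list(
      pseudocount = 1, long_species = "CL(78:12)", short_species = "CL(72:8)",
      richness_threshold = 3
    )
  ), class = "run_config")
}

.validate_config <- function(config, defaults = cl_default_config(),
                             path = "") {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.list(config[[k]]))
      stop("configuration key must be a block: ", path, k)
    if (is.list(defaults[[k]]))
      .validate_config(config[[k]], defaults[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' Keys absent from the file keep their defaults; unknown keys are rejected.
#'
#' @param path YAML file path (NULL = pure defaults).
#' @return A `run_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- cl_default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  .validate_config(user)
  for (blk in names(user))
    for (k in names(user[[blk]]))
      cfg[[blk]][[k]] <- user[[blk]][[k]]
  cfg
}

.generator_from_config <- function(config, layout = NULL, seed = NULL) {
  g <- config$generator
  if (is.null(layout))
    layout <- region_layout(g$layout_type, g$rows, g$cols,
                            class = g$layout_class)
  generator_config(rows = nrow(layout), cols = ncol(layout), layout = layout,
                   resolving_power = g$resolving_power,
                   mz_range = c(g$mz_min, g$mz_max),
                   axis_range = c(g$axis_min, g$axis_max),
                   oversampling = g$oversampling,
                   baseline_mean = g$baseline_mean,
                   baseline_sd = g$baseline_sd,
                   amplitude = g$amplitude,
                   n_isotopologues = g$n_isotopologues,
                   patient_cv = config$cohort$patient_cv,
                   noise_windows = list(c(config$annotation$noise_window_min,
                                          config$annotation$noise_window_max)),
                   seed = if (is.null(seed)) g$seed else seed)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

# ---- commands --------------------------------------------------------------

#' Generate a synthetic imaging run on disk
#'
#' Writes `dataset.imzML`/`dataset.ibd`, the region mask
#' (`mask.csv` + label map), ground-truth tables
#' (`truth_pixels.csv`, `truth_abundances.csv`, `truth_ratios.csv`) and a
#' `manifest.json` recording the configuration hash and seed. Deterministic
#' under the configured seed.
#'
#' @param config a `run_config` (default [cl_default_config()]) or a YAML
#'   path.
#' @param out_dir writable output directory (created if missing).
#' @return Invisibly, the list of written paths.
#' @export
cmd_generate <- function(config = cl_default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  gen <- .generator_from_config(config)
  sim <- generate_imaging_dataset(gen)
  paths <- list(
    imzml = file.path(out_dir, "dataset.imzML"),
    mask = file.path(out_dir, "mask.csv"),
    pixels = file.path(out_dir, "truth_pixels.csv"),
    abundances = file.path(out_dir, "truth_abundances.csv"),
    ratios = file.path(out_dir, "truth_ratios.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_imzml(sim$dataset, paths$imzml)
  write_region_mask(sim$mask, paths$mask)
  utils::write.csv(sim$truth$pixels, paths$pixels, row.names = FALSE)
  utils::write.csv(sim$truth$abundances, paths$abundances, row.names = FALSE)
  utils::write.csv(sim$truth$expected_ratios, paths$ratios, row.names = FALSE)
  manifest <- list(config_hash = .config_hash(config),
                   seed = config$generator$seed,
                   package = "clmsi",
                   version = as.character(utils::packageVersion("clmsi")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(paths)
}

#' Annotate an imzML imaging run
#'
#' Reads a continuous-mode imzML file, annotates every pixel against the
#' default CL/MLCL search space and writes a per-pixel long table
#' (`annotations_pixels.tsv`) plus a species-level summary
#' (`annotations_species.tsv`).
#'
#' @param imzml_path path to a continuous-mode `.imzML` file.
#' @param config a `run_config` or YAML path.
#' @param out_dir output directory.
#' @return Invisibly, a list with the long and aggregated tables and paths.
#' @export
cmd_annotate <- function(imzml_path, config = cl_default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_imzml(imzml_path)
  space <- default_species_space()
  ann <- annotate_dataset(
    ds, space,
    noise_windows = list(c(config$annotation$noise_window_min,
                           config$annotation$noise_window_max)),
    tol_ppm = config$annotation$tol_ppm,
    snr_threshold = config$annotation$snr_threshold,
    charge_tol_ppm = config$annotation$charge_tol_ppm)
  agg <- aggregate_annotations(ann, space)
  p_long <- file.path(out_dir, "annotations_pixels.tsv")
  p_agg <- file.path(out_dir, "annotations_species.tsv")
  utils::write.table(ann, p_long, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(agg, p_agg, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(pixels = ann, species = agg,
                 paths = list(pixels = p_long, species = p_agg)))
}

#' Profile annotated regions: ratios, PCA, tests, ion images
#'
#' Treats each mask region as one profile unit: builds the region-by-species
#' median S/N matrix, computes chain-length ratios and, when enough units are
#' available, PCA and Holm-adjusted group comparisons; writes CSV outputs and
#' PNG ion images of six index species.
#'
#' @param annotations per-pixel long table from [cmd_annotate()] (or its TSV
#'   path).
#' @param mask region label matrix (or the `mask.csv` path from
#'   [cmd_generate()]).
#' @param dataset optional [msi_dataset()] (or imzML path) for ion images.
#' @param config a `run_config` or YAML path.
#' @param out_dir output directory.
#' @return Invisibly, list with `profile_matrix`, `ratios`, `pca`, `tests`.
#' @export
cmd_profile <- function(annotations, mask, dataset = NULL,
                        config = cl_default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  if (is.character(annotations))
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  if (is.character(mask)) mask <- read_region_mask(mask)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  labs <- sort(unique(as.vector(mask)))
  labs <- setdiff(labs, "unassigned")
  pixlab <- function(r, cc) mask[cbind(r + 1L, cc + 1L)]
  npix <- table(factor(as.vector(mask), levels = labs))
  tabs <- lapply(labs, function(lb) {
    sub <- annotations[pixlab(annotations$row, annotations$col) == lb, ,
                       drop = FALSE]
    attr(sub, "n_pixels") <- as.integer(npix[[lb]])
    sub
  })
  space <- default_species_space()
  pm <- per_patient_median(tabs, labs, space$species, labels = labs)
  ratios <- tryCatch(chain_ratio(pm, config$stats$long_species,
                                 config$stats$short_species),
                     error = function(e) NULL)
  pca <- if (nrow(pm) >= 3) tryCatch(
    log_center_pca(pm, pseudocount = config$stats$pseudocount),
    error = function(e) NULL) else NULL
  if (is.null(pca) && nrow(pm) < 3)
    warning("fewer than three regions; PCA skipped")

  utils::write.csv(as.data.frame(unclass(pm)),
                   file.path(out_dir, "profile_matrix.csv"))
  if (!is.null(ratios))
    utils::write.csv(data.frame(region = names(ratios), ratio = as.numeric(ratios)),
                     file.path(out_dir, "chain_ratios.csv"), row.names = FALSE)
  if (!is.null(pca)) {
    utils::write.csv(as.data.frame(pca$scores), file.path(out_dir, "pca_scores.csv"))
    utils::write.csv(as.data.frame(pca$loadings), file.path(out_dir, "pca_loadings.csv"))
  }

  if (!is.null(dataset)) {
    if (is.character(dataset)) dataset <- read_imzml(dataset)
    index_species <- c("CL(72:8)", "CL(72:6)", "CL(72:4)", "CL(74:8)",
                       "CL(76:10)", "CL(78:12)")
    for (sp in index_species) {
      mz <- space$mz[space$species == sp]
      if (!length(mz)) next
      img <- tryCatch(ion_image(dataset, mz, config$annotation$tol_ppm),
                      error = function(e) NULL)
      if (is.null(img)) next
      sc <- img / max(img, 1e-12)
      sc[sc < 0] <- 0
      png::writePNG(sc, file.path(out_dir, paste0(
        "ion_", gsub("[():]", "_", sp), ".png")))
    }
  }
  invisible(list(profile_matrix = pm, ratios = ratios, pca = pca))
}

# ---- cohort driver ---------------------------------------------------------

#' Simulate and profile a patient cohort of one tissue class
#'
#' For each synthetic patient: jitter the class abundance profile
#' (log-normal, configured CV), render a small pixel grid, annotate every
#' pixel and take per-patient median S/N. Memory-bounded: one patient's
#' dataset exists at a time.
#'
#' @param tissue_class tissue class label (see [build_profile()]).
#' @param n_patients number of patients.
#' @param config a `run_config`.
#' @param seed master seed for the cohort (default from the config).
#' @return A `profile_matrix` (patients x species) with `tissue_class` and
#'   `expected_ratio` (per-patient jittered calibration targets) attributes.
#' @export
profile_cohort <- function(tissue_class, n_patients = 25,
                           config = cl_default_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$generator$seed
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 2 * n_patients)
  layout <- matrix(tissue_class, config$cohort$patient_rows,
                   config$cohort$patient_cols)
  space <- default_species_space()
  base <- build_profile(tissue_class)
  tabs <- vector("list", n_patients)
  expected <- numeric(n_patients)
  for (i in seq_len(n_patients)) {
    set.seed(seeds[i])
    prof <- jitter_profile(base, cv = config$cohort$patient_cv)
    expected[i] <- prof$expected_ratio
    gen <- .generator_from_config(config, layout = layout,
                                  seed = seeds[n_patients + i])
    sim <- generate_imaging_dataset(gen, profiles = stats::setNames(
      list(prof), tissue_class))
    mask <- matrix(tissue_class, gen$rows, gen$cols)
    tabs[[i]] <- extract_region_snr(
      sim$dataset, mask, tissue_class, space,
      noise_windows = gen$noise_windows,
      tol_ppm = config$annotation$tol_ppm,
      snr_threshold = config$annotation$snr_threshold,
      charge_tol_ppm = config$annotation$charge_tol_ppm)
  }
  ids <- sprintf("%s_%02d", tissue_class, seq_len(n_patients))
  pm <- per_patient_median(tabs, ids, space$species,
                           labels = rep(tissue_class, n_patients))
  attr(pm, "expected_ratio") <- expected
  pm
}
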