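# Imaging dataset container, ion images, region-of-interest S/N extraction.

#' Construct an imaging dataset
#'
#' Continuous-mode container: one shared m/z axis and one intensity row per
#' pixel. Pixel coordinates are 0-based `(row, col)` in row-major order.
#'
#' @param mz shared m/z axis (monotone increasing).
#' @param intensities numeric matrix, `rows * cols` pixels by `length(mz)`.
#' @param rows,cols grid dimensions.
#' @param metadata list (polarity, resolving power, acquisition m/z range...).
#' @return Object of class `msi_dataset`.
#' @export
msi_dataset <- function(mz, intensities, rows, cols, metadata = list()) {
  stopifnot(is.matrix(intensities), nrow(intensities) == rows * cols,
            ncol(intensities) == length(mz))
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("m/z axis must be strictly increasing")
  structure(list(mz = as.numeric(mz), intensities = intensities,
                 rows = as.integer(rows), cols = as.integer(cols),
                 metadata = metadata),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d x %d pixels, %d m/z samples (%.2f-%.2f)\n",
              x$rows, x$cols, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

# row-major pixel index for 0-based (row, col)
.pixel_index <- function(dataset, row, col) {
  stopifnot(row >= 0, row < dataset$rows, col >= 0, col < dataset$cols)
  row * dataset$cols + col + 1L
}

#' Extract one pixel's spectrum
#'
#' @param dataset an [msi_dataset()].
#' @param row,col 0-based pixel coordinates.
#' @return A profile-mode [mass_spectrum()].
#' @export
pixel_spectrum <- function(dataset, row, col) {
  i <- .pixel_index(dataset, row, col)
  mass_spectrum(dataset$mz, dataset$intensities[i, ], "profile")
}

#' Ion image for a target m/z
#'
#' Per pixel, the maximum profile intensity within `target_mz` plus/minus the
#' ppm tolerance; zero where the window contains no samples.
#'
#' @param dataset an [msi_dataset()].
#' @param target_mz target m/z; must lie inside the dataset's axis range.
#' @param tol_ppm half-width of the extraction window in ppm (> 0).
#' @return Numeric `rows` x `cols` matrix of class `ion_image` with attribute
#'   `target_mz`.
#' @export
ion_image <- function(dataset, target_mz, tol_ppm = 5) {
  stopifnot(inherits(dataset, "msi_dataset"), tol_ppm > 0)
  rng <- range(dataset$mz)
  if (target_mz < rng[1] || target_mz > rng[2])
    stop(sprintf("target m/z %.4f outside acquisition range %.2f-%.2f",
                 target_mz, rng[1], rng[2]))
  tol <- tol_ppm * 1e-6 * target_mz
  lo <- findInterval(target_mz - tol, dataset$mz) + 1L
  hi <- findInterval(target_mz + tol, dataset$mz)
  vals <- if (hi < lo) rep(0, nrow(dataset$intensities)) else
    apply(dataset$intensities[, lo:hi, drop = FALSE], 1, max)
  img <- matrix(vals, nrow = dataset$rows, ncol = dataset$cols, byrow = TRUE)
  structure(img, target_mz = target_mz, class = c("ion_image", "matrix", "array"))
}

#' Per-pixel S/N table for one region of interest
#'
#' Annotates every pixel carrying the requested mask label and returns the
#' long table of per-pixel species annotations with their S/N. Pixels whose
#' noise estimate fails or whose spectrum yields no annotation contribute no
#' rows (downstream medians treat missing species as S/N 0).
#'
#' @param dataset an [msi_dataset()].
#' @param mask character label matrix with the dataset's dimensions.
#' @param label region label to extract (must be present in the mask).
#' @param space species table from [enumerate_cl_space()].
#' @param noise_windows,... passed to [annotate_spectrum()].
#' @return data.frame with `row`, `col`, plus the annotation columns; the
#'   attribute `n_pixels` records how many pixels were extracted.
#' @export
extract_region_snr <- function(dataset, mask, label, space,
                               noise_windows = list(c(630, 688)), ...) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!all(dim(mask) == c(dataset$rows, dataset$cols)))
    stop("mask dimensions must equal dataset dimensions")
  hits <- which(mask == label, arr.ind = TRUE)
  if (!nrow(hits)) stop("label not present in mask: ", label)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    r <- hits[i, 1] - 1L; cc <- hits[i, 2] - 1L
    ann <- tryCatch(
      annotate_spectrum(pixel_spectrum(dataset, r, cc), space,
                        noise_windows = noise_windows, ...),
      error = function(e) NULL)
    if (is.null(ann) || !nrow(ann)) next
    ann$row <- r; ann$col <- cc
    rows[[length(rows) + 1L]] <- ann[, c("row", "col",
                                         setdiff(names(ann), c("row", "col")))]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = integer(), col = integer())
  attr(out, "n_pixels") <- nrow(hits)
  out
}

#' Per-patient median S/N profile matrix
#'
#' Collapses per-pixel S/N tables (one per patient) into a patients-by-species
#' matrix of median S/N. A species not annotated in a pixel counts as S/N 0
#' in that pixel, so medians are defined for every cell; a species never
#' annotated gives a 0 column entry.
#'
#' @param snr_tables list of [extract_region_snr()] results, one per patient.
#' @param patient_ids character vector of patient identifiers (unique).
#' @param species character vector: the species panel (matrix columns).
#' @param labels optional per-patient tissue-class labels, stored as the
#'   `tissue_class` attribute.
#' @return Numeric matrix of class `profile_matrix` (patients x species).
#' @export
per_patient_median <- function(snr_tables, patient_ids, species,
                               labels = NULL) {
  stopifnot(length(snr_tables) == length(patient_ids))
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids")
  m <- matrix(0, nrow = length(patient_ids), ncol = length(species),
              dimnames = list(patient_ids, species))
  for (i in seq_along(snr_tables)) {
    tab <- snr_tables[[i]]
    npx <- attr(tab, "n_pixels")
    if (is.null(npx)) npx <- length(unique(paste(tab$row, tab$col)))
    if (!nrow(tab) || npx == 0) next
    for (sp in intersect(unique(tab$species), species)) {
      v <- tab$snr[tab$species == sp]
      v <- c(v, rep(0, max(0L, npx - length(v))))
      m[i, sp] <- stats::median(v)
    }
  }
  if (!is.null(labels)) attr(m, "tissue_class") <- stats::setNames(labels, patient_ids)
  class(m) <- c("profile_matrix", class(m))
  m
}

#' Write a region mask as a text grid
#'
#' Integer-label CSV grid with a sidecar label map (`<path>.labels.csv`,
#' columns `code`, `label`), avoiding any histology-tool binding.
#'
#' @param mask character label matrix.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_region_mask <- function(mask, path) {
  labs <- sort(unique(as.vector(mask)))
  codes <- matrix(match(as.vector(mask), labs), nrow(mask), ncol(mask))
  utils::write.table(codes, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(data.frame(code = seq_along(labs), label = labs),
                   paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a region mask written by [write_region_mask()]
#'
#' @param path CSV path.
#' @return Character label matrix.
#' @export
read_region_mask <- function(path) {
  codes <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  labmap <- utils::read.csv(paste0(path, ".labels.csv"),
                            stringsAsFactors = FALSE)
  m <- matrix(labmap$label[match(as.vector(codes), labmap$code)],
              nrow(codes), ncol(codes))
  m
}
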