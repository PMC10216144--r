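# Minimal continuous-mode imzML reader/writer.
#
# imzML stores metadata in an mzML-style XML file and the numeric arrays in a
# binary sidecar (.ibd) referenced by byte offset. Only continuous mode (one
# shared m/z axis for every pixel) is supported; processed-mode files are
# rejected. Arrays are written as uncompressed 64-bit floats, so a write/read
# round trip preserves values exactly.

.IMZML_HEADER <- function(uuid_hex, n_spectra, max_x, max_y, mz_len) {
  sprintf(
'<?xml version="1.0" encoding="ISO-8859-1"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <cvList count="3">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>
    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <softwareList count="1">
    <software id="clmsi" version="0.1.0"/>
  </softwareList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
    </scanSettings>
  </scanSettingsList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1"/>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="DP1">
      <processingMethod order="1" softwareRef="clmsi">
        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run defaultInstrumentConfigurationRef="IC1" id="run1">
    <spectrumList count="%d" defaultDataProcessingRef="DP1">
', uuid_hex, max_x, max_y, n_spectra)
}

.IMZML_SPECTRUM <- function(i, x, y, mz_len, mz_offset, int_len, int_offset) {
  sprintf(
'      <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">
        <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>
        <scanList count="1">
          <scan>
            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>
', i - 1L, mz_len, i - 1L, x, y, mz_len, mz_len * 8L, mz_offset,
    int_len, int_len * 8L, int_offset)
}

#' Write an imaging dataset as continuous-mode imzML
#'
#' Writes `<path>` (XML) and the binary sidecar `<path minus .imzML>.ibd`
#' containing the shared m/z axis once plus one 64-bit intensity array per
#' pixel. imzML pixel positions are 1-based, x = column, y = row.
#'
#' @param dataset an [msi_dataset()].
#' @param path output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!grepl("\\.imzML$", path, ignore.case = TRUE))
    stop("path must end in .imzML")
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  uuid_bytes <- as.raw(c(
    utils::head(rep(as.integer(charToRaw("clmsi")), 4), 16)))
  uuid_hex <- paste(toupper(format(uuid_bytes)), collapse = "")
  uuid_hex <- paste0(
    substr(uuid_hex, 1, 8), "-", substr(uuid_hex, 9, 12), "-",
    substr(uuid_hex, 13, 16), "-", substr(uuid_hex, 17, 20), "-",
    substr(uuid_hex, 21, 32))

  nmz <- length(dataset$mz)
  npx <- dataset$rows * dataset$cols
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid_bytes, con)
  writeBin(dataset$mz, con, size = 8, endian = "little")
  mz_offset <- 16
  int_offsets <- 16 + nmz * 8 + (seq_len(npx) - 1) * nmz * 8
  for (p in seq_len(npx))
    writeBin(dataset$intensities[p, ], con, size = 8, endian = "little")

  xml <- file(path, "w")
  on.exit(close(xml), add = TRUE)
  cat(.IMZML_HEADER(uuid_hex, npx, dataset$cols, dataset$rows, nmz),
      file = xml)
  for (p in seq_len(npx)) {
    row <- (p - 1L) %/% dataset$cols
    col <- (p - 1L) %% dataset$cols
    cat(.IMZML_SPECTRUM(p, col + 1L, row + 1L, nmz, mz_offset, nmz,
                        int_offsets[p]),
        file = xml)
  }
  cat("    </spectrumList>\n  </run>\n</mzML>\n", file = xml)
  invisible(path)
}

#' Read a continuous-mode imzML file
#'
#' Processed-mode files (per-pixel m/z axes) are rejected. Every pixel of the
#' bounding grid implied by the positions must be present.
#'
#' @param path path to the `.imzML` file (the `.ibd` sidecar must sit next to
#'   it).
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing binary sidecar: ", ibd_path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  fc <- xml2::xml_find_all(doc, ".//fileContent/cvParam")
  acc <- xml2::xml_attr(fc, "accession")
  if ("IMS:1000031" %in% acc)
    stop("processed-mode imzML is not supported (fileContent, IMS:1000031)")
  if (!"IMS:1000030" %in% acc)
    stop("file does not declare continuous mode (fileContent)")

  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(spectra)) stop("no spectra in file")
  parse_spec <- function(s, i) {
    px <- xml2::xml_find_first(s, ".//scan/cvParam[@accession='IMS:1000050']")
    py <- xml2::xml_find_first(s, ".//scan/cvParam[@accession='IMS:1000051']")
    if (inherits(px, "xml_missing") || inherits(py, "xml_missing"))
      stop("spectrum ", i, ": missing pixel position")
    arrays <- xml2::xml_find_all(s, ".//binaryDataArray")
    if (length(arrays) < 2) stop("spectrum ", i, ": expected two binary arrays")
    meta <- lapply(arrays, function(a) {
      ref <- xml2::xml_attr(xml2::xml_find_first(a, "referenceableParamGroupRef"),
                            "ref")
      getv <- function(accession) {
        nd <- xml2::xml_find_first(
          a, sprintf("cvParam[@accession='%s']", accession))
        if (inherits(nd, "xml_missing"))
          stop("spectrum ", i, ": missing ", accession)
        as.numeric(xml2::xml_attr(nd, "value"))
      }
      list(ref = ref, length = getv("IMS:1000103"), offset = getv("IMS:1000102"))
    })
    refs <- vapply(meta, `[[`, character(1), "ref")
    list(x = as.integer(xml2::xml_attr(px, "value")),
         y = as.integer(xml2::xml_attr(py, "value")),
         mz = meta[[match("mzArray", refs)]],
         int = meta[[match("intensityArray", refs)]])
  }
  info <- lapply(seq_along(spectra), function(i) parse_spec(spectra[[i]], i))

  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  read_at <- function(offset, n) {
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = n, size = 8, endian = "little")
  }
  mzm <- info[[1]]$mz
  mz <- read_at(mzm$offset, mzm$length)

  xs <- vapply(info, `[[`, integer(1), "x")
  ys <- vapply(info, `[[`, integer(1), "y")
  cols <- max(xs); rows <- max(ys)
  if (length(info) != rows * cols)
    stop("pixel grid incomplete: ", length(info), " spectra for a ",
         rows, " x ", cols, " grid")
  ints <- matrix(0, nrow = rows * cols, ncol = length(mz))
  for (s in info) {
    if (s$int$length != length(mz))
      stop("intensity array length differs from shared m/z axis")
    p <- (s$y - 1L) * cols + s$x
    ints[p, ] <- read_at(s$int$offset, s$int$length)
  }
  msi_dataset(mz, ints, rows, cols,
              metadata = list(polarity = "negative", source = path))
}
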