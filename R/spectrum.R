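# Mass spectrum container.

#' Construct a mass spectrum
#'
#' @param mz monotone increasing numeric vector of m/z values.
#' @param intensity numeric vector, same length.
#' @param mode `"profile"` or `"centroid"`.
#' @return Object of class `mass_spectrum`: list with `mz`, `intensity`,
#'   `mode`.
#' @export
mass_spectrum <- function(mz, intensity, mode = c("profile", "centroid")) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("m/z axis must be strictly increasing")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 mode = mode), class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %s mode, %d points, m/z %.4f-%.4f\n",
              x$mode, length(x$mz),
              if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}
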