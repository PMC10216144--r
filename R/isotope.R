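# Isotope envelopes by element-wise convolution, aggregated at nominal mass.

# Natural isotope abundances and masses, indexed by nominal-mass offset from
# the monoisotopic isotope. Fine structure within an offset is aggregated
# (abundance-weighted mean mass), adequate at resolving power 70,000.
.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.0033548378), ab = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503207, 2.01410177785), ab = c(0.999885, 0.000115)),
  O = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
           ab = c(0.99757, 0.00038, 0.00205)),
  P = list(mass = 30.97376163, ab = 1.0),
  N = list(mass = c(14.0030740048, 15.0001088982), ab = c(0.99636, 0.00364)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690),
           ab = c(0.9499, 0.0075, 0.0425))
)

# convolve two aggregated distributions (abund, mean mass per offset),
# truncated to kmax offsets
.iso_convolve <- function(a, b, kmax) {
  n <- min(kmax, length(a$ab) + length(b$ab) - 1L)
  ab <- numeric(n); wm <- numeric(n)
  for (i in seq_along(a$ab)) {
    for (j in seq_along(b$ab)) {
      k <- i + j - 1L
      if (k > n) next
      w <- a$ab[i] * b$ab[j]
      ab[k] <- ab[k] + w
      wm[k] <- wm[k] + w * (a$mass[i] + b$mass[j])
    }
  }
  mass <- ifelse(ab > 0, wm / pmax(ab, .Machine$double.xmin), 0)
  list(ab = ab, mass = mass)
}

.iso_power <- function(d, n, kmax) {
  # exponentiation by squaring of the single-atom distribution
  res <- list(ab = 1.0, mass = 0.0)
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) res <- .iso_convolve(res, base, kmax)
    base <- .iso_convolve(base, base, kmax)
    n <- n %/% 2
  }
  res
}

#' Isotope envelope of a (de)protonated ion
#'
#' Computes the first `k` isotopologue peaks of an ion formed from a neutral
#' elemental formula by removing `|z|` protons (negative `z`) or adding `z`
#' protons (positive `z`). Isotopologues are aggregated at nominal-mass
#' resolution; abundances are normalized so the monoisotopic peak is 1.
#' Successive peaks are spaced by approximately `1.0033548 / |z|` m/z when the
#' M+1 peak is carbon-13 dominated.
#'
#' @param formula an [elemental_formula()] (or parseable string) of the
#'   neutral species.
#' @param z signed integer charge (non-zero); negative = deprotonated.
#' @param k number of isotopologue peaks to return (>= 1).
#' @return Data frame of class `isotope_envelope` with columns `mz` and
#'   `abundance` (monoisotopic = 1); attribute `charge`. Trailing
#'   zero-abundance peaks are dropped, so the result may be shorter than `k`.
#' @examples
#' env <- isotope_envelope(cl_formula(72, 8), z = -2, k = 4)
#' diff(env$mz)[1]  # ~0.5017
#' @export
isotope_envelope <- function(formula, z, k = 4) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "elemental_formula"))
  z <- as.integer(z)
  if (length(z) != 1L || z == 0L) stop("charge z must be a non-zero integer")
  if (k < 1) stop("k must be >= 1")
  unknown <- setdiff(names(formula), names(.ISOTOPES))
  if (length(unknown))
    stop("no isotope data for element(s): ", paste(unknown, collapse = ", "))
  dist <- list(ab = 1.0, mass = 0.0)
  for (el in names(formula))
    dist <- .iso_convolve(dist, .iso_power(.ISOTOPES[[el]], unclass(formula)[el], k),
                          k)
  keep <- which(dist$ab > 0)
  keep <- seq_len(max(keep))  # drop only trailing zeros
  ab <- dist$ab[keep] / dist$ab[1]
  mass <- dist$mass[keep]
  mz <- if (z < 0) (mass - abs(z) * PROTON_MASS) / abs(z)
        else (mass + z * PROTON_MASS) / z
  structure(
    data.frame(mz = mz, abundance = ab),
    charge = z,
    class = c("isotope_envelope", "data.frame")
  )
}
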