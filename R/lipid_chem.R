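# Cardiolipin / monolysocardiolipin composition space, exact m/z, fatty acyls.

#' Neutral elemental formula of a cardiolipin sum composition
#'
#' For CL(X:Y), X total acyl carbons and Y total double bonds over the four
#' chains, the neutral formula is C(X+9) H(2X-2Y+14) O17 P2: the nine backbone
#' carbons come from the two phosphatidylglycerol glycerols plus the bridging
#' glycerol.
#'
#' @param X total acyl-chain carbons (>= 8, four chains of at least 2).
#' @param Y total number of carbon-carbon double bonds (>= 0).
#' @return An [elemental_formula()].
#' @examples
#' cl_formula(72, 8)   # C81H142O17P2
#' @export
cl_formula <- function(X, Y) {
  stopifnot(length(X) == 1L, length(Y) == 1L)
  if (X < 8) stop("CL needs X >= 8 total acyl carbons (four chains of >= 2)")
  if (Y < 0) stop("double-bond count Y must be >= 0")
  h <- 2 * X - 2 * Y + 14
  if (h <= 0) stop("unphysical composition: hydrogen count would be <= 0")
  elemental_formula(C = X + 9, H = h, O = 17, P = 2)
}

#' Neutral elemental formula of a monolysocardiolipin sum composition
#'
#' MLCL is CL with one acyl chain removed by ester hydrolysis (loss of a fatty
#' acyl residue, FA minus H2O), giving C(X+9) H(2X-2Y+16) O16 P2 for
#' MLCL(X:Y) with three chains.
#'
#' Note: published tables occasionally print MLCL formulas that disagree with
#' their own exact m/z (a two-hydrogen discrepancy); this function implements
#' the ester-hydrolysis rule, whose masses match the printed MLCL exact m/z
#' values.
#'
#' @param X total acyl-chain carbons (>= 6, three chains of at least 2).
#' @param Y total number of carbon-carbon double bonds (>= 0).
#' @return An [elemental_formula()].
#' @export
mlcl_formula <- function(X, Y) {
  stopifnot(length(X) == 1L, length(Y) == 1L)
  if (X < 6) stop("MLCL needs X >= 6 total acyl carbons (three chains of >= 2)")
  if (Y < 0) stop("double-bond count Y must be >= 0")
  h <- 2 * X - 2 * Y + 16
  if (h <= 0) stop("unphysical composition: hydrogen count would be <= 0")
  elemental_formula(C = X + 9, H = h, O = 16, P = 2)
}

#' A CL or MLCL species from its sum composition
#'
#' @param lipid_class `"CL"` or `"MLCL"`.
#' @param X,Y total acyl carbons and double bonds.
#' @return A list of class `lipid_species` with elements `lipid_class`,
#'   `total_carbons`, `total_double_bonds`, `neutral_formula`, `neutral_mass`,
#'   and `mz_2minus` (the exact m/z of the doubly deprotonated ion).
#' @export
lipid_species <- function(lipid_class, X, Y) {
  lipid_class <- match.arg(lipid_class, c("CL", "MLCL"))
  f <- switch(lipid_class, CL = cl_formula(X, Y), MLCL = mlcl_formula(X, Y))
  m <- monoisotopic_mass(f)
  structure(list(
    lipid_class = lipid_class,
    total_carbons = as.integer(X),
    total_double_bonds = as.integer(Y),
    neutral_formula = f,
    neutral_mass = m,
    mz_2minus = mz_doubly_deprotonated(m)
  ), class = "lipid_species")
}

#' @export
format.lipid_species <- function(x, ...) {
  sprintf("%s(%d:%d) [M-2H]2- m/z %.5f (%s)", x$lipid_class,
          x$total_carbons, x$total_double_bonds, x$mz_2minus,
          format(x$neutral_formula))
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Species label such as "CL(72:8)"
#' @param x a `lipid_species`, or the table from [enumerate_cl_space()].
#' @return character vector of labels.
#' @export
species_label <- function(x) {
  if (inherits(x, "lipid_species"))
    return(sprintf("%s(%d:%d)", x$lipid_class, x$total_carbons, x$total_double_bonds))
  sprintf("%s(%d:%d)", x$lipid_class, x$total_carbons, x$total_double_bonds)
}

#' Enumerate the CL/MLCL sum-composition space
#'
#' Generates every (class, X, Y) combination over the requested ranges and
#' returns them sorted by exact doubly-deprotonated m/z. Brain CL acyl totals
#' are predominantly even-carbon, so `carbon_step` defaults to 2.
#'
#' @param carbon_min,carbon_max range of total acyl carbons X (inclusive).
#' @param db_min,db_max range of total double bonds Y (inclusive).
#' @param classes character subset of `c("CL", "MLCL")`.
#' @param carbon_step step for X (2 = even totals only; 1 admits odd chains).
#' @return A data.frame of class `cl_species_table` with columns
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `species`
#'   (label), `formula` (string), `neutral_mass`, `mz` (doubly deprotonated),
#'   sorted by `mz`. Empty ranges give a zero-row table.
#' @examples
#' sp <- enumerate_cl_space(68, 80, 2, 14)
#' nrow(sp)  # 91
#' @export
enumerate_cl_space <- function(carbon_min, carbon_max, db_min, db_max,
                               classes = "CL", carbon_step = 2) {
  stopifnot(carbon_step >= 1)
  classes <- match.arg(classes, c("CL", "MLCL"), several.ok = TRUE)
  carbons <- if (carbon_min <= carbon_max)
    seq(carbon_min, carbon_max, by = carbon_step) else integer(0)
  dbs <- if (db_min <= db_max) seq(db_min, db_max) else integer(0)
  grid <- expand.grid(
    lipid_class = classes,
    total_carbons = carbons,
    total_double_bonds = dbs,
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- lipid_species(grid$lipid_class[i], grid$total_carbons[i],
                        grid$total_double_bonds[i])
    data.frame(
      lipid_class = sp$lipid_class,
      total_carbons = sp$total_carbons,
      total_double_bonds = sp$total_double_bonds,
      species = species_label(sp),
      formula = format(sp$neutral_formula),
      neutral_mass = sp$neutral_mass,
      mz = sp$mz_2minus,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lipid_class = character(), total_carbons = integer(),
               total_double_bonds = integer(), species = character(),
               formula = character(), neutral_mass = numeric(),
               mz = numeric(), stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("lipid_class", "total_carbons", "total_double_bonds")]), ]
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("cl_species_table", "data.frame")
  out
}

#' Construct a fatty acyl chain
#'
#' @param carbons chain length a (>= 2).
#' @param double_bonds number of C=C double bonds b, `b <= floor((a - 2) / 2)`.
#' @param db_positions optional integer vector of delta positions (carbon
#'   index counted from the carboxyl carbon); when given, must have length
#'   `double_bonds` with entries in `2..(carbons - 2)`.
#' @return An object of class `fatty_acyl`.
#' @examples
#' fatty_acyl(18, 1, db_positions = 9)   # oleic-type 18:1 delta-9
#' @export
fatty_acyl <- function(carbons, double_bonds, db_positions = NULL) {
  stopifnot(length(carbons) == 1L, length(double_bonds) == 1L)
  carbons <- as.integer(carbons); double_bonds <- as.integer(double_bonds)
  if (carbons < 2) stop("fatty acyl needs >= 2 carbons")
  if (double_bonds < 0) stop("double-bond count must be >= 0")
  if (double_bonds > (carbons - 2) %/% 2)
    stop("too many double bonds for chain length ", carbons)
  if (!is.null(db_positions)) {
    db_positions <- as.integer(db_positions)
    if (length(db_positions) != double_bonds)
      stop("db_positions must have one entry per double bond")
    if (any(db_positions < 2 | db_positions > carbons - 2))
      stop("double-bond positions must lie in 2..(carbons - 2)")
  }
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 db_positions = db_positions), class = "fatty_acyl")
}

#' @export
format.fatty_acyl <- function(x, ...) {
  pos <- if (!is.null(x$db_positions))
    paste0("(", paste0("d", x$db_positions, collapse = ","), ")") else ""
  sprintf("FA %d:%d%s", x$carbons, x$double_bonds, pos)
}

#' @export
print.fatty_acyl <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' m/z of the fatty acid carboxylate anion [FA - H]-
#'
#' CID of deprotonated CL releases the acyl chains as carboxylate anions
#' [CaH(2a-2b-1)O2]-; the returned m/z includes the mass of the extra
#' electron.
#'
#' @param fa a [fatty_acyl()].
#' @return m/z of the singly charged carboxylate anion.
#' @examples
#' fa_anion_mz(fatty_acyl(18, 1))  # 281.24860
#' @export
fa_anion_mz <- function(fa) {
  stopifnot(inherits(fa, "fatty_acyl"))
  f <- elemental_formula(C = fa$carbons,
                         H = 2 * fa$carbons - 2 * fa$double_bonds - 1,
                         O = 2)
  monoisotopic_mass(f) + ELECTRON_MASS
}

#' Acyl-chain combinations consistent with a sum composition
#'
#' All multisets of `n_chains` fatty acyls drawn from `pool` whose carbons sum
#' to `X` and double bonds sum to `Y`. Each multiset is ordered canonically by
#' descending carbons then descending double bonds; the list of multisets is
#' sorted lexicographically on that canonical form.
#'
#' @param X,Y target totals.
#' @param pool list of [fatty_acyl()] candidates (default: the chains commonly
#'   reported in brain CL).
#' @param n_chains 4 for CL, 3 for MLCL.
#' @return A list of multisets; each multiset is a list of `fatty_acyl`
#'   objects with a `label` attribute like `"18:1_18:1_18:1_18:1"`. Possibly
#'   empty.
#' @export
fa_combinations <- function(X, Y, pool = default_fa_pool(), n_chains = 4) {
  stopifnot(length(pool) >= 1, n_chains >= 1)
  stopifnot(all(vapply(pool, inherits, logical(1), "fatty_acyl")))
  np <- length(pool)
  # multisets as non-decreasing index tuples
  idx <- seq_len(np)
  combos <- as.matrix(do.call(expand.grid, rep(list(idx), n_chains)))
  nondecr <- rep(TRUE, nrow(combos))
  if (n_chains > 1) {
    for (j in seq_len(n_chains - 1))
      nondecr <- nondecr & combos[, j] <= combos[, j + 1]
  }
  combos <- combos[nondecr, , drop = FALSE]
  carb <- vapply(pool, function(f) f$carbons, integer(1))
  dbs <- vapply(pool, function(f) f$double_bonds, integer(1))
  sumc <- matrix(carb[combos], nrow(combos))
  sumb <- matrix(dbs[combos], nrow(combos))
  hit <- which(rowSums(sumc) == X & rowSums(sumb) == Y)
  out <- lapply(hit, function(i) {
    chains <- pool[combos[i, ]]
    cc <- vapply(chains, function(f) f$carbons, integer(1))
    bb <- vapply(chains, function(f) f$double_bonds, integer(1))
    ord <- order(-cc, -bb)
    chains <- chains[ord]
    attr(chains, "label") <- paste(sprintf("%d:%d", cc[ord], bb[ord]),
                                   collapse = "_")
    chains
  })
  labs <- vapply(out, attr, character(1), "label")
  out[order(labs, decreasing = TRUE)]
}

#' Default fatty-acyl pool for chain assignment
#'
#' The acyl chains commonly reported as CL constituents in mammalian brain:
#' 14:0, 16:0, 16:1, 18:0, 18:1, 18:2, 18:3, 20:3, 20:4, 22:6.
#' @return list of [fatty_acyl()] objects.
#' @export
default_fa_pool <- function() {
  spec <- list(c(14, 0), c(16, 0), c(16, 1), c(18, 0), c(18, 1), c(18, 2),
               c(18, 3), c(20, 3), c(20, 4), c(22, 6))
  lapply(spec, function(s) fatty_acyl(s[1], s[2]))
}

#' Diagnostic fragment pair localizing a double bond
#'
#' In the hybrid CID/UVPD scheme, photodissociation cleaves the two
#' carbon-carbon bonds flanking a C=C of the fatty acid carboxylate anion,
#' yielding a pair of carboxylate-containing fragment ions separated by
#' exactly 24 Da (one C2 unit). Convention used here for the terminal-atom
#' bookkeeping (kept in this single function so downstream ratio code is
#' convention-independent): the low-mass fragment is the anion
#' [C(n-1)H(2n-3)O2]- from cleavage of the C(n-1)-C(n) bond (n = delta
#' position), and the high-mass partner is that fragment plus C2.
#'
#' @param fa a [fatty_acyl()] with exactly one localized double bond.
#' @return Numeric length-2 vector: the two diagnostic m/z values (low, high),
#'   24.0000 apart.
#' @examples
#' diagnostic_pair_mz(fatty_acyl(18, 1, db_positions = 9))
#' @export
diagnostic_pair_mz <- function(fa) {
  stopifnot(inherits(fa, "fatty_acyl"))
  if (fa$double_bonds != 1 || is.null(fa$db_positions))
    stop("diagnostic pair requires exactly one localized double bond")
  n <- fa$db_positions[1]
  low <- monoisotopic_mass(elemental_formula(C = n - 1, H = 2 * n - 3, O = 2)) +
    ELECTRON_MASS
  c(low, low + 24.0)
}
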