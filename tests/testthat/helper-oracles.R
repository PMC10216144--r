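# Independent oracles and shared fixtures for the test suite.

# Brute-force monoisotopic mass: an independent atomic-mass table and an
# explicit element-by-element loop (no package code).
oracle_mass <- function(counts) {
  tab <- c(C = 12.0, H = 1.00782503207, O = 15.9949146196, P = 30.97376163,
           N = 14.0030740048, S = 31.97207100)
  total <- 0
  for (el in names(counts)) total <- total + counts[[el]] * tab[[el]]
  total
}

oracle_proton <- 1.00727646688
oracle_electron <- 0.00054857991

# published identification table, CL rows: (X, Y, printed measured m/z,
# printed exact m/z, printed formula). The last row's printed attribution
# reads 78:13, which contradicts its own printed formula C87H148O17P2 and
# exact m/z 762.502 (both correspond to 78:11, since H = 2X - 2Y + 14); the
# formula-consistent composition is used here.
table1_cl <- data.frame(
  X = c(70, 70, 72, 72, 72, 74, 74, 74, 76, 78),
  Y = c(5, 4, 8, 6, 4, 8, 7, 6, 10, 11),
  measured = c(712.487, 713.494, 723.480, 725.494, 727.509, 737.494, 738.502,
               739.509, 749.494, 762.501),
  exact_printed = c(712.487, 713.495, 723.479, 725.495, 727.510, 737.495,
                    738.502, 739.510, 749.495, 762.502),
  formula = c("C79H144O17P2", "C79H146O17P2", "C81H142O17P2", "C81H146O17P2",
              "C81H150O17P2", "C83H146O17P2", "C83H148O17P2", "C83H150O17P2",
              "C85H146O17P2", "C87H148O17P2"),
  stringsAsFactors = FALSE
)

# exhaustive multiset enumeration over a pool (independent of the package's
# index arithmetic): recursion over non-decreasing index tuples
oracle_multisets <- function(pool_df, n_chains, X, Y) {
  res <- list()
  recurse <- function(start, chosen) {
    if (length(chosen) == n_chains) {
      if (sum(pool_df$carbons[chosen]) == X &&
          sum(pool_df$dbs[chosen]) == Y)
        res[[length(res) + 1L]] <<- sort(sprintf(
          "%d:%d", pool_df$carbons[chosen], pool_df$dbs[chosen]))
      return(invisible())
    }
    for (i in start:nrow(pool_df)) recurse(i, c(chosen, i))
  }
  recurse(1L, integer(0))
  unique(res)
}

# small fast generator configuration for end-to-end tests
small_config <- function(rows = 2, cols = 2, seed = 101, ...) {
  generator_config(rows = rows, cols = cols, seed = seed, ...)
}

# a one-species profile for controlled rendering tests
single_species_profile <- function(lipid_class = "CL", X = 72, Y = 4,
                                   attenuation = 1) {
  sp <- enumerate_cl_space(X, X, Y, Y, lipid_class)
  structure(list(tissue_class = "NL_grey", species = sp, abundance = 1,
                 attenuation = attenuation, expected_ratio = NA_real_),
            class = "tissue_profile")
}
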