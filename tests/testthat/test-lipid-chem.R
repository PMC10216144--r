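# CL/MLCL composition rules, enumeration, fatty acyls and fragments.

test_that("CL neutral formulas match the published proposed formulas", {
  expect_true(cl_formula(72, 8) == "C81H142O17P2")
  expect_true(cl_formula(70, 4) == "C79H146O17P2")
  expect_true(cl_formula(72, 4) == "C81H150O17P2")
  for (i in seq_len(nrow(table1_cl)))
    expect_true(cl_formula(table1_cl$X[i], table1_cl$Y[i]) ==
                  table1_cl$formula[i])
  expect_error(cl_formula(6, 0), "X >= 8")
  expect_error(cl_formula(72, -1), ">= 0")
})

test_that("MLCL follows the ester-hydrolysis rule (masses, not the
           internally inconsistent printed formulas)", {
  f <- mlcl_formula(52, 2)
  expect_true(f == "C61H116O16P2")
  expect_equal(mz_doubly_deprotonated(monoisotopic_mass(f)), 582.3797,
               tolerance = 1e-4)
  expect_true(mlcl_formula(54, 4) == "C63H116O16P2")
  expect_error(mlcl_formula(4, 0), "X >= 6")
})

test_that("composition-space enumeration is complete, sorted, duplicate-free", {
  sp <- enumerate_cl_space(68, 80, 2, 14, "CL")
  expect_identical(nrow(sp), 91L)  # 7 carbon values x 13 db values
  expect_false(is.unsorted(sp$mz))
  expect_identical(anyDuplicated(sp[c("lipid_class", "total_carbons",
                                      "total_double_bonds")]), 0L)
  expect_true(any(abs(sp$mz - 749.49449) < 5e-5))  # CL(76:10)
  one <- enumerate_cl_space(70, 70, 4, 4, "CL")
  expect_identical(nrow(one), 1L)
  expect_true(parse_formula(one$formula) == "C79H146O17P2")
  # closure over the published CL table entries
  for (i in seq_len(nrow(table1_cl))) {
    hits <- sp$total_carbons == table1_cl$X[i] &
      sp$total_double_bonds == table1_cl$Y[i]
    expect_identical(sum(hits), 1L)
  }
  expect_identical(nrow(enumerate_cl_space(80, 68, 2, 14, "CL")), 0L)
})

test_that("fatty acyl constructor enforces its invariants", {
  expect_error(fatty_acyl(18, 9), "too many double bonds")
  expect_error(fatty_acyl(1, 0), ">= 2 carbons")
  expect_error(fatty_acyl(18, 2, db_positions = 9), "one entry per")
  expect_error(fatty_acyl(18, 1, db_positions = 17), "2\\.\\.")
  expect_silent(fatty_acyl(18, 1, db_positions = 9))
})

test_that("carboxylate anion m/z matches formula arithmetic", {
  # oracle: C18H33O2 plus one electron
  expect_equal(fa_anion_mz(fatty_acyl(18, 1)),
               oracle_mass(list(C = 18, H = 33, O = 2)) + oracle_electron,
               tolerance = 1e-9)
  expect_equal(fa_anion_mz(fatty_acyl(18, 1)), 281.24860, tolerance = 1e-5)
  expect_equal(fa_anion_mz(fatty_acyl(16, 0)), 255.23295, tolerance = 1e-5)
  # one double bond = loss of H2
  expect_equal(fa_anion_mz(fatty_acyl(18, 0)) - fa_anion_mz(fatty_acyl(18, 1)),
               2.01565, tolerance = 1e-5)
})

test_that("chain combinations match published assignments and the
           brute-force enumeration oracle", {
  pool3 <- lapply(list(c(16, 0), c(18, 1), c(18, 2)),
                  function(s) fatty_acyl(s[1], s[2]))
  hit <- fa_combinations(72, 4, pool = pool3, n_chains = 4)
  expect_length(hit, 1)
  expect_identical(attr(hit[[1]], "label"), "18:1_18:1_18:1_18:1")

  pool4 <- lapply(list(c(16, 0), c(16, 1), c(18, 1), c(18, 2)),
                  function(s) fatty_acyl(s[1], s[2]))
  labs <- vapply(fa_combinations(70, 4, pool = pool4, n_chains = 4),
                 attr, character(1), "label")
  expect_true("18:2_18:1_18:1_16:0" %in% labs)

  tiny <- fa_combinations(8, 0, pool = list(fatty_acyl(2, 0)), n_chains = 4)
  expect_length(tiny, 1)
  expect_identical(attr(tiny[[1]], "label"), "2:0_2:0_2:0_2:0")

  # exhaustive equivalence on random pools of size <= 6
  set.seed(7)
  for (rep in 1:8) {
    np <- sample(2:6, 1)
    pool_df <- data.frame(carbons = sample(seq(12, 22, 2), np, replace = TRUE),
                          dbs = sample(0:4, np, replace = TRUE))
    pool_df <- unique(pool_df)
    pool <- lapply(seq_len(nrow(pool_df)), function(i)
      fatty_acyl(pool_df$carbons[i], min(pool_df$dbs[i],
                                         (pool_df$carbons[i] - 2) %/% 2)))
    pool_df$dbs <- vapply(pool, function(f) f$double_bonds, integer(1))
    X <- sample(48:80, 1); Y <- sample(0:8, 1)
    got <- lapply(fa_combinations(X, Y, pool = pool, n_chains = 4),
                  function(ch) sort(vapply(ch, function(f)
                    sprintf("%d:%d", f$carbons, f$double_bonds), character(1))))
    want <- oracle_multisets(pool_df, 4, X, Y)
    expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                    vapply(want, paste, character(1), collapse = "|"))
  }
})

test_that("double-bond diagnostic pairs are 24 Da apart and
           position-resolved", {
  d9 <- diagnostic_pair_mz(fatty_acyl(18, 1, db_positions = 9))
  d11 <- diagnostic_pair_mz(fatty_acyl(18, 1, db_positions = 11))
  expect_equal(diff(d9), 24.0, tolerance = 1e-9)
  expect_equal(diff(d11), 24.0, tolerance = 1e-9)
  # corresponding fragments differ by C2H4
  expect_equal(d11 - d9, rep(28.0313, 2), tolerance = 1e-4)
  # delta-9 and delta-11 ion sets are mutually disjoint
  expect_gt(min(abs(outer(d9, d11, "-"))), 0.1)
  expect_error(diagnostic_pair_mz(fatty_acyl(18, 2)), "one localized")
  expect_error(diagnostic_pair_mz(fatty_acyl(18, 1)), "one localized")
})
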