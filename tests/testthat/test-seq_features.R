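test_that("sanitize uppercases, strips symbols and rejects short sequences", {
  expect_error(sanitize_sequence("mkT*"), "too short")
  expect_identical(sanitize_sequence(strrep("a", 40)), strrep("A", 40))
  expect_warning(out <- sanitize_sequence(paste0(strrep("A", 35), "X")),
                 "nonstandard")
  expect_identical(out, strrep("A", 35))
  expect_identical(suppressWarnings(
    sanitize_sequence(paste0(strrep("ac-", 20), "*"))),
    strrep("AC", 20))
})

test_that("amino-acid composition is normalized and matches brute force", {
  s <- paste0(strrep("A", 10), strrep("C", 10), strrep("D", 10),
              strrep("E", 10))
  ac <- aa_composition(s)
  expect_equal(unname(ac[c("aac_A", "aac_C", "aac_D", "aac_E")]),
               rep(0.25, 4))
  expect_equal(sum(ac), 1)
  expect_equal(unname(aa_composition(strrep("A", 40))[["aac_A"]]), 1)
  set.seed(11)
  s <- rand_protein(200)
  expect_equal(unname(aa_composition(s)), unname(oracle_aac(s)),
               tolerance = 1e-12)
})

test_that("dipeptide composition counts overlapping pairs over L-1", {
  expect_equal(dipeptide_composition(strrep("A", 40))[["dpc_AA"]], 1)
  dc <- dipeptide_composition(strrep("AC", 20))
  expect_equal(dc[["dpc_AC"]], 20 / 39)
  expect_equal(dc[["dpc_CA"]], 19 / 39)
  set.seed(12)
  for (i in 1:5) {
    s <- rand_protein(sample(30:200, 1))
    d <- dipeptide_composition(s)
    expect_equal(sum(d), 1)
    expect_equal(unname(d), unname(oracle_dpc(s)), tolerance = 1e-12)
  }
})

test_that("molecular weight adds exactly one water and is additive", {
  expect_equal(molecular_weight("G"), 75.0666, tolerance = 0.01)
  expect_equal(molecular_weight("GG"), 2 * 57.0513 + 18.0153,
               tolerance = 1e-3)
  set.seed(13)
  s1 <- rand_protein(50); s2 <- rand_protein(70)
  expect_equal(molecular_weight(paste0(s1, s2)),
               molecular_weight(s1) + molecular_weight(s2) - 18.0153)
})

test_that("aromaticity is the F/W/Y fraction", {
  expect_equal(aromaticity(strrep("FWY", 10)), 1)
  expect_equal(aromaticity(strrep("AG", 20)), 0)
  expect_equal(aromaticity(strrep("FAAA", 10)), 0.25)
})

test_that("instability index follows the DIWV formula", {
  expect_equal(instability_index("GG"),
               5 * phagekit:::DIWV["G", "G"])
  # homopolymer closed form: 10 * (L-1)/L * DIWV(X,X)
  L <- 200
  expect_equal(instability_index(strrep("W", L)),
               10 * (L - 1) / L * phagekit:::DIWV["W", "W"])
  set.seed(14)
  s <- rand_protein(100)
  expect_equal(instability_index(s), oracle_instability(s),
               tolerance = 1e-12)
})

test_that("charge has the correct protonation limits and decreases in pH", {
  s <- "KKRHDDEECY"
  nK <- 2; nR <- 1; nH <- 1; n_acid <- 6
  expect_equal(charge_at_pH(s, -10), 1 + nK + nR + nH, tolerance = 1e-4)
  expect_equal(charge_at_pH(s, 24), -(1 + n_acid), tolerance = 1e-4)
  pHs <- seq(0, 14, by = 0.5)
  q <- vapply(pHs, function(p) charge_at_pH(s, p), 0)
  expect_true(all(diff(q) < 0))
})

test_that("isoelectric point zeroes the charge and ranks poly-K/poly-D", {
  set.seed(15)
  s <- rand_protein(80)
  expect_lt(abs(charge_at_pH(s, isoelectric_point(s))), 1e-3)
  expect_gt(isoelectric_point(strrep("K", 30)), 9.5)
  expect_lt(isoelectric_point(strrep("D", 30)), 4.5)
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravy(strrep("A", 40)), 1.8)
  expect_equal(gravy(strrep("AV", 20)), 3.0)
  set.seed(16)
  s <- rand_protein(150)
  expect_equal(gravy(s), oracle_gravy(s), tolerance = 1e-12)
})

test_that("secondary-structure sets overlap on L as documented", {
  expect_equal(unname(ss_fractions(strrep("V", 30))), c(1, 0, 0))
  expect_equal(unname(ss_fractions(strrep("N", 30))), c(0, 1, 0))
  fr <- ss_fractions(strrep("L", 30))
  expect_equal(unname(fr[c("frac_helix", "frac_sheet")]), c(1, 1))
})

test_that("reduced extinction coefficient uses published W/Y weights", {
  expect_equal(extinction_reduced(strrep("W", 30)), 165000)
  expect_equal(extinction_reduced(paste0("WY", strrep("G", 30))), 6990)
  expect_equal(extinction_reduced(strrep("GAS", 12)), 0)
})

test_that("featurize yields 431 named finite features, deterministically", {
  set.seed(17)
  s <- rand_protein(120)
  fv <- featurize(s)
  expect_length(fv, 431)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, featurize(s))
  expect_equal(sum(fv[1:20]), 1)
  expect_equal(sum(fv[21:420]), 1)
})

test_that("featurize is total across the length range", {
  set.seed(18)
  for (L in c(30, 31, 100, 5000, 50000)) {
    fv <- featurize(rand_protein(L))
    expect_true(all(is.finite(fv)))
    expect_equal(fv[["length"]], L)
  }
})

test_that("feature matrices round-trip through CSV", {
  set.seed(19)
  rec <- protein_records(id = paste0("p", 1:3),
                         sequence = replicate(3, rand_protein(60)))
  mat <- featurize_records(rec)
  expect_equal(dim(mat), c(3, 431))
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(mat, path)
  expect_true(file.exists(paste0(path, ".constants.json")))
  back <- read_feature_matrix(path)
  expect_identical(colnames(back), colnames(mat))
  expect_equal(back, mat, tolerance = 1e-12)
})

test_that("featurize_records drops unsanitizable records with a warning", {
  rec <- protein_records(id = c("ok", "short"),
                         sequence = c(strrep("ADKV", 20), "MKT"))
  expect_warning(mat <- featurize_records(rec), "dropped 1")
  expect_identical(rownames(mat), "ok")
})
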