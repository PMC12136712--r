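test_that("interface extraction honors the inclusive distance boundary", {
  # two single-atom residues at controlled separations
  mk <- function(dist_b) {
    atoms <- data.frame(
      chain = c("A", "B"), resno = c(1L, 1L), insert = "",
      resid = "GLY", elety = "CA",
      x = c(0, dist_b), y = 0, z = 0, stringsAsFactors = FALSE)
    structure(list(atoms = atoms, chains = c("A", "B")),
              class = "structure_model")
  }
  expect_equal(nrow(interface_residues(mk(4.99), "A", "B")), 1)
  expect_equal(nrow(interface_residues(mk(5.00), "A", "B")), 1)
  expect_equal(nrow(interface_residues(mk(5.01), "A", "B")), 0)
  expect_error(interface_residues(mk(3), "A", "Z"), "unknown chain")
  expect_error(interface_residues(mk(3), "A", "A"))
})

test_that("planted contacts are recovered exactly and match brute force", {
  for (seed in c(3, 14, 27)) {
    path <- tempfile(fileext = ".pdb")
    truth <- gen_complex(path, n_contacts = 15, n_decoys = 15, seed = seed)
    model <- read_structure(path)
    found <- interface_residues(model, "A", "B", cutoff = 5)
    expect_setequal(found$resno, truth$contact_resno)
    oracle <- brute_force_interface(model, "A", "B", 5)
    expect_setequal(paste(found$chain, found$resno, found$insert), oracle)
    # sidecar round-trips
    side <- jsonlite::read_json(paste0(path, ".truth.json"),
                                simplifyVector = TRUE)
    expect_setequal(side$contact_resno, truth$contact_resno)
  }
})

test_that("contiguous region calling enforces the minimum run length", {
  r <- contiguous_regions(1:7)
  expect_equal(r$start, 1); expect_equal(r$end, 7)
  expect_equal(nrow(contiguous_regions(1:5)), 0)
  r2 <- contiguous_regions(c(10:16, 20:22, 30:40))
  expect_equal(r2$start, c(10, 30))
  expect_equal(r2$end, c(16, 40))
  # invariant to input order
  expect_identical(contiguous_regions(sample(c(10:16, 20:22, 30:40))), r2)
  expect_equal(nrow(contiguous_regions(integer())), 0)
})

test_that("column profiles count occupancy and modal conservation", {
  msa <- c(s1 = "GGA", s2 = "GGC", s3 = "GA-", s4 = "G--")
  cp <- column_profile(msa)
  expect_equal(cp$occupancy, c(1, 0.75, 0.5))
  expect_equal(cp$conservation[1], 1)
  expect_equal(cp$conservation[2], 2 / 3)
  expect_equal(cp$modal_residue[1], "G")
  all_gap <- column_profile(c(a = "-", b = "-"))
  expect_equal(all_gap$occupancy, 0)
  expect_true(is.na(all_gap$conservation))
  expect_true(all_gap$low_alignment_ratio)
})

test_that("profiles and logos are invariant to sequence order", {
  g <- gen_msa(n_seqs = 30, length = 12, seed = 8)
  shuffled <- g$msa[sample(length(g$msa))]
  expect_equal(column_profile(g$msa), column_profile(shuffled))
  expect_equal(logo_matrix(g$msa), logo_matrix(shuffled))
})

test_that("information content spans its closed-form anchor points", {
  invariant <- c(a = "G", b = "G", c = "G")
  expect_equal(logo_matrix(invariant)$ic_bits, log2(20))
  uniform <- stats::setNames(phagekit:::AA_STANDARD, paste0("u", 1:20))
  expect_equal(logo_matrix(uniform)$ic_bits, 0, tolerance = 1e-12)
  half <- c(a = "A", b = "A", c = "C", d = "C")
  expect_equal(logo_matrix(half)$ic_bits, log2(20) - 1)
  # gap handling: frequencies are among non-gap entries only
  gapped <- c(a = "A", b = "A", c = "-", d = "-")
  lm <- logo_matrix(gapped)
  expect_equal(lm$gap_fraction, 0.5)
  expect_equal(unname(lm$frequencies[1, "A"]), 1)
})

test_that("PCA embedding centers, orders variance, and fixes signs", {
  set.seed(9)
  # rank-1 matrix: first component explains everything
  u <- rnorm(30); v <- rnorm(8)
  X <- u %*% t(v)
  p <- pca_embed(X, n_components = 2)
  expect_gte(p$explained_variance[1], 0.999)
  # two planted clusters separate along PC1
  X2 <- rbind(matrix(rnorm(50 * 4, 0), 50),
              matrix(rnorm(50 * 4, 6), 50))
  p2 <- pca_embed(X2)
  gap <- abs(mean(p2$scores[1:50, 1]) - mean(p2$scores[51:100, 1]))
  spread <- max(sd(p2$scores[1:50, 1]), sd(p2$scores[51:100, 1]))
  expect_gt(gap, spread)
  # duplicated rows embed identically; sign convention is deterministic
  X3 <- rbind(X2, X2[1, , drop = FALSE])
  p3 <- pca_embed(X3)
  expect_equal(p3$scores[1, ], p3$scores[101, ])
  i_max <- which.max(abs(p2$loadings[, 1]))
  expect_gt(p2$loadings[i_max, 1], 0)
})
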