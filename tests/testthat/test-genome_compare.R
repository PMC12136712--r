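cds <- function(start, end, strand = "+", product = "",
                category = "") {
  data.frame(kind = "CDS", start = start, end = end, strand = strand,
             product = product, functional_category = category,
             stringsAsFactors = FALSE)
}

test_that("genome stats compute GC and union-rule coding density", {
  expect_equal(genome_stats(genome_record("g", "ATGC"))[["gc_percent"]], 50)
  expect_equal(genome_stats(genome_record("g", "GGCC"))[["gc_percent"]], 100)
  g <- genome_record("g", strrep("A", 100),
                     rbind(cds(1, 50), cds(41, 60)))
  st <- genome_stats(g)
  expect_equal(st[["coding_density_percent"]], 60)  # overlap merged
  expect_equal(st[["length_bp"]], 100)
  expect_error(genome_record("g", ""), "empty")
})

test_that("hit filtering applies inclusive thresholds on all three axes", {
  hits <- data.frame(
    query_id = letters[1:4], subject_id = letters[5:8],
    percent_identity = c(60, 49.9, 50, 60),
    query_coverage = c(90, 90, 85, 84.9),
    e_value = c(1e-12, 1e-12, 1e-9, 1e-12),
    bitscore = 100)
  kept <- filter_hits(hits)
  expect_identical(kept$query_id, c("a", "c"))  # boundary values kept
  expect_identical(filter_hits(hits, max_e = 1e-15)$query_id, character(0))
})

test_that("module location respects gaps and strand orientation", {
  feats <- rbind(
    cds(100, 200, "+", "endolysin", "lysis"),      # gene 1
    cds(300, 400, "+", "holin", "lysis"),          # gene 2
    cds(500, 600, "+", "hypothetical"),            # gap gene
    cds(700, 800, "+", "hypothetical"),            # gap gene
    cds(900, 1000, "+", "O-spanin", "lysis"),      # gene 5
    cds(1100, 1200, "+", "I-spanin", "lysis"))     # gene 6
  g <- genome_record("g", strrep("A", 2000), feats)
  runs <- locate_modules(g, "lysis", max_gap_genes = 2)
  expect_length(runs, 1)
  expect_equal(runs[[1]]$n_genes, 4)
  expect_equal(unname(runs[[1]]$span), c(100, 1200))
  # an opposite-strand member splits the run
  feats2 <- feats
  feats2$strand[5] <- "-"
  g2 <- genome_record("g", strrep("A", 2000), feats2)
  runs2 <- locate_modules(g2, "lysis", max_gap_genes = 2)
  expect_length(runs2, 3)
  # gap larger than allowed splits too
  runs3 <- locate_modules(g, "lysis", max_gap_genes = 1)
  expect_length(runs3, 2)
  expect_length(locate_modules(g, "absent_category"), 0)
})

test_that("pairwise identity is 100 for identical and tracks divergence", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(pairwise_identity(s, s, type = "dna")$identity, 100)
  m <- mutate_genome(genome_record("x", s), 0.10, seed = 8)
  pid <- pairwise_identity(s, m$genome$sequence, type = "dna")$identity
  realized <- 100 * (1 - m$n_substitutions / 300)
  expect_lt(abs(pid - realized), 2)
  p <- strrep("ACDE", 20)
  expect_equal(pairwise_identity(p, p, type = "protein")$identity, 100)
})

test_that("greedy clustering is centroid-greedy and deterministic", {
  set.seed(9)
  a <- rand_protein(80)
  b <- rand_protein(80)
  seqs <- c(s1 = a, s2 = a, s3 = b)
  cl <- greedy_cluster(seqs, id_threshold = 0.5)
  expect_length(cl, 2)
  # impossible threshold: every sequence its own cluster
  expect_length(greedy_cluster(seqs, id_threshold = 1.01), 3)
  # a generated family at ~80% identity collapses to one cluster at 0.5
  fam <- gen_protein_family(rand_protein(100), n = 20,
                            substitution_rate = 0.2, seed = 10)
  expect_length(greedy_cluster(fam, id_threshold = 0.5), 1)
})

test_that("pan-genome partition follows the core/accessory/unique rules", {
  clusters <- list(
    list(centroid_id = "a1", member_ids = c("a1", "b1", "c1")),
    list(centroid_id = "a2", member_ids = c("a2", "b2")),
    list(centroid_id = "c2", member_ids = "c2"))
  genome_of <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
                 c1 = "C", c2 = "C")
  pg <- pan_genome(clusters, genome_of, n_genomes = 3)
  expect_equal(pg$core_count, 1)
  expect_equal(pg$accessory_count, 1)
  expect_equal(pg$unique_count, 1)
  expect_equal(pg$core_count + pg$accessory_count + pg$unique_count,
               pg$n_clusters)
})

test_that("removing one genome never increases the core count", {
  set.seed(21)
  genomes <- c("A", "B", "C", "D")
  clusters <- lapply(1:12, function(i) {
    gs <- sample(genomes, sample(1:4, 1))
    list(centroid_id = paste0("c", i),
         member_ids = paste0(gs, "_", i))
  })
  genome_of <- unlist(lapply(clusters, function(cl) {
    stats::setNames(sub("_.*", "", cl$member_ids), cl$member_ids)
  }))
  full <- pan_genome(clusters, genome_of, 4)
  drop_d <- lapply(clusters, function(cl) {
    cl$member_ids <- cl$member_ids[genome_of[cl$member_ids] != "D"]
    cl
  })
  drop_d <- drop_d[vapply(drop_d, function(cl) length(cl$member_ids) > 0,
                          TRUE)]
  reduced <- pan_genome(drop_d, genome_of, 3)
  # every cluster spanning all four genomes still spans the remaining
  # three, so the core can only grow or hold when a genome is dropped;
  # equivalently, adding a genome never increases the core count
  expect_lte(full$core_count, reduced$core_count)
})

test_that("fragment ANI recovers divergence, is self-100 and floors random", {
  g <- gen_genome(6000, seed = 30)
  expect_equal(orthoani(g, g, fragment_len = 1020)$ani, 100)
  m <- mutate_genome(g, 0.05, seed = 31)
  a <- orthoani(g, m$genome, fragment_len = 1020)
  expect_lt(abs(a$ani - 95), 1)
  # symmetric within 0.5 points by reciprocal construction
  a_rev <- orthoani(m$genome, g, fragment_len = 1020)
  expect_lt(abs(a$ani - a_rev$ani), 0.5)
  unrelated <- gen_genome(6000, seed = 32)
  u <- orthoani(g, unrelated, fragment_len = 1020)
  expect_true(is.na(u$ani))   # undefined, distinct from an error
  expect_equal(u$n_pairs, 0L)
  short <- gen_genome(1500, seed = 33)
  expect_error(orthoani(short, g), "too short")
})

test_that("expected ANI is monotone non-increasing in substitution rate", {
  rates <- c(0, 0.02, 0.05, 0.10)
  for (seed in 1:3) {
    g <- gen_genome(5000, seed = 100 + seed)
    anis <- vapply(seq_along(rates), function(k) {
      m <- mutate_genome(g, rates[k], seed = 200 + seed * 10 + k)
      orthoani(g, m$genome, fragment_len = 1020)$ani
    }, 0)
    expect_true(all(diff(anis) <= 0.5))  # allow sampling jitter
    expect_lt(max(abs(anis - 100 * (1 - rates))), 1)
  }
})
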