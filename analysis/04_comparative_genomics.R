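#!/usr/bin/env Rscript
# Stage 4: comparative genomics. Genome statistics and lysis-module
# detection on the bundled annotated genome, fragment-based ANI against
# the simulated diverged genomes, greedy clustering + pan-genome
# partition of a synthetic gene set, and a UPGMA tree from the ANI
# distance matrix.

suppressMessages(library(phagekit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 37
dir.create("results", showWarnings = FALSE)

gbk <- read_genbank(system.file("extdata", "synthetic_phage.gbk",
                                package = "phagekit"))
st <- genome_stats(gbk)
message(sprintf("annotated genome %s: %d bp, GC %.1f%%, coding density %.1f%%",
                gbk$id, st["length_bp"], st["gc_percent"],
                st["coding_density_percent"]))
mods <- locate_modules(gbk, "lysis", max_gap_genes = 2)
for (m in mods) {
  message(sprintf("lysis module: %d gene(s) [%s] on strand %s, span %d..%d",
                  m$n_genes, paste(m$products, collapse = ", "),
                  m$strand, m$span["start"], m$span["end"]))
}

g <- genome_record("simgenome",
                   read_fasta("results/simulated/genome.fna", "dna")[[1]])
rows <- list()
for (rate in c(2, 5, 10)) {
  path <- sprintf("results/simulated/genome_div%02d.fna", rate)
  gm <- genome_record(sprintf("div%02d", rate),
                      read_fasta(path, "dna")[[1]])
  a <- orthoani(g, gm, fragment_len = 1020)
  rows[[length(rows) + 1]] <- data.frame(
    divergence_percent = rate, ani_percent = a$ani,
    reciprocal_pairs = a$n_pairs)
  message(sprintf("ANI at %d%% divergence: %.2f%% (%d reciprocal pairs)",
                  rate, a$ani, a$n_pairs))
}
ani_tab <- do.call(rbind, rows)
utils::write.csv(ani_tab, "results/ani_by_divergence.csv",
                 row.names = FALSE)

# pan-genome over three synthetic genomes sharing gene families
set.seed(seed)
genomes <- c("gA", "gB", "gC")
seqs <- character(); genome_of <- character()
for (i in 1:8) {
  base <- paste(sample(phagekit:::AA_STANDARD, 90, TRUE), collapse = "")
  fam <- gen_protein_family(base, n = 3, substitution_rate = 0.15,
                            seed = seed + i)
  gs <- sample(genomes, sample(1:3, 1))
  ids <- sprintf("f%d_%s", i, gs)
  seqs[ids] <- unname(fam[-1][seq_along(gs)])
  genome_of[ids] <- gs
}
pg <- pan_genome(greedy_cluster(seqs, 0.5), genome_of, length(genomes))
print(pg)
utils::write.csv(data.frame(class = c("core", "accessory", "unique"),
                            count = c(pg$core_count, pg$accessory_count,
                                      pg$unique_count)),
                 "results/pan_genome_counts.csv", row.names = FALSE)

# UPGMA on ANI-derived distances (100 - ANI), including self
labels <- c("simgenome", paste0("div", sprintf("%02d", c(2, 5, 10))))
d <- matrix(0, 4, 4, dimnames = list(labels, labels))
seq_list <- c(list(g$sequence),
              lapply(c(2, 5, 10), function(r) {
                read_fasta(sprintf("results/simulated/genome_div%02d.fna", r),
                           "dna")[[1]]
              }))
for (i in 1:3) for (j in (i + 1):4) {
  a <- orthoani(genome_record("a", seq_list[[i]]),
                genome_record("b", seq_list[[j]]), fragment_len = 1020)
  d[i, j] <- d[j, i] <- 100 - a$ani
}
nwk <- upgma(d)
write_newick(nwk, "results/genome_upgma.nwk")
message("UPGMA tree: ", nwk)
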