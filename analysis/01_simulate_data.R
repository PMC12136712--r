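#!/usr/bin/env Rscript
# Stage 1: simulate every input the downstream stages consume.
# Two-family tail-protein proteomes (separable by composition), a genome
# plus substituted copies at controlled divergence, a study-condition
# one-step growth curve, a two-chain complex with a planted interface,
# and an MSA with a fixed conservation profile.

suppressMessages(library(phagekit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 37

dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

pr <- gen_proteomes(disjoint_family_profiles(seed = seed),
                    genomes_per_family = 40, seed = seed)
write_fasta(stats::setNames(pr$records$sequence, pr$records$id),
            "results/simulated/tail_proteins.faa")
utils::write.csv(data.frame(genome_id = names(pr$label_map),
                            family = unname(pr$label_map)),
                 "results/simulated/family_labels.csv", row.names = FALSE)
message(sprintf("proteomes: %d tail proteins from %d genomes, 2 families",
                nrow(pr$records), length(pr$label_map)))

g <- gen_genome(10000, seed = seed + 1, id = "simgenome")
write_fasta(stats::setNames(g$sequence, g$id),
            "results/simulated/genome.fna", type = "dna")
for (rate in c(0.02, 0.05, 0.10)) {
  m <- mutate_genome(g, rate, seed = seed + 2)
  write_fasta(stats::setNames(m$genome$sequence, m$genome$id),
              sprintf("results/simulated/genome_div%02.0f.fna", 100 * rate),
              type = "dna")
  message(sprintf("genome at %.0f%% divergence: %d realized substitutions",
                  100 * rate, m$n_substitutions))
}

gcv <- gen_growth_curve(seed = seed + 3)  # study conditions: burst 146
utils::write.csv(data.frame(time_min = gcv$curve$times,
                            pfu_per_ml = gcv$curve$titers),
                 "results/simulated/growth_curve.csv", row.names = FALSE)

gen_complex("results/simulated/complex.pdb", n_contacts = 25,
            n_decoys = 25, seed = seed + 4)

msa <- gen_msa(n_seqs = 50, length = 40,
               conservation_profile = c(rep(0.95, 20), rep(0.5, 20)),
               gap_rate = 0.05, seed = seed + 5)
write_fasta(msa$msa, "results/simulated/rbp_alignment.afa")

message("simulated inputs written under results/simulated/")
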