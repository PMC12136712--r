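#!/usr/bin/env Rscript
# Stage 2: physicochemical featurization of the simulated tail proteins.
# Each protein becomes a 431-dimensional descriptor vector (amino-acid
# composition, dipeptide composition, and 11 ProtParam-style scalars).

suppressMessages(library(phagekit))

seqs <- read_fasta("results/simulated/tail_proteins.faa")
labels <- utils::read.csv("results/simulated/family_labels.csv")
rec <- protein_records(id = names(seqs), sequence = unname(seqs),
                       product = "tail protein",
                       genome_id = sub("_p[0-9]+$", "", names(seqs)))

mat <- featurize_records(rec)
write_feature_matrix(mat, "results/feature_matrix.csv")
message(sprintf("featurized %d proteins -> %d descriptors each",
                nrow(mat), ncol(mat)))
message(sprintf("mean GRAVY %.2f, mean pI %.2f, mean length %.0f",
                mean(mat[, "gravy"]), mean(mat[, "isoelectric_point"]),
                mean(mat[, "length"])))
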