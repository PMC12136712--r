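#!/usr/bin/env Rscript
# Stage 6: structural interface and conservation analysis. Interface
# residues of the simulated two-chain complex at 5 Angstroms, contiguous
# interaction regions (>= 6 consecutive residues), per-column
# conservation of the simulated RBP alignment, a sequence-logo matrix,
# and a PCA embedding of the tail-protein feature matrix.

suppressMessages(library(phagekit))
dir.create("results", showWarnings = FALSE)

model <- read_structure("results/simulated/complex.pdb")
iface <- interface_residues(model, "A", "B", cutoff = 5.0)
message(sprintf("interface: %d chain-A residues within 5 A of chain B",
                nrow(iface)))
utils::write.csv(iface, "results/interface_residues.csv",
                 row.names = FALSE)
regions <- contiguous_regions(iface$resno, min_len = 6)
message(sprintf("contiguous regions (>=6 consecutive residues): %d",
                nrow(regions)))
utils::write.csv(regions, "results/interface_regions.csv",
                 row.names = FALSE)

msa <- read_msa("results/simulated/rbp_alignment.afa")
prof <- column_profile(msa, min_occupancy = 0.5)
utils::write.csv(prof, "results/column_profile.csv", row.names = FALSE)
message(sprintf(paste0("alignment: %d columns, mean conservation %.2f ",
                       "(first half %.2f, second half %.2f)"),
                nrow(prof), mean(prof$conservation),
                mean(prof$conservation[1:20]),
                mean(prof$conservation[21:40])))

lg <- logo_matrix(msa, positions = 1:20)
utils::write.csv(data.frame(position = lg$positions, lg$frequencies,
                            ic_bits = lg$ic_bits,
                            gap_fraction = lg$gap_fraction),
                 "results/logo_matrix.csv", row.names = FALSE)

mat <- read_feature_matrix("results/feature_matrix.csv")
p <- pca_embed(mat, n_components = 2)
utils::write.csv(data.frame(id = rownames(p$scores), p$scores),
                 "results/pca_scores.csv", row.names = FALSE)
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * p$explained_variance[1],
                100 * p$explained_variance[2]))
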