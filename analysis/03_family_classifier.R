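#!/usr/bin/env Rscript
# Stage 3: random-forest family classification of tail proteins with
# stratified 10-fold cross-validation, then a genome-level family call
# by majority vote over one genome's tail proteins.

suppressMessages(library(phagekit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 37

seqs <- read_fasta("results/simulated/tail_proteins.faa")
labels <- utils::read.csv("results/simulated/family_labels.csv")
label_map <- stats::setNames(labels$family, labels$genome_id)
rec <- protein_records(id = names(seqs), sequence = unname(seqs),
                       product = "tail protein",
                       genome_id = sub("_p[0-9]+$", "", names(seqs)))

ds <- assemble_dataset(select_tail_proteins(rec), label_map)
cv <- stratified_cv(ds, k = 10, n_estimators = 1000, seed = seed)
print(cv)

dir.create("results", showWarnings = FALSE)
utils::write.csv(as.data.frame.matrix(cv$confusion_matrix),
                 "results/confusion_matrix.csv")
jsonlite::write_json(list(overall_accuracy = cv$overall_accuracy,
                          fold_accuracies = cv$fold_accuracies,
                          per_class_recall = as.list(cv$per_class_recall),
                          k = cv$k, seed = cv$seed),
                     "results/cv_report.json", auto_unbox = TRUE,
                     pretty = TRUE)

fit <- train_forest(ds, n_estimators = 1000, seed = seed)
one_genome <- rec[rec$genome_id == rec$genome_id[1], ]
call <- predict_genome_family(fit, one_genome)
message(sprintf("genome %s -> family %s (vote %.2f over %d tail proteins)",
                one_genome$genome_id[1], call$family,
                max(call$vote_fractions), call$n_proteins))
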