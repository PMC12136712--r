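make_benchmark <- function(genomes_per_family = 8, tail_count = 3,
                           seed = 37) {
  profiles <- disjoint_family_profiles(seed = seed,
                                       length_range = c(60, 120),
                                       tail_count = tail_count)
  gen_proteomes(profiles, genomes_per_family = genomes_per_family,
                seed = seed)
}

test_that("tail-protein selection is case-insensitive substring matching", {
  rec <- protein_records(
    id = c("a", "b", "c", "d"),
    sequence = strrep("ADKV", 20),
    product = c("Tail fiber protein", "tail completion protein",
                "portal protein", "major capsid protein"))
  sel <- select_tail_proteins(rec)
  expect_identical(sel$id, c("a", "b"))
  expect_warning(select_tail_proteins(rec[3:4, ]), "no tail")
})

test_that("dataset assembly featurizes, drops unlabeled genomes, keeps order", {
  pr <- make_benchmark(genomes_per_family = 2)
  ds <- assemble_dataset(pr$records, pr$label_map)
  expect_equal(nrow(ds$features), nrow(pr$records))
  expect_identical(ds$protein_ids, pr$records$id)
  expect_equal(ncol(ds$features), 431)
  # unlabeled genome dropped with a warning
  lm2 <- pr$label_map[-1]
  expect_warning(ds2 <- assemble_dataset(pr$records, lm2), "unlabeled")
  expect_equal(nrow(ds2$features),
               sum(pr$records$genome_id %in% names(lm2)))
  # single family is untrainable
  one <- pr$label_map[pr$label_map == pr$label_map[1]]
  expect_error(suppressWarnings(assemble_dataset(pr$records, one)),
               "untrainable")
})

test_that("forest training is reproducible and fits separable data", {
  pr <- make_benchmark()
  ds <- assemble_dataset(pr$records, pr$label_map)
  fit1 <- train_forest(ds, n_estimators = 100, seed = 37)
  fit2 <- train_forest(ds, n_estimators = 100, seed = 37)
  p1 <- predict(fit1, ds$features)
  expect_identical(p1, predict(fit2, ds$features))
  expect_equal(mean(p1 == ds$labels), 1)
})

test_that("stratified CV balances folds, never leaks, and reports honestly", {
  pr <- make_benchmark()
  ds <- assemble_dataset(pr$records, pr$label_map)
  k <- 4
  fold <- phagekit:::stratified_folds(ds$labels, k, seed = 37)
  expect_true(all(tabulate(fold, k) > 0))
  expect_length(fold, length(ds$labels))  # every sample in exactly one fold
  for (cl in levels(ds$labels)) {
    counts <- tabulate(fold[ds$labels == cl], k)
    expect_lte(diff(range(counts)), 1)  # within one sample of balance
  }
  cv <- stratified_cv(ds, k = k, n_estimators = 100, seed = 37)
  expect_equal(cv$overall_accuracy,
               sum(diag(cv$confusion_matrix)) / sum(cv$confusion_matrix))
  expect_equal(unname(rowSums(cv$confusion_matrix)),
               unname(as.vector(table(ds$labels))))
  expect_error(stratified_cv(ds, k = 1), "k must be")
})

test_that("CV on permutation-null labels sits at chance", {
  # 3 balanced classes, n=300: accuracy should land within 3 SE of 1/3
  set.seed(41)
  X <- matrix(rnorm(300 * 10), 300, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  ds <- list(features = X,
             labels = factor(rep(c("a", "b", "c"), each = 100)),
             protein_ids = as.character(1:300),
             genome_ids = as.character(1:300))
  cv <- stratified_cv(ds, k = 5, n_estimators = 100, seed = 37)
  se <- sqrt((1 / 3) * (2 / 3) / 300)
  expect_lt(abs(cv$overall_accuracy - 1 / 3), 3 * se)
})

test_that("duplicated points per class are classified perfectly", {
  X <- rbind(matrix(0, 20, 5), matrix(10, 20, 5))
  colnames(X) <- paste0("f", 1:5)
  ds <- list(features = X, labels = factor(rep(c("lo", "hi"), each = 20)),
             protein_ids = as.character(1:40),
             genome_ids = as.character(1:40))
  cv <- stratified_cv(ds, k = 4, n_estimators = 50, seed = 37)
  expect_equal(cv$overall_accuracy, 1)
})

test_that("genome-level family call aggregates votes with deterministic ties", {
  pr <- make_benchmark()
  ds <- assemble_dataset(pr$records, pr$label_map)
  fit <- train_forest(ds, n_estimators = 200, seed = 37)
  one_genome <- pr$records[pr$records$genome_id == pr$records$genome_id[1], ]
  call <- predict_genome_family(fit, one_genome)
  expect_identical(call$family, unname(pr$label_map[one_genome$genome_id[1]]))
  expect_equal(call$n_proteins, nrow(one_genome))
  expect_equal(sum(call$vote_fractions), 1)
  empty <- pr$records[0, ]
  expect_error(predict_genome_family(fit, empty), "unclassifiable")
})

test_that("small CV accuracy is stable in the number of trees", {
  pr <- make_benchmark()
  ds <- assemble_dataset(pr$records, pr$label_map)
  acc100 <- stratified_cv(ds, k = 4, n_estimators = 100,
                          seed = 37)$overall_accuracy
  acc500 <- stratified_cv(ds, k = 4, n_estimators = 500,
                          seed = 37)$overall_accuracy
  expect_gte(acc500, acc100 - 0.02)
})
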