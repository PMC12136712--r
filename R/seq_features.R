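#' Protein record table
#'
#' Builds the canonical protein record table used throughout the package:
#' one row per protein with its identifier, free-text product annotation,
#' amino-acid sequence, source genome and (optionally) a family label.
#'
#' @param id character vector of unique protein identifiers.
#' @param sequence character vector of amino-acid sequences (sanitized or
#'   raw; see [sanitize_sequence()]).
#' @param product free-text product annotations (default empty).
#' @param genome_id source genome identifiers (default empty).
#' @param family_label taxonomic family labels (default empty).
#' @return data.frame with columns `id`, `product`, `sequence`,
#'   `genome_id`, `family_label`.
#' @export
protein_records <- function(id, sequence, product = "", genome_id = "",
                            family_label = "") {
  if (anyDuplicated(id)) stop("protein ids must be unique within a dataset")
  data.frame(id = as.character(id),
             product = rep_len(as.character(product), length(id)),
             sequence = as.character(sequence),
             genome_id = rep_len(as.character(genome_id), length(id)),
             family_label = rep_len(as.character(family_label), length(id)),
             stringsAsFactors = FALSE)
}

#' Sanitize a raw amino-acid sequence
#'
#' Uppercases, strips stop (`*`) and gap (`-`) symbols, and removes
#' ambiguity or nonstandard letters (B, Z, X, U, O, J) with a warning.
#' Records retaining fewer than `min_length` standard residues are
#' rejected: dipeptide statistics are meaningless on fragments.
#'
#' @param raw_sequence character scalar, possibly containing lowercase,
#'   gaps, stops and ambiguity codes.
#' @param min_length minimum number of standard residues after cleaning
#'   (default 30).
#' @return cleaned uppercase sequence of the 20 standard letters.
#' @export
sanitize_sequence <- function(raw_sequence, min_length = 30) {
  stopifnot(is.character(raw_sequence), length(raw_sequence) == 1L)
  s <- toupper(raw_sequence)
  s <- gsub("[*-]", "", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  keep <- chars %in% AA_STANDARD
  if (any(!keep)) {
    warning(sprintf("removed %d nonstandard residue(s): %s",
                    sum(!keep), paste(unique(chars[!keep]), collapse = "")))
    chars <- chars[keep]
  }
  if (length(chars) < min_length) {
    stop(sprintf("sequence too short/degenerate: %d standard residues (< %d)",
                 length(chars), min_length))
  }
  paste(chars, collapse = "")
}

aa_counts <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- table(factor(chars, levels = AA_STANDARD))
  as.numeric(tab)
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 standard residues; sums to 1.
#'
#' @param sequence sanitized amino-acid sequence.
#' @return named numeric vector of 20 fractions (`aac_A` .. `aac_Y`).
#' @export
aa_composition <- function(sequence) {
  n <- aa_counts(sequence)
  out <- n / sum(n)
  names(out) <- paste0("aac_", AA_STANDARD)
  out
}

#' Dipeptide composition
#'
#' Overlapping dipeptide counts divided by (L - 1); sums to 1 for any
#' sequence of length >= 2. The 400 entries are ordered first residue
#' fastest-changing last, i.e. `dpc_AA, dpc_AC, ..., dpc_YY`.
#'
#' @param sequence sanitized amino-acid sequence (length >= 2).
#' @return named numeric vector of 400 fractions.
#' @export
dipeptide_composition <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  stopifnot(L >= 2)
  dp <- paste0(chars[-L], chars[-1])
  levels <- as.vector(t(outer(AA_STANDARD, AA_STANDARD, paste0)))
  out <- as.numeric(table(factor(dp, levels = levels))) / (L - 1)
  names(out) <- paste0("dpc_", levels)
  out
}

#' Molecular weight (average masses)
#'
#' Sum of average residue masses plus one water (peptide-bond
#' bookkeeping: a chain of n residues has n - 1 bonds, so exactly one
#' water is added regardless of length).
#'
#' @param sequence amino-acid sequence.
#' @return mass in Daltons.
#' @export
molecular_weight <- function(sequence) {
  n <- aa_counts(sequence)
  sum(n * RESIDUE_MASS[AA_STANDARD]) + WATER_MASS
}

#' Aromaticity
#'
#' Fraction of aromatic residues (F, W, Y).
#'
#' @param sequence amino-acid sequence.
#' @return fraction in [0, 1].
#' @export
aromaticity <- function(sequence) {
  n <- aa_counts(sequence)
  names(n) <- AA_STANDARD
  (n["F"] + n["W"] + n["Y"])[[1]] / sum(n)
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic:
#' II = (10 / L) * sum over consecutive pairs of DIWV weights.
#' Values above 40 predict in-vitro instability.
#'
#' @param sequence amino-acid sequence (length >= 2).
#' @return instability score.
#' @export
instability_index <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  stopifnot(L >= 2)
  (10 / L) * sum(DIWV[cbind(chars[-L], chars[-1])])
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the free N-terminus, C-terminus, and
#' the ionizable side chains (acidic: D, E, C, Y; basic: K, R, H), using
#' the Bjellqvist pKa set (see `PKA_POSITIVE` / `PKA_NEGATIVE` in the
#' constants table). Strictly decreasing in pH.
#'
#' @param sequence amino-acid sequence.
#' @param pH solution pH.
#' @return net charge (elementary charges).
#' @export
charge_at_pH <- function(sequence, pH) {
  n <- aa_counts(sequence)
  names(n) <- AA_STANDARD
  pos_n <- c(Nterm = 1, n[c("K", "R", "H")])
  neg_n <- c(Cterm = 1, n[c("D", "E", "C", "Y")])
  pos <- sum(pos_n / (1 + 10^(pH - PKA_POSITIVE)))
  neg <- sum(neg_n / (1 + 10^(PKA_NEGATIVE - pH)))
  pos - neg
}

#' Isoelectric point
#'
#' pH at which the net charge is zero, found by bisection on [0, 14]
#' (charge is strictly decreasing in pH so the root is unique).
#'
#' @param sequence amino-acid sequence.
#' @param tol charge tolerance at convergence (default 1e-4).
#' @return pI in [0, 14].
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    q <- charge_at_pH(sequence, mid)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues. Positive values
#' indicate hydrophobic proteins.
#'
#' @param sequence amino-acid sequence.
#' @return GRAVY score.
#' @export
gravy <- function(sequence) {
  n <- aa_counts(sequence)
  sum(n * KYTE_DOOLITTLE[AA_STANDARD]) / sum(n)
}

#' Secondary-structure fractions
#'
#' Fractions of residues belonging to the ProtParam helix, turn and
#' sheet residue sets. The sets overlap by construction (L is in both
#' helix and sheet), so the three fractions need not sum to 1.
#'
#' @param sequence amino-acid sequence.
#' @return named numeric vector `frac_helix`, `frac_turn`, `frac_sheet`.
#' @export
ss_fractions <- function(sequence) {
  n <- aa_counts(sequence)
  names(n) <- AA_STANDARD
  L <- sum(n)
  c(frac_helix = sum(n[SS_HELIX]) / L,
    frac_turn  = sum(n[SS_TURN]) / L,
    frac_sheet = sum(n[SS_SHEET]) / L)
}

#' Molar extinction coefficient at 280 nm (reduced cysteines)
#'
#' 5500 * nW + 1490 * nY; no cystine term since cysteines are assumed
#' reduced.
#'
#' @param sequence amino-acid sequence.
#' @return extinction coefficient in M^-1 cm^-1.
#' @export
extinction_reduced <- function(sequence) {
  n <- aa_counts(sequence)
  names(n) <- AA_STANDARD
  (EXTINCTION_TRP * n["W"] + EXTINCTION_TYR * n["Y"])[[1]]
}

#' Names of the 431 feature descriptors, in canonical order
#'
#' 20 amino-acid composition fractions, 400 dipeptide composition
#' fractions, then 11 scalar descriptors. The order is frozen: feature
#' matrices serialize and round-trip against it.
#'
#' @return character vector of length 431.
#' @export
feature_names <- function() {
  dp <- as.vector(t(outer(AA_STANDARD, AA_STANDARD, paste0)))
  c(paste0("aac_", AA_STANDARD),
    paste0("dpc_", dp),
    "length", "mol_weight_Da", "aromaticity", "instability_index",
    "isoelectric_point", "gravy", "charge_pH7",
    "frac_helix", "frac_turn", "frac_sheet", "extinction_reduced_M-1cm-1")
}

#' Featurize one protein sequence
#'
#' Computes the full 431-dimensional physicochemical descriptor vector:
#' amino-acid composition (20), dipeptide composition (400), and the
#' scalar descriptors length, molecular weight, aromaticity, instability
#' index, isoelectric point, GRAVY, net charge at pH 7, helix/turn/sheet
#' fractions, and the reduced-cysteine extinction coefficient.
#' Deterministic: identical sequences give identical vectors.
#'
#' @param sequence sanitized amino-acid sequence.
#' @return named numeric vector of length 431 (order = [feature_names()]).
#' @export
featurize <- function(sequence) {
  out <- c(aa_composition(sequence),
           dipeptide_composition(sequence),
           length = nchar(sequence),
           mol_weight_Da = molecular_weight(sequence),
           aromaticity = aromaticity(sequence),
           instability_index = instability_index(sequence),
           isoelectric_point = isoelectric_point(sequence),
           gravy = gravy(sequence),
           charge_pH7 = charge_at_pH(sequence, 7),
           ss_fractions(sequence),
           extinction_reduced(sequence))
  names(out) <- feature_names()
  out
}

#' Featurize a protein record table
#'
#' Sanitizes each sequence and stacks the per-protein descriptor vectors
#' into a feature matrix. Records failing sanitization (too short or
#' degenerate) are dropped with a warning naming them.
#'
#' @param records protein record table (see [protein_records()]).
#' @param min_length minimum sanitized length (default 30).
#' @return numeric matrix, one row per retained protein (rownames = ids),
#'   431 named columns.
#' @export
featurize_records <- function(records, min_length = 30) {
  rows <- vector("list", nrow(records))
  kept <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- tryCatch(sanitize_sequence(records$sequence[i], min_length),
                  error = function(e) NULL)
    if (!is.null(s)) {
      rows[[i]] <- featurize(s)
      kept[i] <- TRUE
    }
  }
  if (any(!kept)) {
    warning(sprintf("dropped %d record(s) failing sanitization: %s",
                    sum(!kept),
                    paste(records$id[!kept], collapse = ", ")))
  }
  mat <- do.call(rbind, rows[kept])
  rownames(mat) <- records$id[kept]
  mat
}

#' Write a feature matrix to CSV with a constants sidecar
#'
#' The CSV has an `id` column followed by the 431 descriptor columns.
#' The JSON sidecar records the descriptor constants in force (pKa set,
#' hydropathy scale, secondary-structure sets, DIWV provenance) so a
#' matrix is interpretable without the generating session.
#'
#' @param mat feature matrix from [featurize_records()].
#' @param path output CSV path; the sidecar is written to
#'   `<path>.constants.json`.
#' @return invisibly, the CSV path.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    pKa_positive = as.list(PKA_POSITIVE),
    pKa_negative = as.list(PKA_NEGATIVE),
    hydropathy_scale = "Kyte-Doolittle",
    ss_sets = list(helix = SS_HELIX, turn = SS_TURN, sheet = SS_SHEET),
    instability_weights = "Guruprasad DIWV",
    masses = "average residue masses + one water",
    extinction = list(W = EXTINCTION_TRP, Y = EXTINCTION_TYR)
  )
  jsonlite::write_json(sidecar, paste0(path, ".constants.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix CSV back to a matrix
#'
#' @param path CSV written by [write_feature_matrix()].
#' @return numeric matrix with protein-id rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$id
  mat
}
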