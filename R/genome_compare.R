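#' Genome record
#'
#' A nucleotide sequence plus its annotated features. Coordinates are
#' 1-based inclusive (GenBank convention); a linear contig is assumed
#' (no wrap-around features).
#'
#' @param id genome identifier.
#' @param sequence nucleotide string (ACGT, uppercased on input).
#' @param features data.frame with columns `kind` (CDS/tRNA/other),
#'   `start`, `end`, `strand` (+/-), `product`, `functional_category`;
#'   may be empty.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = NULL) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty genome sequence")
  if (is.null(features)) {
    features <- data.frame(kind = character(), start = integer(),
                           end = integer(), strand = character(),
                           product = character(),
                           functional_category = character(),
                           stringsAsFactors = FALSE)
  }
  if (nrow(features)) {
    stopifnot(all(features$kind %in% c("CDS", "tRNA", "other")),
              all(features$strand %in% c("+", "-")),
              all(features$start >= 1),
              all(features$start <= features$end),
              all(features$end <= nchar(sequence)))
  }
  structure(list(id = id, sequence = sequence, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record %s: %d bp, %d feature(s)\n",
              x$id, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Basic genome statistics
#'
#' Length, GC content and coding density. Coding density is the length
#' of the union of CDS intervals (overlaps merged) over the genome
#' length, as a percentage.
#'
#' @param g genome_record.
#' @return named numeric vector `length_bp`, `gc_percent`,
#'   `coding_density_percent`.
#' @export
genome_stats <- function(g) {
  len <- nchar(g$sequence)
  chars <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  gc <- 100 * sum(chars %in% c("G", "C")) / len
  cds <- g$features[g$features$kind == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = cds$start, end = cds$end))
    coding <- 100 * sum(IRanges::width(ir)) / len
  } else {
    coding <- 0
  }
  c(length_bp = len, gc_percent = gc, coding_density_percent = coding)
}

#' Filter similarity hits at identity / coverage / e-value thresholds
#'
#' Keeps hits with identity >= `min_identity`, coverage >=
#' `min_coverage` and e-value <= `max_e`; all boundaries inclusive.
#' Defaults are the conventional BLASTp screening thresholds
#' (50 % identity, 85 % coverage, 1e-9).
#'
#' @param hits data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `query_coverage`, `e_value` (and any others,
#'   preserved).
#' @param min_identity,min_coverage percent thresholds.
#' @param max_e e-value ceiling.
#' @return filtered data.frame, row order preserved.
#' @export
filter_hits <- function(hits, min_identity = 50, min_coverage = 85,
                        max_e = 1e-9) {
  keep <- hits$percent_identity >= min_identity &
    hits$query_coverage >= min_coverage &
    hits$e_value <= max_e
  hits[keep, , drop = FALSE]
}

#' Locate co-oriented functional gene modules
#'
#' Finds maximal runs of annotated genes sharing a functional category
#' and strand, allowing up to `max_gap_genes` intervening genes of other
#' categories between consecutive members. This is the adjacency logic
#' used to call lysis cassettes (endolysin, holin, spanins colocalized
#' and co-oriented).
#'
#' @param g genome_record whose features carry `functional_category`.
#' @param category category to search for (e.g. "lysis").
#' @param max_gap_genes maximum intervening genes tolerated (default 2).
#' @return list of runs; each run is a list with `feature_idx` (row
#'   indices into `g$features`), `products`, `strand`, `span`
#'   (start, end in bp), `n_genes`.
#' @export
locate_modules <- function(g, category, max_gap_genes = 2) {
  f <- g$features
  ord <- order(f$start)
  f <- f[ord, , drop = FALSE]
  hit <- which(f$functional_category == category)
  if (!length(hit)) return(list())
  runs <- list()
  cur <- hit[1]
  for (i in hit[-1]) {
    gap <- i - cur[length(cur)] - 1L
    same_strand <- f$strand[i] == f$strand[cur[1]]
    if (gap <= max_gap_genes && same_strand) {
      cur <- c(cur, i)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- i
    }
  }
  runs[[length(runs) + 1L]] <- cur
  lapply(runs, function(idx) {
    list(feature_idx = ord[idx],
         products = f$product[idx],
         strand = f$strand[idx[1]],
         span = c(start = min(f$start[idx]), end = max(f$end[idx])),
         n_genes = length(idx))
  })
}

#' Global pairwise percent identity
#'
#' Needleman-Wunsch global alignment with affine gaps (match +2,
#' mismatch -1, gap open -4, gap extend -1 by default); identity is
#' matches over alignment columns (gap columns included), on the 0-100
#' scale. Works on nucleotide or amino-acid sequences (`type`).
#'
#' @param seq_a,seq_b character sequences.
#' @param type "dna" or "protein".
#' @param match,mismatch,gap_open,gap_extend alignment scores (signs as
#'   conventionally written; penalties negative).
#' @return list: `identity` (percent), `score`, `alignment_length`.
#' @export
pairwise_identity <- function(seq_a, seq_b, type = c("dna", "protein"),
                              match = 2, mismatch = -1,
                              gap_open = -4, gap_extend = -1) {
  type <- match.arg(type)
  if (type == "dna") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = TRUE)
    a <- Biostrings::DNAString(seq_a)
    b <- Biostrings::DNAString(seq_b)
  } else {
    letters <- Biostrings::AA_STANDARD
    mat <- matrix(mismatch, length(letters), length(letters),
                  dimnames = list(letters, letters))
    diag(mat) <- match
    a <- Biostrings::AAString(seq_a)
    b <- Biostrings::AAString(seq_b)
  }
  aln <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                       gapOpening = abs(gap_open),
                                       gapExtension = abs(gap_extend),
                                       type = "global")
  list(identity = 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln),
       score = Biostrings::score(aln),
       alignment_length = Biostrings::nchar(aln))
}

#' Greedy centroid clustering of sequences
#'
#' USEARCH-style centroid-greedy clustering: sequences are processed
#' longest-first (ties by input order); each sequence joins the first
#' existing centroid it matches at >= `id_threshold` global identity,
#' else founds a new cluster. Deterministic given the input.
#'
#' @param seqs named character vector of sequences (names are ids).
#' @param id_threshold identity threshold as a fraction (default 0.5).
#' @param type "protein" (default) or "dna".
#' @return list of clusters; each has `centroid_id` and `member_ids`
#'   (centroid included).
#' @export
greedy_cluster <- function(seqs, id_threshold = 0.5,
                           type = c("protein", "dna")) {
  type <- match.arg(type)
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ord <- order(-nchar(seqs))  # stable: ties keep input order
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      cen <- clusters[[k]]$centroid_seq
      pid <- pairwise_identity(seqs[[i]], cen, type = type)$identity / 100
      if (pid >= id_threshold) {
        clusters[[k]]$member_ids <- c(clusters[[k]]$member_ids, names(seqs)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(centroid_id = names(seqs)[i],
             centroid_seq = seqs[[i]],
             member_ids = names(seqs)[i])
    }
  }
  lapply(clusters, function(cl) cl[c("centroid_id", "member_ids")])
}

#' Pan-genome partition of gene clusters
#'
#' Classifies each cluster by the set of genomes it spans: core = in all
#' `n_genomes`, unique = in exactly one, accessory = in between.
#'
#' @param clusters list from [greedy_cluster()].
#' @param genome_of named character vector mapping member id -> genome id.
#' @param n_genomes total number of genomes in the comparison.
#' @return list of class `pan_genome_summary`: `clusters` (with
#'   `genome_set` and `class` added), `core_count`, `accessory_count`,
#'   `unique_count`, `n_clusters`.
#' @export
pan_genome <- function(clusters, genome_of, n_genomes) {
  annotated <- lapply(clusters, function(cl) {
    gs <- sort(unique(unname(genome_of[cl$member_ids])))
    cl$genome_set <- gs
    cl$class <- if (length(gs) == n_genomes) "core"
      else if (length(gs) == 1) "unique"
      else "accessory"
    cl
  })
  classes <- vapply(annotated, `[[`, "", "class")
  structure(list(clusters = annotated,
                 core_count = sum(classes == "core"),
                 accessory_count = sum(classes == "accessory"),
                 unique_count = sum(classes == "unique"),
                 n_clusters = length(annotated)),
            class = "pan_genome_summary")
}

#' @export
print.pan_genome_summary <- function(x, ...) {
  cat(sprintf("pan-genome: %d clusters (core %d, accessory %d, unique %d)\n",
              x$n_clusters, x$core_count, x$accessory_count, x$unique_count))
  invisible(x)
}

chop_fragments <- function(sequence, fragment_len) {
  L <- nchar(sequence)
  n <- L %/% fragment_len   # trailing partial fragment discarded
  if (n < 1) return(character())
  starts <- (seq_len(n) - 1L) * fragment_len + 1L
  substring(sequence, starts, starts + fragment_len - 1L)
}

#' Fragment-based average nucleotide identity (OrthoANI scheme)
#'
#' Both genomes are chopped into consecutive windows of `fragment_len`
#' (trailing partial windows discarded). Each fragment is globally
#' aligned against every fragment of the other genome; reciprocal best
#' pairs whose normalized alignment score passes `min_score_frac` are
#' averaged into the ANI. Raw percent identity of unrelated DNA under
#' global alignment sits near 48 %, so fragment alignability is judged
#' on the score normalized by the perfect-match score
#' (score / (match * fragment_len)): unrelated fragments score about
#' 0.1, fragments within ~30 % substitution divergence score above 0.5.
#'
#' @param g1,g2 genome_record objects, each at least 2 fragments long.
#' @param fragment_len window size in bp (default 1020).
#' @param min_score_frac alignability floor on the normalized score
#'   (default 0.35).
#' @return list: `ani` (percent, or NA when no fragment pair is
#'   alignable — a distinct "undefined" signal, not an error),
#'   `n_pairs` (reciprocal best pairs used), `n_fragments` (per genome).
#' @export
orthoani <- function(g1, g2, fragment_len = 1020, min_score_frac = 0.35) {
  fa <- chop_fragments(g1$sequence, fragment_len)
  fb <- chop_fragments(g2$sequence, fragment_len)
  if (length(fa) < 2 || length(fb) < 2) {
    stop("genome too short: need at least 2 full fragments")
  }
  idm <- matrix(NA_real_, length(fa), length(fb))
  okm <- matrix(FALSE, length(fa), length(fb))
  max_score <- 2 * fragment_len
  for (i in seq_along(fa)) {
    for (j in seq_along(fb)) {
      r <- pairwise_identity(fa[i], fb[j], type = "dna")
      idm[i, j] <- r$identity
      okm[i, j] <- (r$score / max_score) >= min_score_frac
    }
  }
  score_only <- idm
  score_only[!okm] <- -Inf
  best_b <- apply(score_only, 1, which.max)  # best fragment of g2 per g1 fragment
  best_a <- apply(score_only, 2, which.max)
  ids <- c()
  n_pairs <- 0L
  for (i in seq_along(fa)) {
    j <- best_b[i]
    if (okm[i, j] && best_a[j] == i) {
      ids <- c(ids, idm[i, j])
      n_pairs <- n_pairs + 1L
    }
  }
  list(ani = if (n_pairs > 0) mean(ids) else NA_real_,
       n_pairs = n_pairs,
       n_fragments = c(length(fa), length(fb)))
}
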