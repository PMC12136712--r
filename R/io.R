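#' Read a protein or nucleotide multi-FASTA
#'
#' @param path FASTA path.
#' @param type "protein" or "dna".
#' @return named character vector of sequences (names = first token of
#'   each header).
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::readAAStringSet(path)
    else Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  out <- as.character(set)
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  out
}

#' Write sequences to FASTA
#'
#' Round-trips losslessly with [read_fasta()] for id + sequence content.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param type "protein" or "dna".
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::AAStringSet(seqs)
    else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA (MSA)
#'
#' All sequences must have equal (aligned) length.
#'
#' @param path aligned-FASTA path.
#' @return named character vector of aligned sequences.
#' @export
read_msa <- function(path) {
  seqs <- as.character(Biostrings::readBStringSet(path))
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1)
  if (length(unique(nchar(seqs))) != 1) {
    stop("not an alignment: sequence lengths differ in ", path)
  }
  seqs
}

parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) < 2) {
    if (length(nums) == 1) nums <- c(nums, nums) else return(NULL)
  }
  list(start = as.integer(nums[1]),
       end = as.integer(nums[length(nums)]),
       strand = strand)
}

#' Read a GenBank flat file into a genome record
#'
#' Minimal parser for single-record GenBank flat files: LOCUS id,
#' CDS/tRNA features (other feature keys become kind "other"; `source`
#' is skipped), `complement(a..b)` strand handling, `/product` and
#' `/function` qualifiers (the latter mapped to `functional_category`),
#' and the ORIGIN sequence block. Coordinates stay 1-based inclusive.
#' Joined (multi-interval) locations are collapsed to their outer span.
#'
#' @param path GenBank flat-file path.
#' @return genome_record.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("malformed GenBank file (no LOCUS line): ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  if (!length(origin)) stop("malformed GenBank file (no ORIGIN): ", path)
  seq_lines <- lines[(origin[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feats <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1] + 1):(origin[1] - 1)]
    # a feature line has its key in column 6; continuation lines are
    # indented to column 22
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1] - 1 else length(block)
      key <- strsplit(trimws(block[from]), "\\s+")[[1]][1]
      if (key == "source") next
      loc <- paste(trimws(sub("^\\s*\\S+\\s*", "", block[from])))
      body <- paste(trimws(block[from:to]), collapse = " ")
      pos <- parse_gb_location(loc)
      if (is.null(pos)) stop("unparseable location at feature line ", from)
      get_qual <- function(q) {
        m <- regmatches(body, regexpr(sprintf('/%s="[^"]*"', q), body))
        if (!length(m)) return("")
        sub(sprintf('/%s="([^"]*)"', q), "\\1", m)
      }
      feats[[length(feats) + 1L]] <- data.frame(
        kind = if (key %in% c("CDS", "tRNA")) key else "other",
        start = pos$start, end = pos$end, strand = pos$strand,
        product = get_qual("product"),
        functional_category = get_qual("function"),
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  genome_record(id, sequence, features)
}

#' Read a tabular similarity hit table (BLAST outfmt-6 dialect)
#'
#' Twelve tab-separated columns: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bitscore. Query coverage is not part of outfmt 6; supply
#' query lengths to derive it as aligned query span / query length, or
#' it is set to NA.
#'
#' @param path TSV path (no header).
#' @param query_lengths optional named vector of query lengths.
#' @return data.frame with the HitRecord columns `query_id`,
#'   `subject_id`, `percent_identity`, `query_coverage`, `e_value`,
#'   `bitscore` plus the raw coordinate columns.
#' @export
read_hits_table <- function(path, query_lengths = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 tab-separated columns in ", path)
  names(df)[1:12] <- c("query_id", "subject_id", "percent_identity",
                       "aln_length", "mismatches", "gap_opens",
                       "qstart", "qend", "sstart", "send",
                       "e_value", "bitscore")
  cov <- rep(NA_real_, nrow(df))
  if (!is.null(query_lengths)) {
    ql <- query_lengths[df$query_id]
    cov <- 100 * (abs(df$qend - df$qstart) + 1) / ql
  }
  df$query_coverage <- cov
  df
}

#' Write a Newick tree string to file
#'
#' @param newick Newick string (from [upgma()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}

#' Read a plate-assay CSV into an assay table
#'
#' Expected columns: `strain_id`, `species`, `spot_result`, then any
#' number of `pfu_rep*` replicate-count columns.
#'
#' @param path CSV path.
#' @return data.frame with a list-column `replicate_pfu` collecting the
#'   per-row replicate counts (NAs dropped).
#' @export
read_assay_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "species", "spot_result")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("assay table missing column(s): ", paste(missing, collapse = ", "))
  }
  reps <- grep("^pfu_rep", names(df))
  df$replicate_pfu <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, reps])
    v[!is.na(v)]
  })
  df
}
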