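#' Parse a PDB file into a structure model
#'
#' Reads ATOM records of MODEL 1 via \pkg{bio3d}, keeping heavy atoms of
#' standard polymer residues only: hydrogens, waters, HETATM ligands and
#' alternate locations other than the highest-occupancy one (ties kept
#' as 'A') are dropped. Residues are identified by chain, author number
#' and insertion code.
#'
#' @param path PDB file path.
#' @param keep_het keep HETATM records (default FALSE).
#' @return object of class `structure_model`: a data.frame `atoms` with
#'   columns `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`,
#'   `z`, plus `chains` (chain ids present).
#' @export
read_structure <- function(path, keep_het = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (!keep_het) a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[a$resid != "HOH", , drop = FALSE]
  # heavy atoms only: drop hydrogens by element symbol
  elesym <- a$elesy
  if (is.null(elesym) || all(is.na(elesym)) || all(elesym == "")) {
    elesym <- toupper(substr(gsub("[0-9]", "", a$elety), 1, 1))
  }
  a <- a[!(toupper(trimws(elesym)) %in% c("H", "D")), , drop = FALSE]
  # altloc: keep highest occupancy, ties -> 'A'
  if (any(a$alt != "" & !is.na(a$alt))) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      occ <- a$o[idx]
      best <- idx[occ == max(occ)]
      if (length(best) > 1) {
        alt_a <- best[a$alt[best] == "A"]
        best <- if (length(alt_a)) alt_a[1] else best[1]
      }
      best
    }), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }
  atoms <- data.frame(chain = a$chain,
                      resno = a$resno,
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      resid = a$resid,
                      elety = a$elety,
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(atoms = atoms, chains = unique(atoms$chain)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d heavy atoms, chains %s\n",
              nrow(x$atoms), paste(x$chains, collapse = ",")))
  invisible(x)
}

#' Interface residues between two chain groups at a distance cutoff
#'
#' A residue of `group_a` is an interface residue when ANY of its heavy
#' atoms lies within `cutoff` (inclusive) of ANY heavy atom of
#' `group_b`. The minimum atom-atom distance per group-a residue is
#' reported.
#'
#' @param model structure_model from [read_structure()].
#' @param group_a,group_b disjoint, non-empty chain-id sets.
#' @param cutoff distance cutoff in Angstroms (default 5.0, inclusive).
#' @return data.frame of group-a residues at the interface: `chain`,
#'   `resno`, `insert`, `resid`, `min_dist`, sorted by chain then
#'   residue number.
#' @export
interface_residues <- function(model, group_a, group_b, cutoff = 5.0) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1,
            !length(intersect(group_a, group_b)))
  unknown <- setdiff(c(group_a, group_b), model$chains)
  if (length(unknown)) {
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  }
  at <- model$atoms
  A <- at[at$chain %in% group_a, , drop = FALSE]
  B <- at[at$chain %in% group_b, , drop = FALSE]
  bxyz <- as.matrix(B[, c("x", "y", "z")])
  key <- paste(A$chain, A$resno, A$insert, sep = "|")
  res <- lapply(split(seq_len(nrow(A)), key), function(idx) {
    axyz <- as.matrix(A[idx, c("x", "y", "z"), drop = FALSE])
    # squared cross-distances, vectorized
    d2 <- outer(rowSums(axyz^2), rowSums(bxyz^2), "+") -
      2 * axyz %*% t(bxyz)
    md <- sqrt(max(0, min(d2)))
    data.frame(chain = A$chain[idx[1]], resno = A$resno[idx[1]],
               insert = A$insert[idx[1]], resid = A$resid[idx[1]],
               min_dist = md, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[out$min_dist <= cutoff, , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contiguous residue regions of minimum length
#'
#' Maximal runs of consecutive author residue numbers with length >=
#' `min_len` (the convention used to call major interaction regions,
#' e.g. six or more consecutive interface residues).
#'
#' @param residue_numbers integer vector (a set; order irrelevant).
#' @param min_len minimum run length (default 6).
#' @return data.frame `start`, `end`, `length`, sorted; zero rows when
#'   no run qualifies.
#' @export
contiguous_regions <- function(residue_numbers, min_len = 6) {
  v <- sort(unique(as.integer(residue_numbers)))
  if (!length(v)) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  brk <- c(0, which(diff(v) != 1), length(v))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
    run <- v[(brk[i] + 1):brk[i + 1]]
    data.frame(start = run[1], end = run[length(run)],
               length = length(run))
  }))
  out <- out[out$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

msa_to_matrix <- function(msa) {
  if (is.character(msa)) {
    chars <- strsplit(toupper(msa), "", fixed = TRUE)
    stopifnot(length(unique(lengths(chars))) == 1)
    mat <- do.call(rbind, chars)
    rownames(mat) <- names(msa)
    return(mat)
  }
  if (inherits(msa, "AAStringSet") || inherits(msa, "XStringSet")) {
    return(msa_to_matrix(as.character(msa)))
  }
  stopifnot(is.matrix(msa))
  msa
}

GAP_CHARS <- c("-", ".")

#' Per-column occupancy and conservation profile of an alignment
#'
#' Occupancy is the non-gap fraction of a column; conservation is the
#' frequency of the modal residue among non-gap entries. Columns whose
#' occupancy falls below `min_occupancy` are flagged as
#' low-alignment-ratio (conservation there compares too few sequences
#' to be reliable). All-gap columns have undefined (NA) conservation.
#'
#' @param msa named character vector of aligned sequences (equal
#'   lengths), an `AAStringSet`, or a character matrix.
#' @param min_occupancy occupancy threshold for the reliability flag
#'   (default 0.5).
#' @return data.frame per column: `column`, `occupancy`, `conservation`,
#'   `modal_residue`, `ic_bits`, `low_alignment_ratio`.
#' @export
column_profile <- function(msa, min_occupancy = 0.5) {
  mat <- msa_to_matrix(msa)
  n <- nrow(mat)
  out <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    res <- col[!(col %in% GAP_CHARS)]
    occ <- length(res) / n
    if (!length(res)) {
      return(data.frame(column = j, occupancy = 0, conservation = NA_real_,
                        modal_residue = NA_character_, ic_bits = NA_real_,
                        low_alignment_ratio = TRUE))
    }
    tab <- sort(table(res), decreasing = TRUE)
    p <- as.numeric(tab) / length(res)
    ic <- log2(20) + sum(p * log2(p))
    data.frame(column = j,
               occupancy = occ,
               conservation = p[1],
               modal_residue = names(tab)[1],
               ic_bits = ic,
               low_alignment_ratio = occ < min_occupancy)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Position frequency matrix and information content for sequence logos
#'
#' Per-position residue frequencies among non-gap entries, plus the
#' information content IC = log2(20) - H (bits), for rendering sequence
#' logos. Gap entries contribute nothing (logos show gaps as blanks),
#' but the per-position gap fraction is reported.
#'
#' @param msa alignment as in [column_profile()].
#' @param positions integer vector of alignment columns (default all).
#' @return list: `frequencies` (positions x 20 matrix), `ic_bits`
#'   (numeric), `gap_fraction` (numeric), `positions`.
#' @export
logo_matrix <- function(msa, positions = NULL) {
  mat <- msa_to_matrix(msa)
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  stopifnot(all(positions >= 1), all(positions <= ncol(mat)))
  freq <- matrix(0, length(positions), 20,
                 dimnames = list(positions, AA_STANDARD))
  ic <- numeric(length(positions))
  gapf <- numeric(length(positions))
  for (k in seq_along(positions)) {
    col <- mat[, positions[k]]
    gap <- col %in% GAP_CHARS
    gapf[k] <- mean(gap)
    res <- col[!gap]
    if (length(res)) {
      tab <- table(factor(res, levels = AA_STANDARD))
      p <- as.numeric(tab) / length(res)
      freq[k, ] <- p
      nz <- p[p > 0]
      ic[k] <- log2(20) + sum(nz * log2(nz))
    } else {
      ic[k] <- NA_real_
    }
  }
  list(frequencies = freq, ic_bits = ic, gap_fraction = gapf,
       positions = positions)
}

#' PCA embedding of a feature matrix
#'
#' Column-centered (unscaled) principal components via SVD. The sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive, making scores reproducible across platforms.
#'
#' @param feature_matrix numeric matrix, rows = samples.
#' @param n_components number of components to return (default 2).
#' @return list: `scores` (n x k), `loadings` (p x k),
#'   `explained_variance` (fractions, sum <= 1).
#' @export
pca_embed <- function(feature_matrix, n_components = 2) {
  stopifnot(is.matrix(feature_matrix) || is.data.frame(feature_matrix))
  X <- as.matrix(feature_matrix)
  k <- min(n_components, nrow(X) - 1, ncol(X))
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  load <- p$rotation[, seq_len(k), drop = FALSE]
  sc <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      sc[, j] <- -sc[, j]
    }
  }
  list(scores = sc, loadings = load,
       explained_variance = ev[seq_len(k)])
}
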