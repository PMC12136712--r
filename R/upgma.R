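#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering producing an ultrametric
#' tree in Newick form. At each step the pair of clusters with the
#' smallest average distance is merged; ties are broken by the
#' lexicographically smallest (label-sorted) pair, so the result is
#' deterministic. Leaf-to-root path length equals half the merge
#' distance of the root, and every leaf is equidistant from the root.
#'
#' @param d symmetric numeric matrix with zero diagonal, or a `dist`
#'   object.
#' @param labels tip labels; defaults to the matrix dimnames.
#' @return Newick string (with terminating semicolon); branch lengths
#'   are cophenetic half-distances.
#' @export
upgma <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  stopifnot(length(labels) == n, all(abs(diag(d)) < 1e-12),
            all(d >= 0), isTRUE(all.equal(d, t(d))))
  if (n == 1) return(paste0(labels, ";"))

  # active clusters: newick fragment, height, size, sorted member labels
  cl <- lapply(seq_len(n), function(i) {
    list(newick = labels[i], height = 0, size = 1L, key = labels[i])
  })
  dm <- d
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        dd <- dm[a, b]
        if (dd < best_d - 1e-12) {
          best <- c(a, b); best_d <- dd
        } else if (abs(dd - best_d) <= 1e-12) {
          # lexicographic tie-break on the sorted label-pair key
          cand <- sort(c(cl[[a]]$key, cl[[b]]$key))
          inc <- sort(c(cl[[best[1]]]$key, cl[[best[2]]]$key))
          if (paste(cand, collapse = "\r") < paste(inc, collapse = "\r")) {
            best <- c(a, b)
          }
        }
      }
    }
    a <- best[1]; b <- best[2]
    h <- best_d / 2
    # order children lexicographically for a canonical string
    kids <- if (cl[[a]]$key <= cl[[b]]$key) c(a, b) else c(b, a)
    newick <- sprintf("(%s:%.10g,%s:%.10g)",
                      cl[[kids[1]]]$newick, h - cl[[kids[1]]]$height,
                      cl[[kids[2]]]$newick, h - cl[[kids[2]]]$height)
    sz <- cl[[a]]$size + cl[[b]]$size
    merged <- list(newick = newick, height = h, size = sz,
                   key = min(cl[[a]]$key, cl[[b]]$key))
    # size-weighted average distance to every other active cluster
    for (o in setdiff(active, c(a, b))) {
      dm[a, o] <- dm[o, a] <-
        (cl[[a]]$size * dm[a, o] + cl[[b]]$size * dm[b, o]) / sz
    }
    cl[[a]] <- merged
    active <- setdiff(active, b)
  }
  paste0(cl[[active]]$newick, ";")
}

#' Cophenetic (tree) distances implied by a UPGMA merge trace
#'
#' Convenience wrapper: runs [upgma()] and returns the Newick string
#' together with the pairwise path lengths of the re-parsed tree, for
#' ultrametricity checks.
#'
#' @param d distance matrix as in [upgma()].
#' @return list: `newick`, `cophenetic` (matrix of leaf-to-leaf path
#'   lengths; requires the \pkg{ape} package).
#' @export
upgma_with_cophenetic <- function(d) {
  nwk <- upgma(d)
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("ape is required to re-parse the Newick string")
  }
  tr <- ape::read.tree(text = nwk)
  list(newick = nwk, cophenetic = ape::cophenetic.phylo(tr))
}
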