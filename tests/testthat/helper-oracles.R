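# Independent naive re-implementations used as oracles. Each works by
# explicit looping / direct formula evaluation, sharing only the
# published constant tables with the package.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(n) {
  paste(sample(AAS, n, replace = TRUE), collapse = "")
}

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(20); names(out) <- AAS
  for (c in ch) out[c] <- out[c] + 1
  out / length(ch)
}

oracle_dpc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(400)
  names(out) <- as.vector(t(outer(AAS, AAS, paste0)))
  for (i in seq_len(length(ch) - 1)) {
    dp <- paste0(ch[i], ch[i + 1])
    out[dp] <- out[dp] + 1
  }
  out / (length(ch) - 1)
}

oracle_mw <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  total <- 18.0153
  for (c in ch) total <- total + phagekit:::RESIDUE_MASS[[c]]
  total
}

oracle_aromaticity <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  sum(ch == "F" | ch == "W" | ch == "Y") / length(ch)
}

oracle_instability <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  s <- 0
  for (i in seq_len(length(ch) - 1)) {
    s <- s + phagekit:::DIWV[ch[i], ch[i + 1]]
  }
  10 * s / length(ch)
}

oracle_gravy <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  s <- 0
  for (c in ch) s <- s + phagekit:::KYTE_DOOLITTLE[[c]]
  s / length(ch)
}

oracle_charge <- function(seq, pH) {
  ch <- strsplit(seq, "")[[1]]
  pos <- phagekit:::PKA_POSITIVE
  neg <- phagekit:::PKA_NEGATIVE
  q <- 1 / (1 + 10^(pH - pos[["Nterm"]])) -
    1 / (1 + 10^(neg[["Cterm"]] - pH))
  for (c in ch) {
    if (c %in% c("K", "R", "H")) q <- q + 1 / (1 + 10^(pH - pos[[c]]))
    if (c %in% c("D", "E", "C", "Y")) q <- q - 1 / (1 + 10^(neg[[c]] - pH))
  }
  q
}

oracle_pi <- function(seq) {
  stats::uniroot(function(p) oracle_charge(seq, p), c(0, 14),
                 tol = 1e-8)$root
}

oracle_ss <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  c(helix = mean(ch %in% c("V", "I", "Y", "F", "W", "L")),
    turn  = mean(ch %in% c("N", "P", "G", "S")),
    sheet = mean(ch %in% c("E", "M", "A", "L")))
}

oracle_extinction <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  5500 * sum(ch == "W") + 1490 * sum(ch == "Y")
}

# all-pairs O(n^2) atom-distance oracle for interface extraction
brute_force_interface <- function(model, group_a, group_b, cutoff) {
  at <- model$atoms
  A <- at[at$chain %in% group_a, ]
  B <- at[at$chain %in% group_b, ]
  hits <- character()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
      if (d <= cutoff) {
        hits <- c(hits, paste(A$chain[i], A$resno[i], A$insert[i]))
      }
    }
  }
  sort(unique(hits))
}
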