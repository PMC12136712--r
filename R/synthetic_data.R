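#' Synthetic data generators
#'
#' Seeded generators producing inputs with the statistical structure
#' each pipeline stage assumes, so the whole pipeline runs and can be
#' validated against known ground truth without any downloads. Every
#' generator is a pure function of its arguments including the seed.
#'
#' @name synthetic_data
NULL

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Family composition profiles with disjoint residue support
#'
#' Two (or more) family profiles whose residue usage concentrates on
#' disjoint residue sets, drawn from a Dirichlet with large alpha on the
#' family's own set and near-zero elsewhere. Proteomes sampled from such
#' profiles are separable by amino-acid composition by construction.
#'
#' @param n_families number of families (2..4; 20 residues split evenly).
#' @param alpha_on Dirichlet concentration on the family's residue set
#'   (default 5).
#' @param alpha_off concentration off-set (default 0.01).
#' @param length_range protein length range (default c(150, 400)).
#' @param tail_count tail proteins per genome (default 5).
#' @param seed integer seed.
#' @return list of family profiles: `family`, `freqs` (named 20-simplex),
#'   `length_range`, `tail_count`.
#' @export
disjoint_family_profiles <- function(n_families = 2, alpha_on = 5,
                                     alpha_off = 0.01,
                                     length_range = c(150, 400),
                                     tail_count = 5, seed = 37) {
  stopifnot(n_families >= 2, n_families <= 4)
  set.seed(seed)
  split_sets <- split(AA_STANDARD,
                      rep(seq_len(n_families), length.out = 20))
  lapply(seq_len(n_families), function(f) {
    alpha <- rep(alpha_off, 20)
    names(alpha) <- AA_STANDARD
    alpha[split_sets[[f]]] <- alpha_on
    freqs <- rdirichlet1(alpha)
    names(freqs) <- AA_STANDARD
    list(family = paste0("Family", LETTERS[f]), freqs = freqs,
         length_range = length_range, tail_count = tail_count)
  })
}

#' Generate multi-family synthetic phage proteomes
#'
#' For each family profile, draws `genomes_per_family` genomes each
#' carrying `tail_count` tail-annotated proteins whose residues are
#' sampled i.i.d. from the family's residue-frequency vector. Product
#' strings contain "tail" so the records pass tail-protein selection.
#'
#' @param profiles list of family profiles (see
#'   [disjoint_family_profiles()]).
#' @param genomes_per_family genomes per family.
#' @param seed integer seed.
#' @return list: `records` (protein record table), `label_map` (named
#'   genome_id -> family), `ground_truth` (the profiles used).
#' @export
gen_proteomes <- function(profiles, genomes_per_family = 40, seed = 37) {
  set.seed(seed)
  products <- c("tail fiber protein", "tail spike protein",
                "tail completion protein", "tail tube protein",
                "baseplate tail protein")
  rows <- list()
  label_map <- character()
  for (pf in profiles) {
    for (g in seq_len(genomes_per_family)) {
      gid <- sprintf("%s_g%02d", pf$family, g)
      label_map[gid] <- pf$family
      for (p in seq_len(pf$tail_count)) {
        L <- sample(pf$length_range[1]:pf$length_range[2], 1)
        seq <- paste(sample(AA_STANDARD, L, replace = TRUE,
                            prob = pf$freqs), collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_p%02d", gid, p),
          product = products[(p - 1L) %% length(products) + 1L],
          sequence = seq, genome_id = gid,
          family_label = pf$family, stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, rows), label_map = label_map,
       ground_truth = profiles)
}

#' Generate a triphasic one-step growth curve
#'
#' Flat baseline until the latent period, linear rise over
#' `rise_duration`, then flat plateau, with multiplicative lognormal
#' noise of the given coefficient of variation. Defaults emulate the
#' KPP105 study conditions: baseline 1e5 PFU/mL, burst 146 (plateau
#' 1.46e7), latent period 20 min, burst complete at 60 min, 5-minute
#' sampling.
#'
#' @param baseline,plateau titers in PFU/mL.
#' @param latent latent period, minutes.
#' @param rise_duration rise phase length, minutes.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param sampling_interval minutes between samples.
#' @param t_max last sampling time (default latent + rise_duration + 20).
#' @param seed integer seed.
#' @return list: `curve` (a [growth_curve()]), `ground_truth` (baseline,
#'   plateau, latent, burst size, rise end).
#' @export
gen_growth_curve <- function(baseline = 1e5, plateau = 1.46e7,
                             latent = 20, rise_duration = 40,
                             noise_cv = 0.05, sampling_interval = 5,
                             t_max = latent + rise_duration + 20,
                             seed = 37) {
  set.seed(seed)
  times <- seq(0, t_max, by = sampling_interval)
  mu <- ifelse(times <= latent, baseline,
               ifelse(times >= latent + rise_duration, plateau,
                      baseline + (times - latent) / rise_duration *
                        (plateau - baseline)))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
    titers <- mu * noise
  } else {
    titers <- mu
  }
  list(curve = growth_curve(times, titers),
       ground_truth = list(baseline = baseline, plateau = plateau,
                           latent = latent,
                           rise_end = latent + rise_duration,
                           burst_size = plateau / baseline))
}

#' Generate a random genome record
#'
#' @param length genome length in bp.
#' @param gc GC fraction (default 0.5).
#' @param seed integer seed.
#' @param id genome identifier.
#' @return genome_record with no features.
#' @export
gen_genome <- function(length, gc = 0.5, seed = 37, id = "synthetic") {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome_record(id, paste(sample(names(p), length, TRUE, prob = p),
                          collapse = ""))
}

#' Mutate a genome by i.i.d. substitutions
#'
#' Each site is substituted, independently with the given rate, to one
#' of the three other bases (uniformly). The realized substitution count
#' is reported as ground truth for divergence/ANI validation.
#'
#' @param g genome_record.
#' @param substitution_rate per-site substitution probability.
#' @param seed integer seed.
#' @return list: `genome` (mutated genome_record), `n_substitutions`
#'   (realized count).
#' @export
mutate_genome <- function(g, substitution_rate, seed = 37) {
  set.seed(seed)
  chars <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < substitution_rate
  bases <- c("A", "C", "G", "T")
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  list(genome = genome_record(paste0(g$id, "_mut"),
                              paste(chars, collapse = ""),
                              g$features),
       n_substitutions = sum(hit))
}

#' Generate a two-chain complex with a planted contact set
#'
#' Builds a PDB file of two single-atom-per-residue chains (A and B).
#' `n_contacts` residue pairs are placed with atom distance strictly
#' below `cutoff`; `n_decoys` pairs at distance above `cutoff + margin`.
#' Pairs sit on a widely spaced lattice (50 Angstrom pitch) so no
#' unintended cross-pair contact can arise, making the planted set the
#' exact interface at the cutoff. A JSON sidecar with the planted
#' contact residue numbers is written next to the PDB.
#'
#' @param path output PDB path; sidecar goes to `<path>.truth.json`.
#' @param n_contacts,n_decoys numbers of contact and decoy residue pairs.
#' @param cutoff contact distance cutoff in Angstroms (default 5).
#' @param margin decoy clearance beyond the cutoff in Angstroms (default
#'   1); must be positive, otherwise contacts and decoys would be
#'   ambiguous and the generator refuses.
#' @param seed integer seed.
#' @return invisibly, a list: `path`, `contact_resno` (chain A residue
#'   numbers in contact), `decoy_resno`.
#' @export
gen_complex <- function(path, n_contacts = 25, n_decoys = 25,
                        cutoff = 5.0, margin = 1.0, seed = 37) {
  if (margin <= 0) stop("margin must be positive: planted set ambiguous")
  set.seed(seed)
  n <- n_contacts + n_decoys
  is_contact <- sample(rep(c(TRUE, FALSE), c(n_contacts, n_decoys)))
  pitch <- 50
  side <- ceiling(sqrt(n))
  xa <- ya <- za <- xb <- yb <- zb <- numeric(n)
  for (i in seq_len(n)) {
    gx <- ((i - 1) %% side) * pitch
    gy <- ((i - 1) %/% side) * pitch
    d <- if (is_contact[i]) stats::runif(1, 1.5, cutoff - 0.1)
      else stats::runif(1, cutoff + margin, cutoff + margin + 5)
    theta <- stats::runif(1, 0, 2 * pi)
    phi <- acos(stats::runif(1, -1, 1))
    xa[i] <- gx; ya[i] <- gy; za[i] <- 0
    xb[i] <- gx + d * sin(phi) * cos(theta)
    yb[i] <- gy + d * sin(phi) * sin(theta)
    zb[i] <- d * cos(phi)
  }
  resno <- seq_len(n)
  bio3d::write.pdb(file = path,
                   xyz = c(c(rbind(xa, ya, za)), c(rbind(xb, yb, zb))),
                   resno = c(resno, resno),
                   chain = rep(c("A", "B"), each = n),
                   resid = rep("GLY", 2 * n),
                   elety = rep("CA", 2 * n),
                   o = rep(1, 2 * n), b = rep(0, 2 * n))
  truth <- list(path = path,
                contact_resno = resno[is_contact],
                decoy_resno = resno[!is_contact],
                cutoff = cutoff, margin = margin, seed = seed)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE)
  invisible(truth)
}

#' Generate an aligned FASTA with a specified conservation profile
#'
#' For each column a modal residue is drawn; each sequence carries the
#' modal residue with the column's conservation probability, a uniform
#' other residue otherwise, and a gap independently with `gap_rate`.
#'
#' @param n_seqs number of sequences.
#' @param length alignment length (columns).
#' @param conservation_profile per-column modal-residue probability,
#'   recycled to `length`.
#' @param gap_rate i.i.d. per-entry gap probability.
#' @param seed integer seed.
#' @return list: `msa` (named character vector of aligned sequences),
#'   `ground_truth` (modal residues and the conservation profile).
#' @export
gen_msa <- function(n_seqs = 50, length = 40,
                    conservation_profile = 0.9, gap_rate = 0.05,
                    seed = 37) {
  set.seed(seed)
  p <- rep_len(conservation_profile, length)
  modal <- sample(AA_STANDARD, length, replace = TRUE)
  mat <- matrix("", n_seqs, length)
  for (j in seq_len(length)) {
    others <- setdiff(AA_STANDARD, modal[j])
    pick <- ifelse(stats::runif(n_seqs) < p[j], modal[j],
                   sample(others, n_seqs, replace = TRUE))
    gap <- stats::runif(n_seqs) < gap_rate
    pick[gap] <- "-"
    mat[, j] <- pick
  }
  msa <- apply(mat, 1, paste, collapse = "")
  names(msa) <- sprintf("seq%03d", seq_len(n_seqs))
  list(msa = msa,
       ground_truth = list(modal = modal, conservation = p,
                           gap_rate = gap_rate))
}

#' Generate a family of related sequences around a seed sequence
#'
#' Residue-substitutes a seed protein at the given per-site rate to
#' produce homologs of controlled identity, for clustering validation.
#'
#' @param seed_sequence amino-acid seed sequence.
#' @param n number of derived sequences.
#' @param substitution_rate per-site substitution probability.
#' @param seed integer seed.
#' @return named character vector including the seed as the first entry.
#' @export
gen_protein_family <- function(seed_sequence, n = 20,
                               substitution_rate = 0.2, seed = 37) {
  set.seed(seed)
  chars0 <- strsplit(seed_sequence, "", fixed = TRUE)[[1]]
  out <- c(seed = seed_sequence)
  for (i in seq_len(n)) {
    chars <- chars0
    hit <- stats::runif(length(chars)) < substitution_rate
    for (k in which(hit)) {
      chars[k] <- sample(setdiff(AA_STANDARD, chars[k]), 1)
    }
    out[sprintf("member%02d", i)] <- paste(chars, collapse = "")
  }
  out
}
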