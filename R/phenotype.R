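#' Efficiency of plating (EOP)
#'
#' EOP = mean(target plaque counts) / mean(host plaque counts) x 100,
#' with the host strain defined as 100 %. The spread is propagated from
#' the replicates: with equal replicate numbers, the SD of the paired
#' per-replicate ratios; otherwise a first-order (delta-method)
#' approximation from the two means and SDs.
#'
#' @param target_counts,host_counts numeric vectors of replicate PFU
#'   counts (same phage dilution on both strains).
#' @return named numeric vector `eop_percent`, `sd_percent`.
#' @export
eop <- function(target_counts, host_counts) {
  stopifnot(length(target_counts) >= 1, length(host_counts) >= 1,
            all(target_counts >= 0), all(host_counts >= 0))
  mh <- mean(host_counts)
  if (mh <= 0) stop("host mean PFU is zero: EOP undefined")
  mt <- mean(target_counts)
  value <- 100 * mt / mh
  if (length(target_counts) == length(host_counts) &&
      length(target_counts) >= 2) {
    sd_out <- stats::sd(100 * target_counts / host_counts)
  } else if (length(target_counts) >= 2 && length(host_counts) >= 2) {
    # delta method: var(t/h) ~ (1/mh^2) var(t) + (mt^2/mh^4) var(h)
    vt <- stats::var(target_counts) / length(target_counts)
    vh <- stats::var(host_counts) / length(host_counts)
    sd_out <- 100 * sqrt(vt / mh^2 + mt^2 * vh / mh^4)
  } else {
    sd_out <- NA_real_
  }
  c(eop_percent = value, sd_percent = sd_out)
}

#' Count susceptible strains in a host-range assay table
#'
#' A strain counts as susceptible when its spot test is positive AND its
#' EOP is greater than zero: strains that clear a spot but yield no
#' plaques in the plating assay are scored resistant.
#'
#' @param table data.frame with columns `strain_id`, `species`,
#'   `spot_result` ("+"/"-"), `eop_percent`.
#' @param species optional species filter (exact match); default all.
#' @return integer count.
#' @export
count_susceptible <- function(table, species = NULL) {
  if (!is.null(species)) {
    table <- table[table$species == species, , drop = FALSE]
  }
  sum(table$spot_result == "+" & table$eop_percent > 0)
}

#' Fold reduction between two log10 titers
#'
#' 10^(initial - final). The report helper rounds to two significant
#' figures, matching how stability losses are conventionally quoted
#' (e.g. 8.5 to 5.3 log10 PFU/mL is a ~1.6e3-fold reduction).
#'
#' @param log10_initial,log10_final titers in log10 PFU/mL.
#' @return fold reduction (numeric).
#' @export
fold_reduction <- function(log10_initial, log10_final) {
  10^(log10_initial - log10_final)
}

#' Format a fold reduction to two significant figures
#'
#' @param fold numeric fold reduction from [fold_reduction()].
#' @return character like "1.6e+03".
#' @export
format_fold <- function(fold) {
  formatC(signif(fold, 2), format = "g", digits = 2)
}

#' One-step growth-curve container
#'
#' @param times sampling times in minutes, strictly increasing, >= 5
#'   points.
#' @param titers free-phage titers in PFU/mL, positive.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(times, titers) {
  stopifnot(length(times) == length(titers), length(times) >= 5,
            all(diff(times) > 0), all(titers > 0))
  structure(list(times = times, titers = titers), class = "growth_curve")
}

#' Latent period, burst period and burst size from a one-step growth curve
#'
#' Assumes the canonical triphasic shape: a baseline of free infected
#' centers, a rise as cells lyse, and a plateau once the burst is
#' complete. The baseline is estimated iteratively from the first two
#' points outward, absorbing successive points while they stay at or
#' below `rise_factor` times the running baseline; the latent period is
#' the last baseline time. The plateau is the mean of the points within
#' 10 % of the curve maximum (the tail of a triphasic curve). Burst size is
#' the plateau/baseline titer ratio (at low MOI with pre-wash
#' adsorption, infected centers equal the baseline PFU); the alternative
#' (plateau - baseline)/baseline convention is available via
#' `subtract_baseline`.
#'
#' @param curve a [growth_curve()].
#' @param rise_factor titer multiple that signals the onset of lysis
#'   (default 2).
#' @param subtract_baseline use (plateau - baseline)/baseline instead of
#'   plateau/baseline (default FALSE).
#' @return list: `latent_min`, `burst_period` (start, end in minutes),
#'   `burst_size`, `baseline`, `plateau`.
#' @export
growth_curve_analysis <- function(curve, rise_factor = 2.0,
                                  subtract_baseline = FALSE) {
  t <- curve$times; y <- curve$titers
  n <- length(y)
  est <- mean(y[1:2])
  i <- 3L
  while (i <= n && y[i] <= rise_factor * est) {
    est <- mean(y[1:i])
    i <- i + 1L
  }
  if (i > n) stop("no burst detected: curve never rises above baseline")
  baseline <- est
  latent <- t[i - 1L]
  top <- max(y)
  # plateau = points within 10 % of the maximum; for a triphasic curve
  # these are the tail points (the rise crosses 0.9*max at most once)
  in_plateau <- y >= 0.9 * top
  plateau_idx <- which(in_plateau)
  plateau <- mean(y[plateau_idx])
  burst <- if (subtract_baseline) (plateau - baseline) / baseline
    else plateau / baseline
  list(latent_min = latent,
       burst_period = c(start = latent, end = t[plateau_idx[1]]),
       burst_size = burst,
       baseline = baseline,
       plateau = plateau)
}

#' Host-range assay table of the KPP105 study
#'
#' The published spot-test and EOP results: 15 ESBL-positive
#' *Klebsiella pneumoniae* blood isolates plus 9 other Gram-negative
#' strains. Three *K. pneumoniae* strains (KBN B-1, K20-KPN-12-057,
#' K22-KPN-13-007) show a positive spot but zero EOP and are scored
#' resistant.
#'
#' @return data.frame with columns `strain_id`, `species`,
#'   `spot_result`, `eop_percent`, `eop_sd`.
#' @export
kpp105_host_range <- function() {
  kp <- data.frame(
    strain_id = c("KBN K-1", "KBN K-2", "KBN P-1", "KBN B-1",
                  "K01-KPN-13-134", "K01-KPN-13-149", "K07-KPN-13-002",
                  "K14-KPN-13-016", "K16-KPN-13-008", "K16-KPN-13-022",
                  "K20-KPN-12-057", "K20-KPN-12-067", "K21-KPN-12-013",
                  "K22-KPN-13-007", "K22-KPN-13-013"),
    species = "Klebsiella pneumoniae",
    spot_result = "+",
    eop_percent = c(100, 97.6, 92.3, 0, 93.3, 89.5, 75.4, 49.5, 69.8,
                    75.1, 0, 70.2, 82.9, 0, 82.8),
    eop_sd = c(0, 1.9, 2.8, NA, 2.1, 3.7, 4.3, 2.5, 1.6, 2.5, NA, 3.4,
               1.9, NA, 2.5),
    stringsAsFactors = FALSE)
  other <- data.frame(
    strain_id = c("ATCC17978", "15-0628", "KCTC2949", "KCTC1039",
                  "K01-ECO12-052", "KCTC2566", "KCTC2004", "ATCC14028",
                  "KCCM12021"),
    species = c("Acinetobacter baumannii", "Citrobacter freundii",
                "Cronobacter sakazakii", "Escherichia coli",
                "Escherichia coli", "Proteus mirabilis",
                "Pseudomonas aeruginosa", "Salmonella Typhimurium",
                "Salmonella Enteritidis"),
    spot_result = "-",
    eop_percent = 0,
    eop_sd = NA,
    stringsAsFactors = FALSE)
  rbind(kp, other)
}
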