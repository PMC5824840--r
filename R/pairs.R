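#' Genome-wide significant SNP-probe pairs from a probe-level scan
#'
#' Applies the probe-level FDR threshold to a [scan_probes()] result and
#' expands it to the SNP level: a SNP-probe pair is significant when the
#' probe's q-value passes `fdr` and the pair's nominal P falls below the
#' probe-specific nominal threshold implied by the probe's fitted beta
#' null at the genome-wide adjusted-P cutoff (the largest adjusted P among
#' FDR-passing probes) — the standard way permutation-calibrated mappers
#' extend probe-level significance to all cis-SNPs.
#'
#' @param scan A [scan_probes()] result list.
#' @param fdr Probe-level FDR threshold (default 0.01).
#' @return Tibble of significant associations: all [cis_scan()] columns
#'   plus the probe's `qvalue` and `p_nominal_threshold`.
#' @export
significant_pairs <- function(scan, fdr = 0.01) {
  probes <- scan$probes
  sig <- probes[probes$qvalue < fdr, ]
  if (!nrow(sig)) {
    return(dplyr::mutate(scan$associations[0, ],
                         qvalue = numeric(0),
                         p_nominal_threshold = numeric(0)))
  }
  adj_cut <- max(sig$adj_p)
  sig$p_nominal_threshold <- ifelse(
    is.na(sig$beta_a),
    sig$best_p,  # degenerate beta fit: lead pair only
    qbeta(adj_cut, sig$beta_a, sig$beta_b)
  )
  scan$associations |>
    dplyr::inner_join(
      sig[, c("probe", "qvalue", "p_nominal_threshold")], by = "probe"
    ) |>
    dplyr::filter(.data$p <= .data$p_nominal_threshold)
}

#' Raw candidate SNP-eProbe-CpG combinations
#'
#' For each eProbe's lead eSNP, finds every CpG for which that SNP is a
#' genome-wide-significant meSNP, yielding the raw (lead eSNP, eProbe,
#' CpG) combinations that may share a causal variant.
#'
#' @param eqtl_leads Tibble of eQTL lead pairs: columns `probe` (eProbe)
#'   and `lead_snp` (e.g. the `probes` table of [scan_probes()] filtered to
#'   significant probes).
#' @param meqtl_signif Significant meQTL SNP-CpG pairs from
#'   [significant_pairs()] on the methylation scan: columns `probe` (CpG),
#'   `snp`, `p`, `beta`.
#' @param eqtl_snps,meqtl_snps Optional character vectors giving the SNP
#'   universes of the two scans; an error is raised if they are disjoint.
#' @return Tibble with one row per combination: `esnp`, `eprobe`, `cpg`,
#'   `meqtl_p`, `meqtl_beta`.
#' @export
find_candidate_pairs <- function(eqtl_leads, meqtl_signif,
                                 eqtl_snps = NULL, meqtl_snps = NULL) {
  stopifnot(all(c("probe", "lead_snp") %in% names(eqtl_leads)))
  if (!is.null(eqtl_snps) && !is.null(meqtl_snps) &&
      !length(intersect(eqtl_snps, meqtl_snps))) {
    abort("eQTL and meQTL scans share no SNPs (disjoint SNP universes).")
  }
  eqtl_leads |>
    dplyr::select(eprobe = "probe", esnp = "lead_snp") |>
    dplyr::inner_join(
      dplyr::select(meqtl_signif, esnp = "snp", cpg = "probe",
                    meqtl_p = "p", meqtl_beta = "beta"),
      by = "esnp", relationship = "many-to-many"
    )
}

#' Prune candidate combinations to one CpG per expression probe
#'
#' Two-step CpG pruning to remove redundancy among correlated CpG
#' clusters: (1) among CpGs associated with the same lead eSNP, keep the
#' CpG whose own lead meSNP is in the highest LD (r²) with that eSNP;
#' (2) require each eProbe to pair with exactly one CpG — the one whose
#' lead meSNP has the highest r² with the probe's lead eSNP. Exact r² ties
#' are broken by smaller meQTL P, then lower CpG coordinate.
#'
#' @param raw_pairs Output of [find_candidate_pairs()].
#' @param meqtl_leads Tibble mapping each CpG to its lead meSNP: columns
#'   `probe` (CpG) and `lead_snp`.
#' @param geno A [genotype_matrix()] used to compute lead-lead r².
#' @param cpg_pos Optional tibble (`probe`, `pos`) for coordinate
#'   tie-breaks; defaults to positions in `geno` order (ties then broken
#'   by CpG ID).
#' @return Tibble of candidate pairs: `eprobe`, `cpg`, `lead_esnp`,
#'   `lead_mesnp`, `r2_leads`, `meqtl_p`.
#' @export
prune_pairs <- function(raw_pairs, meqtl_leads, geno, cpg_pos = NULL) {
  if (!nrow(raw_pairs)) {
    return(tibble::tibble(eprobe = character(0), cpg = character(0),
                          lead_esnp = character(0), lead_mesnp = character(0),
                          r2_leads = numeric(0), meqtl_p = numeric(0)))
  }
  x <- raw_pairs |>
    dplyr::left_join(
      dplyr::select(meqtl_leads, cpg = "probe", lead_mesnp = "lead_snp"),
      by = "cpg"
    )
  pair_r2 <- function(s1, s2) {
    if (is.na(s2)) return(NA_real_)
    if (s1 == s2) return(1)
    suppressWarnings(ld_r2(geno$dosages[, s1], geno$dosages[, s2]))
  }
  x$r2_leads <- purrr::map2_dbl(x$esnp, x$lead_mesnp, pair_r2)
  if (is.null(cpg_pos)) {
    cpg_pos <- tibble::tibble(probe = sort(unique(x$cpg)))
    cpg_pos$pos <- seq_len(nrow(cpg_pos))
  }
  x <- dplyr::left_join(x, dplyr::select(cpg_pos, cpg = "probe", cpg_coord = "pos"),
                        by = "cpg")
  pick <- function(df) {
    df |>
      dplyr::arrange(dplyr::desc(.data$r2_leads), .data$meqtl_p,
                     .data$cpg_coord) |>
      dplyr::slice(1L)
  }
  x |>
    dplyr::group_by(.data$esnp, .data$eprobe) |>  # step 1: per shared SNP
    dplyr::group_modify(~ pick(.x)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$eprobe) |>              # step 2: one CpG per eProbe
    dplyr::group_modify(~ pick(.x)) |>
    dplyr::ungroup() |>
    dplyr::transmute(eprobe = .data$eprobe, cpg = .data$cpg,
                     lead_esnp = .data$esnp, lead_mesnp = .data$lead_mesnp,
                     r2_leads = .data$r2_leads, meqtl_p = .data$meqtl_p)
}
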