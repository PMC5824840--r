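#' Read / write a dosage matrix as TSV
#'
#' The canonical flat format: columns `snp`, `chrom`, `pos`, then one
#' column per sample with dosages in \[0, 2\].
#'
#' @param path File path.
#' @return [read_dosage_tsv()] returns a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = readr::col_character()))
  stopifnot(all(c("snp", "chrom", "pos") %in% names(x)))
  samp <- setdiff(names(x), c("snp", "chrom", "pos"))
  dos <- t(as.matrix(x[, samp]))
  colnames(dos) <- x$snp
  genotype_matrix(dos, x[, c("snp", "chrom", "pos")])
}

#' @rdname read_dosage_tsv
#' @param geno A [genotype_matrix()].
#' @export
write_dosage_tsv <- function(geno, path) {
  out <- dplyr::bind_cols(
    geno$snps[, c("snp", "chrom", "pos")],
    tibble::as_tibble(t(geno$dosages))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read genotype dosages from a VCF with a DS FORMAT field
#'
#' Requires the `vcfR` package.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the 'vcfR' package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  genotype_matrix(
    t(ds),
    tibble::tibble(snp = ids, chrom = fix[, "CHROM"],
                   pos = as.numeric(fix[, "POS"]))
  )
}

#' Write genotype dosages as a minimal VCF with a DS FORMAT field
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path (plain text).
#' @export
write_dosage_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  ), con)
  body <- vapply(seq_len(nrow(geno$snps)), function(i) {
    paste(c(geno$snps$chrom[i], geno$snps$pos[i], geno$snps$snp[i],
            "A", "B", ".", "PASS", ".", "DS",
            formatC(geno$dosages[, i], format = "g", digits = 6)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write a phenotype matrix as TSV
#'
#' Probe rows, sample columns; the first column `probe` holds probe IDs
#' and the header row holds sample IDs. Probe anchor positions travel
#' separately as BED ([read_bed()]).
#'
#' @param path File path.
#' @param anno Tibble with `probe`, `chrom`, `pos` for each probe.
#' @param scale Scale tag for [phenotype_matrix()].
#' @return [read_phenotype_tsv()] returns a [phenotype_matrix()].
#' @export
read_phenotype_tsv <- function(path, anno,
                               scale = "log-expression") {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(names(x)[1] == "probe")
  vals <- t(as.matrix(x[, -1]))
  colnames(vals) <- x$probe
  anno <- anno[match(x$probe, anno$probe), ]
  phenotype_matrix(vals, anno, scale = scale)
}

#' @rdname read_phenotype_tsv
#' @param pheno A [phenotype_matrix()].
#' @export
write_phenotype_tsv <- function(pheno, path) {
  out <- dplyr::bind_cols(
    tibble::tibble(probe = pheno$probes$probe),
    tibble::as_tibble(t(pheno$values))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write point features as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive
#' (VCF convention). A point feature at 1-based position `pos` is the BED
#' interval `(pos - 1, pos)`; the converters are inverse bijections.
#'
#' @param path File path.
#' @return [read_bed()] returns a tibble `probe`, `chrom`, `pos` (1-based).
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                       show_col_types = FALSE, comment = "#",
                       col_types = readr::cols(chrom = readr::col_character()))
  tibble::tibble(probe = x$name, chrom = as.character(x$chrom),
                 pos = x$start + 1)
}

#' @rdname read_bed
#' @param anno Tibble with `probe`, `chrom`, `pos` (1-based).
#' @export
write_bed <- function(anno, path) {
  readr::write_tsv(
    tibble::tibble(chrom = anno$chrom, start = anno$pos - 1, end = anno$pos,
                   name = anno$probe),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the tunable constants of the full workflow with the standard
#' defaults: 500 kb cis window, 250 kb co-localization region, probe-level
#' scan FDR 0.01, causal-analysis FDR 0.05, adaptive permutations
#' 1000-10000, prior fractions f in \{0.75, 0.5, 0.25, 0.1, 0.05\}, CCV
#' designation threshold 0.8, LD-pruning r² 0.3.
#'
#' @param cis_window,coloc_region_bp Window sizes in bp.
#' @param scan_fdr,causal_fdr FDR levels.
#' @param n_perm Adaptive permutation bounds.
#' @param f_grid Prior fractions for the co-localization grid.
#' @param ccv_threshold P(CCV) designation threshold.
#' @param prune_r2 LD-pruning threshold.
#' @param maf_min MAF filter (exclusive).
#' @param abf_w ABF prior effect SD.
#' @param seed Root seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A `pipeline_config` list with a `hash` field.
#' @export
pipeline_config <- function(cis_window = 5e5, coloc_region_bp = 2.5e5,
                            scan_fdr = 0.01, causal_fdr = 0.05,
                            n_perm = c(1000, 10000),
                            f_grid = c(0.75, 0.5, 0.25, 0.1, 0.05),
                            ccv_threshold = 0.8, prune_r2 = 0.3,
                            maf_min = 0.05, abf_w = 0.15,
                            seed = 1L, out_dir = tempfile("comolq_")) {
  if (!length(f_grid)) abort("`f_grid` must not be empty.")
  if (any(f_grid <= 0 | f_grid >= 1)) abort("`f_grid` values must be in (0,1).")
  if (cis_window <= 0 || coloc_region_bp <= 0) abort("windows must be positive.")
  if (scan_fdr <= 0 || scan_fdr >= 1 || causal_fdr <= 0 || causal_fdr >= 1) {
    abort("FDR levels must be in (0,1).")
  }
  cfg <- list(cis_window = cis_window, coloc_region_bp = coloc_region_bp,
              scan_fdr = scan_fdr, causal_fdr = causal_fdr, n_perm = n_perm,
              f_grid = f_grid, ccv_threshold = ccv_threshold,
              prune_r2 = prune_r2, maf_min = maf_min, abf_w = abf_w,
              seed = as.integer(seed), out_dir = out_dir)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Assemble and validate a study bundle
#'
#' Binds genotypes, the two phenotype panels, covariates and the panel
#' assignment into one validated object: applies the MAF filter, drops
#' phenotype samples without genotypes (with a message), and — when
#' co-localization is to be run — enforces that the eQTL and meQTL panels
#' are disjoint, a requirement of two-summary-statistic co-localization.
#'
#' @param geno A [genotype_matrix()].
#' @param expression,methylation [phenotype_matrix()] objects on their
#'   analysis scales.
#' @param panels List with character vectors `eqtl`, `meqtl`, and
#'   optionally `overlap` (defaults to meQTL samples with expression).
#' @param covars_e,covars_m Optional covariate matrices for the two scans.
#' @param config A [pipeline_config()].
#' @param coloc Will co-localization be run? (enforces panel disjointness)
#' @return A `study_bundle` list.
#' @export
load_study <- function(geno, expression, methylation, panels,
                       covars_e = NULL, covars_m = NULL,
                       config = pipeline_config(), coloc = TRUE) {
  geno <- filter_maf(geno, config$maf_min)
  miss_e <- setdiff(expression$samples, geno$samples)
  miss_m <- setdiff(methylation$samples, geno$samples)
  if (length(miss_e) + length(miss_m)) {
    inform(sprintf("dropping %d expression / %d methylation samples without genotypes.",
                   length(miss_e), length(miss_m)))
  }
  panels$eqtl <- intersect(panels$eqtl, geno$samples)
  panels$meqtl <- intersect(panels$meqtl, geno$samples)
  if (coloc && length(intersect(panels$eqtl, panels$meqtl))) {
    abort("eQTL and meQTL panels overlap; co-localization requires disjoint panels.")
  }
  panels$overlap <- intersect(panels$overlap %||%
                                intersect(methylation$samples, expression$samples),
                              geno$samples)
  structure(
    list(geno = geno, expression = expression, methylation = methylation,
         panels = panels, covars_e = covars_e, covars_m = covars_m,
         config = config),
    class = "study_bundle"
  )
}

#' Run the full joint-QTL workflow
#'
#' Executes, in order: the cis-eQTL scan on the eQTL panel, the cis-meQTL
#' scan on the meQTL panel, candidate-pair construction and CpG pruning,
#' co-localization across the `f` grid with internal empirical
#' calibration, and the causal analyses (partial correlation and both
#' mediation models) on the overlap panel for pairs designated
#' co-localized at the calibration-selected prior. All result tables are
#' written as TSV under `config$out_dir` with `config_hash` and `seed`
#' columns and also returned.
#'
#' @param bundle A [load_study()] bundle.
#' @param n_indep_eqtl,n_indep_meqtl,n_snps_total QTL counts for
#'   [derive_priors()]; defaults derive them from the scans themselves
#'   (independent signals = FDR-passing probes after LD pruning of leads)
#'   and the panel SNP count.
#' @return A named list of tibbles: `eqtl`, `meqtl`, `pairs`, `coloc`,
#'   `calibration`, `causal`, `direction`.
#' @export
run_pipeline <- function(bundle, n_indep_eqtl = NULL, n_indep_meqtl = NULL,
                         n_snps_total = NULL) {
  stopifnot(inherits(bundle, "study_bundle"))
  cfg <- bundle$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  geno <- bundle$geno

  ge <- subset_geno(geno, samples = bundle$panels$eqtl)
  gm <- subset_geno(geno, samples = bundle$panels$meqtl)
  scan_e <- scan_probes(ge, bundle$expression, bundle$covars_e,
                        window = cfg$cis_window, n_perm = cfg$n_perm,
                        seed = derive_seed(cfg$seed, "escan"))
  scan_m <- scan_probes(gm, bundle$methylation, bundle$covars_m,
                        window = cfg$cis_window, n_perm = cfg$n_perm,
                        seed = derive_seed(cfg$seed, "mscan"))

  eqtl_sig <- scan_e$probes[scan_e$probes$qvalue < cfg$scan_fdr, ]
  meqtl_signif <- significant_pairs(scan_m, cfg$scan_fdr)
  meqtl_leads <- scan_m$probes[scan_m$probes$qvalue < cfg$scan_fdr, ]

  raw <- find_candidate_pairs(eqtl_sig, meqtl_signif,
                              eqtl_snps = ge$snps$snp, meqtl_snps = gm$snps$snp)
  cpg_anno <- bundle$methylation$probes
  pairs <- prune_pairs(raw, meqtl_leads, geno,
                       cpg_pos = cpg_anno[, c("probe", "pos")])

  n_snps_total <- n_snps_total %||% ncol(geno$dosages)
  n_indep_eqtl <- n_indep_eqtl %||% max(nrow(eqtl_sig), 1L)
  n_indep_meqtl <- n_indep_meqtl %||% max(nrow(meqtl_leads), 1L)
  priors_grid <- dplyr::bind_rows(lapply(
    cfg$f_grid, function(f)
      derive_priors(n_indep_eqtl, n_indep_meqtl, n_snps_total, f)
  ))

  snp_pos <- geno$snps[, c("snp", "pos")]
  cl <- coloc_candidates(pairs, scan_e$associations, scan_m$associations,
                         snp_pos, cpg_anno, priors_grid, W = cfg$abf_w,
                         region_bp = cfg$coloc_region_bp,
                         cis_window = cfg$cis_window)
  calib <- if (nrow(cl) && dplyr::n_distinct(cl$f) >= 2) {
    empirical_calibration(cl, cfg$ccv_threshold)
  } else NULL
  f_sel <- if (!is.null(calib)) attr(calib, "selected_f") else cfg$f_grid[1]

  ccv <- cl[cl$f == f_sel & cl$pp4 > cfg$ccv_threshold, , drop = FALSE]
  ov <- bundle$panels$overlap
  causal <- NULL; direction <- NULL
  if (nrow(ccv) && length(ov) >= 10) {
    rows <- purrr::pmap(
      list(ccv$eprobe, ccv$cpg, ccv$lead_esnp),
      function(ep, cg, lead) {
        e <- bundle$expression$values[ov, ep]
        m <- bundle$methylation$values[ov, cg]
        g <- geno$dosages[ov, lead]
        pc <- partial_correlation(e, m, g)
        med <- run_both_models(g, e, m)
        dplyr::bind_cols(
          tibble::tibble(eprobe = ep, cpg = cg, lead_esnp = lead),
          tidyr::pivot_wider(
            med[, c("model", "p_sobel", "prop_mediated")],
            names_from = "model",
            values_from = c("p_sobel", "prop_mediated")
          ),
          pc
        )
      }
    )
    causal <- dplyr::bind_rows(rows)
    dirs <- tibble::tibble(
      beta_e = scan_e$probes$lead_beta[match(ccv$eprobe, scan_e$probes$probe)],
      beta_m = scan_m$probes$lead_beta[match(ccv$cpg, scan_m$probes$probe)],
      r_em = causal$r_before,
      sobel_p = pmin(causal$p_sobel_SME, causal$p_sobel_SEM),
      corr_p = causal$p_after
    )
    direction <- direction_summary(dirs)
  }

  results <- list(eqtl = scan_e$probes, meqtl = scan_m$probes, pairs = pairs,
                  coloc = cl, calibration = calib, causal = causal,
                  direction = direction)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.null(x) || !nrow(x)) next
    x$config_hash <- cfg$hash
    x$seed <- cfg$seed
    readr::write_tsv(x, file.path(cfg$out_dir, paste0(nm, ".tsv")))
  }
  results
}
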