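#' Post-calling filter configuration
#'
#' Thresholds applied after variant calling, mirroring the usual VCFtools /
#' Stacks populations options for RADseq SNP matrices: per-genotype depth and
#' quality bounds, a cap on observed per-site heterozygosity, a minimum
#' fraction of genotyped individuals per site, and retention of a single
#' (first) SNP per RADseq locus so sites can be treated as unlinked.
#'
#' @param min_dp,max_dp keep genotypes with `min_dp <= DP <= max_dp` (reads).
#' @param min_gq keep genotypes with `GQ >= min_gq` (phred-like score).
#' @param max_obs_het drop sites whose observed heterozygosity (fraction of
#'   heterozygotes among non-missing genotypes) exceeds this proportion.
#' @param min_presence_R drop sites genotyped in fewer than this fraction of
#'   all individuals (the `-R` option of Stacks populations).
#' @param single_snp_per_locus keep only the first SNP of each locus.
#' @export
filter_config <- function(min_dp = 10, max_dp = 50, min_gq = 20,
                          max_obs_het = 0.65, min_presence_R = 0.8,
                          single_snp_per_locus = TRUE) {
  if (min_dp > max_dp) stop("min_dp must be <= max_dp")
  if (max_obs_het < 0 || max_obs_het > 1) stop("max_obs_het must be in [0,1]")
  if (min_presence_R < 0 || min_presence_R > 1) stop("min_presence_R must be in [0,1]")
  structure(list(min_dp = min_dp, max_dp = max_dp, min_gq = min_gq,
                 max_obs_het = max_obs_het, min_presence_R = min_presence_R,
                 single_snp_per_locus = isTRUE(single_snp_per_locus)),
            class = "refugia_filter_config")
}

#' Mask genotypes failing depth/quality thresholds
#'
#' Sets individual genotypes to missing when their read depth falls outside
#' `[min_dp, max_dp]` or their quality is below `min_gq`; bounds pass
#' inclusively (DP = 10 and DP = 50 are kept, GQ = 20 is kept). Sites are
#' never dropped here -- partially genotyped sites remain available to the
#' projection step.
#'
#' @param gm a `refugia_genotypes`.
#' @param cfg a `filter_config()`.
#' @return The matrix with failing genotypes set to `NA`.
#' @export
apply_genotype_filters <- function(gm, cfg = filter_config()) {
  if (is.null(gm$dp)) stop("genotype matrix lacks the DP field")
  if (is.null(gm$gq)) stop("genotype matrix lacks the GQ field")
  bad <- gm$dp < cfg$min_dp | gm$dp > cfg$max_dp | gm$gq < cfg$min_gq
  bad[is.na(bad)] <- TRUE
  gm$genotypes[bad] <- NA
  gm
}

#' Drop sites failing presence, heterozygosity, or linkage rules
#'
#' Applied after [apply_genotype_filters()], in a fixed order: (1) drop sites
#' genotyped in fewer than `min_presence_R` of all individuals; (2) drop
#' sites whose observed heterozygosity among the remaining genotypes exceeds
#' `max_obs_het`; (3) if `single_snp_per_locus`, keep only the first SNP
#' (smallest position) of each locus. A per-rule kept/dropped tally is
#' attached as attribute `"filter_tally"`.
#'
#' @inheritParams apply_genotype_filters
#' @export
apply_site_filters <- function(gm, cfg = filter_config()) {
  n_in <- nrow(gm$genotypes)
  ni <- ncol(gm$genotypes)

  presence <- rowSums(!is.na(gm$genotypes)) / ni
  keep1 <- presence >= cfg$min_presence_R
  n_presence <- sum(!keep1)
  gm <- subset_sites(gm, keep1)

  n_called <- rowSums(!is.na(gm$genotypes))
  n_het <- rowSums(gm$genotypes == 1L, na.rm = TRUE)
  het <- ifelse(n_called > 0, n_het / n_called, 0)
  keep2 <- het <= cfg$max_obs_het
  n_het_drop <- sum(!keep2)
  gm <- subset_sites(gm, keep2)

  n_linked <- 0L
  if (cfg$single_snp_per_locus && nrow(gm$genotypes) > 0) {
    ord <- order(gm$locus_id, gm$pos)
    first <- ord[!duplicated(gm$locus_id[ord])]
    keep3 <- sort(first)
    n_linked <- nrow(gm$genotypes) - length(keep3)
    gm <- subset_sites(gm, keep3)
  }

  attr(gm, "filter_tally") <- c(
    input = n_in, dropped_presence = n_presence, dropped_het = n_het_drop,
    dropped_extra_snp = n_linked, kept = nrow(gm$genotypes)
  )
  gm
}

#' Read a VCF with DP/GQ FORMAT fields into a genotype matrix
#'
#' @param path VCF 4.x file (plain or gzipped; parsed with \pkg{vcfR}).
#' @param pop_map either a named character vector (sample to population) or
#'   the path of a two-column tab-separated population map.
#' @return A [genotype_matrix()]. The CHROM column is taken as the RADseq
#'   locus identifier and POS as the within-locus SNP order.
#' @export
read_vcf_genotypes <- function(path, pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map)) {
    pm <- utils::read.table(pop_map, sep = "\t", header = FALSE,
                            col.names = c("sample", "population"),
                            colClasses = "character")
    pop_map <- stats::setNames(pm$population, pm$sample)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  fix <- vcfR::getFIX(v)
  genotype_matrix(dos, dp = dp, gq = gq,
                  locus_id = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  pop_map = pop_map, ref = fix[, "REF"], alt = fix[, "ALT"])
}

#' Write a genotype matrix as a VCF 4.2 file (GT:DP:GQ)
#'
#' Deterministic output: the header carries a fixed `fileDate` so identical
#' inputs give byte-identical files.
#'
#' @param gm a `refugia_genotypes`.
#' @param path output path (plain text).
#' @export
write_genotype_vcf <- function(gm, path) {
  samples <- colnames(gm$genotypes)
  gt_str <- matrix("./.", nrow(gm$genotypes), ncol(gm$genotypes))
  gt_str[which(gm$genotypes == 0L)] <- "0/0"
  gt_str[which(gm$genotypes == 1L)] <- "0/1"
  gt_str[which(gm$genotypes == 2L)] <- "1/1"
  fmt_num <- function(m) {
    if (is.null(m)) return(rep(".", length(gt_str)))
    out <- as.character(as.vector(m))
    out[is.na(out)] <- "."
    out
  }
  dp <- fmt_num(gm$dp)
  gq <- fmt_num(gm$gq)
  cells <- matrix(paste(gt_str, dp, gq, sep = ":"),
                  nrow(gt_str), ncol(gt_str))
  header <- c(
    "##fileformat=VCFv4.2",
    "##fileDate=20260101",
    "##source=refugia",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gt_str)), function(i) {
    paste(c(gm$locus_id[i], gm$pos[i], ".", gm$ref[i], gm$alt[i], ".",
            "PASS", ".", "GT:DP:GQ", cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a two-column sample-to-population map
#' @param pop_map named character vector (names = samples).
#' @param path output path.
#' @export
write_popmap <- function(pop_map, path) {
  writeLines(paste(names(pop_map), pop_map, sep = "\t"), path)
  invisible(path)
}
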