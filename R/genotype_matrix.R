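#' Diploid genotype matrix with per-genotype depth and quality
#'
#' Sites x samples storage of biallelic diploid genotypes as alt-allele
#' dosage (0, 1, 2 or `NA` for missing), together with per-genotype read
#' depth (`dp`), phred-like genotype quality (`gq`), a per-site locus
#' identifier (RADseq fragment) with position giving the within-locus SNP
#' order, and a sample-to-population map.
#'
#' @param genotypes integer matrix, sites x samples, values in `{0,1,2,NA}`.
#' @param dp,gq numeric matrices of the same shape (may be `NULL` when the
#'   source lacks them; the genotype filters then refuse to run).
#' @param locus_id character/integer vector, one locus label per site.
#' @param pos integer vector of within-locus positions (SNP order).
#' @param pop_map named character vector, `names = sample`, value =
#'   population label. Must cover every sample column.
#' @param ref,alt optional per-site allele labels (defaults A/T). For
#'   simulated data `ref` is the true ancestral allele.
#' @return An object of class `refugia_genotypes`.
#' @export
genotype_matrix <- function(genotypes, dp = NULL, gq = NULL,
                            locus_id = NULL, pos = NULL, pop_map,
                            ref = NULL, alt = NULL) {
  genotypes <- as.matrix(genotypes)
  ns <- nrow(genotypes)
  ni <- ncol(genotypes)
  if (!all(genotypes %in% c(0L, 1L, 2L, NA))) {
    stop("genotypes must be alt-allele dosage 0/1/2 or NA")
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- sprintf("sample%03d", seq_len(ni))
  }
  samples <- colnames(genotypes)
  for (nm in c("dp", "gq")) {
    m <- get(nm)
    if (!is.null(m) && !all(dim(m) == dim(genotypes))) {
      stop(sprintf("%s shape must match genotypes", toupper(nm)))
    }
  }
  if (!is.null(dp) && any(dp < 0, na.rm = TRUE)) stop("DP must be >= 0")
  if (is.null(locus_id)) locus_id <- sprintf("locus_%06d", seq_len(ns))
  if (is.null(pos)) pos <- stats::ave(seq_len(ns), locus_id, FUN = seq_along)
  if (length(locus_id) != ns || length(pos) != ns) {
    stop("locus_id/pos must have one entry per site")
  }
  pop_map <- pop_map[samples]
  if (any(is.na(pop_map)) || is.null(names(pop_map))) {
    stop("every sample needs a population in pop_map")
  }
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep("T", ns)
  structure(
    list(genotypes = genotypes, dp = dp, gq = gq,
         locus_id = as.character(locus_id), pos = as.integer(pos),
         pop_map = pop_map, ref = ref, alt = alt),
    class = "refugia_genotypes"
  )
}

#' @export
print.refugia_genotypes <- function(x, ...) {
  cat(sprintf("genotype matrix: %d sites x %d samples, %d loci, pops: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$locus_id)),
              paste(sort(unique(x$pop_map)), collapse = ", ")))
  cat(sprintf("missing genotypes: %.1f%%\n",
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
dim.refugia_genotypes <- function(x) dim(x$genotypes)

# subset sites, preserving all parallel slots
subset_sites <- function(gm, keep) {
  gm$genotypes <- gm$genotypes[keep, , drop = FALSE]
  for (nm in c("dp", "gq")) {
    if (!is.null(gm[[nm]])) gm[[nm]] <- gm[[nm]][keep, , drop = FALSE]
  }
  gm$locus_id <- gm$locus_id[keep]
  gm$pos <- gm$pos[keep]
  gm$ref <- gm$ref[keep]
  gm$alt <- gm$alt[keep]
  gm
}

# per-population alt counts and non-missing allele totals for every site
pop_allele_counts <- function(gm, pop) {
  cols <- names(gm$pop_map)[gm$pop_map == pop]
  if (length(cols) == 0) stop(sprintf("unknown population '%s'", pop))
  g <- gm$genotypes[, cols, drop = FALSE]
  list(alt = rowSums(g, na.rm = TRUE),
       n = 2L * rowSums(!is.na(g)))
}
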