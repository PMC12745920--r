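#' Private alleles per population
#'
#' Counts, for each population, the (site, allele) pairs where the allele
#' (reference or alternate) is observed in that population and in no other.
#' Missing genotypes are ignored. Spatial aggregation of private allelic
#' richness is one line of evidence for a glacial refugium.
#'
#' @param gm a [genotype_matrix()] with at least two populations.
#' @return Named integer vector of private-allele counts per population.
#' @export
private_alleles <- function(gm) {
  pops <- sort(unique(gm$pop_map))
  if (length(pops) < 2) stop("private alleles need >= 2 populations")
  # presence[site, pop] per allele
  has_alt <- has_ref <- matrix(FALSE, nrow(gm$genotypes), length(pops),
                               dimnames = list(NULL, pops))
  for (p in pops) {
    g <- gm$genotypes[, names(gm$pop_map)[gm$pop_map == p], drop = FALSE]
    has_alt[, p] <- rowSums(g > 0, na.rm = TRUE) > 0
    has_ref[, p] <- rowSums(g < 2, na.rm = TRUE) > 0
  }
  priv <- function(hasm) {
    n_with <- rowSums(hasm)
    colSums(hasm & n_with == 1)
  }
  priv(has_alt) + priv(has_ref)
}

#' Nucleotide diversity per population
#'
#' Per-site heterozygosity with the unbiased small-sample correction,
#' `pi_site = n/(n-1) * (1 - sum_a p_a^2)` with `n` the non-missing allele
#' count in the population, summed over variant sites and divided by the
#' total number of surveyed sites (variant plus invariant). The denominator
#' is caller-supplied because a SNP matrix does not carry the invariant-site
#' count of the underlying loci.
#'
#' @param gm a [genotype_matrix()].
#' @param n_sites_surveyed total surveyed sites, `>=` the variant-site count.
#' @return Named numeric vector of per-population pi. Sites with fewer than
#'   2 non-missing alleles in a population contribute 0 there; their count
#'   is attached as attribute `"n_low_coverage"`.
#' @export
nucleotide_diversity <- function(gm, n_sites_surveyed) {
  if (n_sites_surveyed < nrow(gm$genotypes)) {
    stop("n_sites_surveyed must be >= number of variant sites")
  }
  pops <- sort(unique(gm$pop_map))
  out <- stats::setNames(numeric(length(pops)), pops)
  low <- stats::setNames(integer(length(pops)), pops)
  for (p in pops) {
    ac <- pop_allele_counts(gm, p)
    ok <- ac$n >= 2
    low[p] <- sum(!ok)
    pa <- ac$alt[ok] / ac$n[ok]
    n <- ac$n[ok]
    pi_site <- (n / (n - 1)) * (1 - pa^2 - (1 - pa)^2)
    out[p] <- sum(pi_site) / n_sites_surveyed
  }
  attr(out, "n_low_coverage") <- low
  out
}

#' Per-population summary table (private alleles and pi)
#'
#' @inheritParams nucleotide_diversity
#' @return data.frame with columns `population`, `private_alleles`, `pi`,
#'   `n_sites_surveyed`.
#' @export
pop_summary <- function(gm, n_sites_surveyed) {
  pa <- private_alleles(gm)
  pi <- nucleotide_diversity(gm, n_sites_surveyed)
  data.frame(population = names(pa), private_alleles = as.integer(pa),
             pi = as.numeric(pi[names(pa)]),
             n_sites_surveyed = n_sites_surveyed, row.names = NULL)
}
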