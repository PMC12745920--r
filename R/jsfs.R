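#' Build a joint site frequency spectrum from genotypes
#'
#' Every site with at least `n1` non-missing alleles in `popA` and `n2` in
#' `popB` contributes its hypergeometric down-projection to the `(n1, n2)`
#' spectrum, so partially genotyped sites are used rather than discarded
#' (the behaviour of easySFS). Sites below either threshold are skipped.
#' The total contributed mass (including mass landing in the masked
#' monomorphic corners) equals the number of usable sites.
#'
#' @param gm a [genotype_matrix()]; the alt allele is taken as derived.
#' @param popA,popB population labels from the population map; `popA` maps
#'   to the first spectrum axis.
#' @param n1,n2 even haploid projection sizes, at most twice the number of
#'   individuals in the respective population.
#' @param fold fold the spectrum (minor-allele orientation)? Default `TRUE`,
#'   for data without a polarising outgroup.
#' @param partial if `FALSE`, drop partially genotyped sites instead of
#'   projecting them: a site then contributes (its exact counts) only when
#'   genotyped in exactly `n1` and `n2` alleles.
#' @return A `refugia_spectrum` of site counts.
#' @export
build_jsfs <- function(gm, popA, popB, n1, n2, fold = TRUE, partial = TRUE) {
  if (n1 %% 2 != 0 || n2 %% 2 != 0) stop("projection sizes must be even")
  a <- pop_allele_counts(gm, popA)
  b <- pop_allele_counts(gm, popB)
  if (n1 > 2 * sum(gm$pop_map == popA) || n2 > 2 * sum(gm$pop_map == popB)) {
    stop("projection size exceeds available alleles")
  }
  usable <- a$n >= n1 & b$n >= n2
  out <- matrix(0, n1 + 1L, n2 + 1L)
  idx <- which(usable)
  if (!partial) idx <- idx[a$n[idx] == n1 & b$n[idx] == n2]
  if (length(idx)) {
    # group identical (altA, nA, altB, nB) site patterns, then rank-1 updates
    key <- paste(a$alt[idx], a$n[idx], b$alt[idx], b$n[idx])
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " "))
    storage.mode(parts) <- "numeric"
    for (r in seq_len(nrow(parts))) {
      wA <- stats::dhyper(0:n1, parts[r, 1], parts[r, 2] - parts[r, 1], n1)
      wB <- stats::dhyper(0:n2, parts[r, 3], parts[r, 4] - parts[r, 3], n2)
      out <- out + as.numeric(tab[r]) * outer(wA, wB)
    }
  }
  if (fold) out <- fold_data(out)
  spectrum2d(out, folded = fold, pop_labels = c(popA, popB))
}

#' Choose projection sizes maximising segregating mass
#'
#' Searches candidate even haploid sizes for the pair `(n1p, n2p)` that
#' maximises the total projected segregating (interior, unmasked) mass --
#' the expected number of sites still polymorphic after down-projection.
#' Missing data create the trade-off: larger sizes use more alleles per site
#' but exclude incompletely genotyped sites. Ties are broken toward larger
#' `n1p + n2p`, then larger `n1p`.
#'
#' @inheritParams build_jsfs
#' @return Named integer vector `c(n1p, n2p)`; the full candidate table is
#'   attached as attribute `"mass_table"`.
#' @export
best_projection <- function(gm, popA, popB) {
  a <- pop_allele_counts(gm, popA)
  b <- pop_allele_counts(gm, popB)
  cand1 <- seq(2L, max(a$n), by = 2L)
  cand2 <- seq(2L, max(b$n), by = 2L)
  if (max(a$n) < 2 || max(b$n) < 2) stop("no population has 2 genotyped alleles")

  # per site and candidate size: P(projected sample is all-ancestral / all-derived)
  edge_probs <- function(alt, n, cands) {
    one <- function(np, k) {
      out <- rep(NA_real_, length(alt))
      ok <- n >= np
      out[ok] <- stats::dhyper(k[ok], alt[ok], n[ok] - alt[ok], np)
      out
    }
    p0 <- vapply(cands, function(np) one(np, rep(0L, length(alt))),
                 numeric(length(alt)))
    pf <- vapply(cands, function(np) one(np, rep(np, length(alt))),
                 numeric(length(alt)))
    list(p0 = rbind(p0), pf = rbind(pf))  # sites x candidates
  }
  ea <- edge_probs(a$alt, a$n, cand1)
  eb <- edge_probs(b$alt, b$n, cand2)

  mass <- matrix(NA_real_, length(cand1), length(cand2),
                 dimnames = list(cand1, cand2))
  for (i in seq_along(cand1)) {
    for (j in seq_along(cand2)) {
      ok <- !is.na(ea$p0[, i]) & !is.na(eb$p0[, j])
      if (!any(ok)) next
      p_mono <- ea$p0[ok, i] * eb$p0[ok, j] + ea$pf[ok, i] * eb$pf[ok, j]
      mass[i, j] <- sum(1 - p_mono)
    }
  }
  if (all(is.na(mass))) stop("no site is usable at any projection size")
  best <- max(mass, na.rm = TRUE)
  hits <- which(mass >= best - 1e-9, arr.ind = TRUE)
  tot <- cand1[hits[, 1]] + cand2[hits[, 2]]
  hits <- hits[order(-tot, -cand1[hits[, 1]])[1], , drop = FALSE]
  out <- c(n1p = cand1[hits[1, 1]], n2p = cand2[hits[1, 2]])
  attr(out, "mass_table") <- mass
  out
}
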