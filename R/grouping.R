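#' Evanno delta-K from clustering log-likelihood traces
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' the second-difference statistic locating an abrupt change in the
#' likelihood of clustering runs across K; undefined at the smallest and
#' largest K. Requires replicate runs per K (for the standard deviation).
#'
#' @param trace data.frame with columns `K` and `logL` (one row per
#'   replicate run), or the path of a TSV with columns K, replicate, logL.
#' @return data.frame with `K` and `delta_k` for interior K, sorted by K;
#'   the best-supported K (argmax) is attached as attribute `"best_k"`.
#' @export
evanno_delta_k <- function(trace) {
  if (is.character(trace)) {
    trace <- utils::read.table(trace, header = TRUE, sep = "\t")
    names(trace)[names(trace) == "logL"] <- "logL"
  }
  if (!all(c("K", "logL") %in% names(trace))) {
    stop("trace needs columns K and logL")
  }
  ks <- sort(unique(trace$K))
  if (length(ks) < 3) stop("delta-K needs >= 3 consecutive K values")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  ms <- tapply(trace$logL, trace$K, mean)[as.character(ks)]
  sds <- tapply(trace$logL, trace$K, stats::sd)[as.character(ks)]
  if (any(is.na(sds))) stop("delta-K needs >= 2 replicates per K")
  interior <- ks[-c(1, length(ks))]
  dk <- vapply(interior, function(k) {
    i <- which(ks == k)
    num <- abs(ms[i + 1] - 2 * ms[i] + ms[i - 1])
    if (sds[i] == 0) {
      warning(sprintf("sd of L at K=%d is 0; delta-K infinite", k))
      return(Inf)
    }
    num / sds[i]
  }, numeric(1))
  out <- data.frame(K = interior, delta_k = dk)
  attr(out, "best_k") <- interior[which.max(dk)]
  out
}

#' Filter populations by admixture level
#'
#' Keeps populations whose major cluster assignment exceeds `major_gt` and
#' whose second most frequent cluster stays below `second_lt` (both strict),
#' excluding admixed populations whose demographic signal may be hidden by
#' gene flow.
#'
#' @param q Q matrix (rows = populations, columns = cluster proportions;
#'   rows must sum to 1 within 1e-6), e.g. from [simulate_q_matrices()] or
#'   [read_q_matrix()].
#' @param major_gt,second_lt thresholds (defaults 0.5 and 0.35).
#' @return list with `kept` and `excluded` row-name vectors and the
#'   decision `table`.
#' @export
admixture_filter <- function(q, major_gt = 0.5, second_lt = 0.35) {
  q <- as.matrix(q)
  if (any(abs(rowSums(q) - 1) > 1e-6) || any(q < 0)) {
    stop("Q matrix rows must be proportions summing to 1")
  }
  if (is.null(rownames(q))) rownames(q) <- sprintf("pop%d", seq_len(nrow(q)))
  major <- apply(q, 1, max)
  second <- apply(q, 1, function(r) sort(r, decreasing = TRUE)[2])
  keep <- major > major_gt & second < second_lt
  list(kept = rownames(q)[keep], excluded = rownames(q)[!keep],
       table = data.frame(population = rownames(q), major = major,
                          second = second, kept = keep, row.names = NULL))
}

#' Read a population x cluster Q matrix from TSV
#' @param path TSV file: first column population, remaining columns cluster
#'   proportions. Individual-level matrices may be averaged to population
#'   level with `aggregate_by` (a named vector individual -> population).
#' @param aggregate_by optional named character vector mapping rows to
#'   populations; rows are averaged per population.
#' @export
read_q_matrix <- function(path, aggregate_by = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (!is.null(aggregate_by)) {
    pops <- aggregate_by[rownames(m)]
    m <- apply(m, 2, function(col) tapply(col, pops, mean))
    m <- m / rowSums(m)
  }
  m
}

#' Validate proposed geo-genetic groups against the 2-of-3 criteria
#'
#' A proposed group of populations is validated when at least two of three
#' criteria hold: (i) membership in a distinct genetic cluster, (ii) a
#' divergent branch in the phylogenetic network, (iii) strong geographic
#' isolation. Criterion flags are supplied per population (they encode
#' expert judgement and upstream analyses); a group-level flag holds only
#' if it holds for every member.
#'
#' @param criteria data.frame with columns `population`, `distinct_cluster`,
#'   `divergent_branch`, `geographically_isolated` (logical).
#' @param proposed_groups named list of population character vectors; must
#'   partition the populations of `criteria`.
#' @return data.frame per group: the three group-level flags, `n_criteria`,
#'   and `validated`.
#' @export
assign_geo_genetic_groups <- function(criteria, proposed_groups) {
  flags <- c("distinct_cluster", "divergent_branch", "geographically_isolated")
  if (!all(c("population", flags) %in% names(criteria))) {
    stop("criteria must have columns population + the three criterion flags")
  }
  members <- unlist(proposed_groups)
  if (any(duplicated(members))) stop("groups overlap")
  if (!setequal(members, criteria$population)) {
    stop("groups must partition the populations in criteria")
  }
  rows <- lapply(names(proposed_groups), function(g) {
    sel <- criteria[criteria$population %in% proposed_groups[[g]], flags]
    gf <- vapply(sel, all, TRUE)
    data.frame(group = g, t(gf), n_criteria = sum(gf),
               validated = sum(gf) >= 2)
  })
  do.call(rbind, rows)
}

#' Flag geographically isolated populations (optional helper)
#'
#' Marks populations whose nearest other population exceeds a distance
#' threshold. This is a mechanical aid; the isolation criterion in
#' [assign_geo_genetic_groups()] ultimately encodes expert judgement.
#'
#' @param coords matrix/data.frame with rownames = populations and two
#'   coordinate columns (same units as `threshold`).
#' @param threshold isolation distance.
#' @return named logical vector.
#' @export
flag_isolated_populations <- function(coords, threshold) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  apply(d, 1, min) > threshold
}
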