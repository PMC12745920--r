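test_that("genotype filters mask on DP bounds inclusively and on GQ", {
  dosage <- matrix(1L, 5, 1)
  gm <- make_gm(dosage, "A", dp = c(8, 10, 50, 51, 30), gq = 99)
  out <- apply_genotype_filters(gm, filter_config())
  expect_equal(is.na(out$genotypes[, 1]), c(TRUE, FALSE, FALSE, TRUE, FALSE))

  gm2 <- make_gm(dosage, "A", dp = 30, gq = 19)
  out2 <- apply_genotype_filters(gm2, filter_config())
  expect_true(all(is.na(out2$genotypes)))

  cfg <- filter_config(min_dp = 0, max_dp = Inf, min_gq = 0)
  expect_equal(apply_genotype_filters(gm, cfg)$genotypes, gm$genotypes)
})

test_that("genotype filters demand DP and GQ fields", {
  gm <- make_gm(matrix(1L, 2, 2), c("A", "A"))
  gm$dp <- NULL
  expect_error(apply_genotype_filters(gm), "DP")
  gm <- make_gm(matrix(1L, 2, 2), c("A", "A"))
  gm$gq <- NULL
  expect_error(apply_genotype_filters(gm), "GQ")
})

test_that("site filters drop on heterozygosity, presence and extra SNPs", {
  # 10 individuals, site 1 with 7/10 heterozygous exceeds 0.65
  dosage <- rbind(c(rep(1L, 7), 0L, 0L, 2L),
                  c(rep(0L, 9), 1L))
  gm <- make_gm(dosage, rep("A", 10))
  out <- apply_site_filters(gm, filter_config(single_snp_per_locus = FALSE))
  expect_equal(nrow(out$genotypes), 1L)
  tal <- attr(out, "filter_tally")
  expect_equal(unname(tal["dropped_het"]), 1L)

  # presence rule: site 2 genotyped in 3/6 < 0.8
  dosage <- rbind(rep(0:1, 3), c(1L, NA, 0L, NA, 1L, NA))
  gm <- make_gm(dosage, rep("A", 6))
  out <- apply_site_filters(gm, filter_config(single_snp_per_locus = FALSE))
  expect_equal(nrow(out$genotypes), 1L)
  expect_equal(unname(attr(out, "filter_tally")["dropped_presence"]), 1L)

  # single-SNP rule keeps the first SNP of a 3-SNP locus
  dosage <- rbind(c(0L, 1L), c(1L, 0L), c(0L, 2L))
  gm <- make_gm(dosage, c("A", "A"), locus_id = rep("loc1", 3),
                pos = c(5L, 1L, 9L))
  out <- apply_site_filters(gm, filter_config(min_presence_R = 0))
  expect_equal(nrow(out$genotypes), 1L)
  expect_equal(out$pos, 1L)  # smallest position = first SNP

  # tallies account for every input site
  expect_equal(sum(attr(out, "filter_tally")[c("dropped_presence",
                                               "dropped_het",
                                               "dropped_extra_snp",
                                               "kept")]), 3)
})

test_that("filters are idempotent and benign data pass unchanged", {
  set.seed(42)
  dosage <- matrix(sample(0:2, 60, replace = TRUE, prob = c(.5, .2, .3)),
                   10, 6)
  gm <- make_gm(dosage, rep(c("A", "B"), each = 3),
                locus_id = sprintf("loc%d", 1:10))
  cfg <- filter_config()
  once <- apply_site_filters(apply_genotype_filters(gm, cfg), cfg)
  twice <- apply_site_filters(apply_genotype_filters(once, cfg), cfg)
  expect_equal(twice$genotypes, once$genotypes)
  expect_equal(twice$locus_id, once$locus_id)
  expect_equal(once$genotypes, gm$genotypes)  # all DP/GQ/het/presence fine
})

test_that("VCF round-trip preserves dosage, DP, GQ and locus identity", {
  set.seed(7)
  dosage <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 10, 4)
  dp <- matrix(sample(5:60, 40, replace = TRUE), 10, 4)
  gq <- matrix(sample(10:99, 40, replace = TRUE), 10, 4)
  pm <- stats::setNames(rep(c("A", "B"), each = 2), sprintf("s%02d", 1:4))
  gm <- genotype_matrix(matrix(dosage, 10, 4,
                               dimnames = list(NULL, names(pm))),
                        dp = dp, gq = gq,
                        locus_id = rep(sprintf("loc%d", 1:5), each = 2),
                        pos = rep(c(3L, 8L), 5), pop_map = pm)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  pmf <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_vcf(gm, vcf)
  write_popmap(gm$pop_map, pmf)
  rt <- read_vcf_genotypes(vcf, pmf)
  expect_equal(unname(rt$genotypes), unname(gm$genotypes))
  expect_equal(unname(rt$dp), unname(dp))
  expect_equal(unname(rt$gq), unname(gq))
  expect_equal(rt$locus_id, gm$locus_id)
  expect_equal(rt$pos, gm$pos)
  expect_equal(rt$pop_map, gm$pop_map)
})
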