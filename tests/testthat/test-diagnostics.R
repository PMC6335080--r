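panelA <- paste0("a", 1:6)
panelB <- paste0("b", 1:6)

diag_dm <- function(DA, DB, DH = NULL, p = 8L) {
  D <- cbind(DA, DB, DH)
  ids <- c(panelA, panelB, if (!is.null(DH)) paste0("h", seq_len(ncol(DH))))
  toy_dm(D, stats::setNames(rep(p, ncol(D)), ids))
}

test_that("strict fixation defines diagnostic loci", {
  DA <- matrix(8L, 3, 6); DB <- matrix(0L, 3, 6)
  DB[2, 1] <- 1L                     # one panelB accession carries the allele
  dm <- diag_dm(DA, DB)
  mk <- find_diagnostic_snps(dm, panelA, panelB)
  # sites 1 and 3 are fixed differences (dual: alt marks A, ref marks B);
  # at site 2 the alt allele leaks into panelB so only the ref allele stays
  # diagnostic (for B, since it is absent from panelA)
  expect_equal(mk$site, 1:3)
  expect_equal(mk$direction, c("A", "B", "A"))
  expect_equal(mk$allele, c("alt", "ref", "alt"))
  expect_equal(mk$dual, c(TRUE, FALSE, TRUE))
  # relaxed purity readmits the leaked alt allele as A-diagnostic
  mk2 <- find_diagnostic_snps(dm, panelA, panelB, purity = 0.8)
  expect_equal(mk2$direction[mk2$site == 2L], "A")
  expect_error(find_diagnostic_snps(dm, panelA[1:3], panelB), "fewer than 5")
})

test_that("composition classes hybrids locus by locus and sums to one", {
  DA <- matrix(8L, 10, 6); DB <- matrix(0L, 10, 6)
  DH <- cbind(rep(8L, 10),            # pure A hybrid
              c(rep(8L, 5), rep(0L, 5)),  # half A half B
              rep(4L, 10))            # both alleles everywhere
  dm <- diag_dm(DA, DB, DH)
  mk <- find_diagnostic_snps(dm, panelA, panelB)
  comp <- genome_composition(dm, mk, paste0("h", 1:3), min_loci = 5L)
  expect_equal(comp$fracA, c(1, 0.5, 0))
  expect_equal(comp$fracB, c(0, 0.5, 0))
  expect_equal(comp$frac_both, c(0, 0, 1))
  expect_equal(comp$fracA + comp$fracB + comp$frac_both + comp$frac_neither,
               rep(1, 3))
  # too few genotyped loci -> missing with reason
  comp2 <- genome_composition(dm, mk, "h1", min_loci = 50L)
  expect_true(is.na(comp2$fracA))
  expect_equal(comp2$reason, "insufficient loci")
})

test_that("composition is invariant to swapping the panel labels", {
  set.seed(51)
  co <- simulate_cohort(sim_config(n_sites = 600L, n_fixed_diff = 200L,
                                   n_accessions = c(speciesA = 12L, speciesB = 12L,
                                                    hybrid = 6L, outgroup = 0L),
                                   ploidy = list(speciesA = 8L, speciesB = 8L,
                                                 hybrid = 8L, outgroup = 8L),
                                   hybrid_composition = 0.7, seed = 51L))
  dm <- truth_dm(co)
  pops <- split(co$meta$id, co$meta$group)
  mk_ab <- find_diagnostic_snps(dm, pops$speciesA, pops$speciesB)
  mk_ba <- find_diagnostic_snps(dm, pops$speciesB, pops$speciesA)
  c_ab <- genome_composition(dm, mk_ab, pops$hybrid)
  c_ba <- genome_composition(dm, mk_ba, pops$hybrid)
  expect_equal(c_ab$fracA, c_ba$fracB, tolerance = 1e-12)
  expect_equal(c_ab$fracB, c_ba$fracA, tolerance = 1e-12)
})

test_that("marker discovery recovers planted fixed differences accurately", {
  co <- simulate_cohort(sim_config(n_sites = 1000L, n_fixed_diff = 200L,
                                   n_accessions = c(speciesA = 20L, speciesB = 20L,
                                                    hybrid = 0L, outgroup = 0L),
                                   seed = 52L))
  dm <- genotype_variants(co$variants, co$meta)
  fl <- apply_filters(dm, co$variants)
  pops <- split(co$meta$id, co$meta$group)
  mk <- find_diagnostic_snps(fl$level2, pops$speciesA, pops$speciesB)
  planted <- site_key(co$variants$sites[co$truth$fixed_diff_sites, ])
  found <- site_key(fl$level2$sites[mk$site, ])
  recall <- mean(planted %in% found)
  false_disc <- mean(!found %in% planted)
  expect_gte(recall, 0.9)
  expect_lte(false_disc, 0.05)
})

test_that("marker discovery is stable across independent panel halves", {
  co <- simulate_cohort(sim_config(n_sites = 800L, n_fixed_diff = 200L,
                                   n_accessions = c(speciesA = 20L, speciesB = 20L,
                                                    hybrid = 0L, outgroup = 0L),
                                   seed = 53L))
  dm <- truth_dm(co)
  pops <- split(co$meta$id, co$meta$group)
  h1 <- find_diagnostic_snps(dm, pops$speciesA[1:10], pops$speciesB[1:10])
  h2 <- find_diagnostic_snps(dm, pops$speciesA[11:20], pops$speciesB[11:20])
  agree <- length(intersect(h1$site, h2$site)) /
    max(length(h1$site), length(h2$site))
  expect_gte(agree, 0.9)
})

test_that("composition error shrinks as the marker panel grows", {
  err_at <- function(nmk) {
    co <- simulate_cohort(sim_config(n_sites = 1200L, n_fixed_diff = nmk,
                                     n_accessions = c(speciesA = 10L, speciesB = 10L,
                                                      hybrid = 12L, outgroup = 0L),
                                     ploidy = list(speciesA = 8L, speciesB = 8L,
                                                   hybrid = 8L, outgroup = 8L),
                                     hybrid_composition = 0.7, seed = 54L))
    dm <- truth_dm(co)
    pops <- split(co$meta$id, co$meta$group)
    mk <- find_diagnostic_snps(dm, pops$speciesA, pops$speciesB)
    mk <- mk[mk$site %in% co$truth$fixed_diff_sites, ]
    comp <- genome_composition(dm, mk, pops$hybrid)
    truth <- co$truth$composition
    mean(abs(comp$fracB - truth$fracB[match(comp$id, truth$id)]))
  }
  expect_lt(err_at(1000L), err_at(100L))
})
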