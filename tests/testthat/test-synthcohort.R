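small_cfg <- function(...) {
  sim_config(n_sites = 200L, n_genes = 20L,
             n_accessions = c(speciesA = 6L, speciesB = 6L, hybrid = 4L,
                              outgroup = 0L), ...)
}

test_that("configs are validated", {
  expect_error(sim_config(divergence_fst = 0), "divergence_fst")
  expect_error(sim_config(divergence_fst = 1.2), "divergence_fst")
  expect_error(sim_config(ancestry_block_length_bp = 0), "positive")
  expect_error(sim_config(ploidy = list(speciesA = 7L, speciesB = 8L,
                                        hybrid = 8L, outgroup = 8L)), "even")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(error_rate = 0.7), "error_rate")
})

test_that("identical seeds give bit-identical cohorts", {
  c1 <- simulate_cohort(small_cfg(seed = 5L))
  c2 <- simulate_cohort(small_cfg(seed = 5L))
  expect_identical(c1$truth$dosages, c2$truth$dosages)
  expect_identical(c1$variants$ad_alt, c2$variants$ad_alt)
  expect_identical(c1$env, c2$env)
  c3 <- simulate_cohort(small_cfg(seed = 6L))
  expect_false(identical(c1$truth$dosages, c3$truth$dosages))
})

test_that("dosages respect ploidy and share site ordering with the truth", {
  co <- simulate_cohort(small_cfg(seed = 7L))
  pl <- matrix(rep(co$truth$ploidy, each = nrow(co$truth$dosages)),
               nrow(co$truth$dosages))
  expect_true(all(co$truth$dosages >= 0 & co$truth$dosages <= pl))
  expect_equal(nrow(co$variants$sites), nrow(co$truth$dosages))
  expect_true(all(co$truth$species_freq >= 0 & co$truth$species_freq <= 1))
})

test_that("vanishing divergence collapses both species onto the ancestral frequency", {
  cfg <- small_cfg(divergence_fst = 1e-6, seed = 8L)
  pr <- simulate_progenitor_populations(cfg)
  expect_lt(max(abs(pr$freq[, "speciesA"] - pr$freq[, "ancestral"])), 0.01)
  expect_lt(max(abs(pr$freq[, "speciesB"] - pr$freq[, "ancestral"])), 0.01)
})

test_that("hybrid mosaics honour composition limits and block lengths", {
  # composition 1 -> hybrids are speciesB draws
  cfg <- small_cfg(hybrid_composition = 1.0, seed = 9L)
  pr <- simulate_progenitor_populations(cfg)
  set.seed(1)
  h <- simulate_hybrids(cfg, pr$sites, pr$freq, n_hybrids = 4L)
  expect_true(all(h$ancestryB))
  expect_equal(h$true_composition$fracB, rep(1, 4))
  # block length far beyond the chromosome -> single ancestry per chromosome
  cfg2 <- small_cfg(ancestry_block_length_bp = 1e12, hybrid_composition = 0.5,
                    seed = 10L)
  set.seed(2)
  h2 <- simulate_hybrids(cfg2, pr$sites, pr$freq, n_hybrids = 6L)
  for (j in 1:6) {
    st <- split(h2$ancestryB[, j], pr$sites$chrom)
    expect_true(all(vapply(st, function(s) length(unique(s)) == 1, TRUE)))
  }
  # realised composition concentrates near the target for many blocks
  cfg3 <- sim_config(n_chromosomes = 2L, chrom_length_bp = 5e7, n_sites = 400L,
                     n_genes = 20L, site_spacing_model = "uniform",
                     ancestry_block_length_bp = 5e5,
                     hybrid_composition = 0.7,
                     n_accessions = c(speciesA = 6L, speciesB = 6L,
                                      hybrid = 10L, outgroup = 0L), seed = 11L)
  pr3 <- simulate_progenitor_populations(cfg3)
  set.seed(3)
  h3 <- simulate_hybrids(cfg3, pr3$sites, pr3$freq, n_hybrids = 20L)
  expect_lt(abs(mean(h3$true_composition$fracB) - 0.7), 0.05)
})

test_that("the read model reproduces its closed-form alt fraction", {
  cfg <- small_cfg(mean_depth = 100, depth_dispersion = Inf,
                   error_rate = 0.005, seed = 12L)
  sites <- data.frame(chrom = "chr01", pos0 = 1:10000 * 10L, ref = "A", alt = "G")
  # d = 0, eps = 0 -> alt depth always 0; d = p -> ref depth always 0
  cfg0 <- small_cfg(mean_depth = 50, depth_dispersion = Inf, error_rate = 0,
                    seed = 12L)
  set.seed(4)
  vt0 <- simulate_reads(matrix(0L, 100, 1), 8L, sites[1:100, ], cfg0, "s1")
  expect_true(all(vt0$ad_alt == 0))
  vtp <- simulate_reads(matrix(8L, 100, 1), 8L, sites[1:100, ], cfg0, "s1")
  expect_true(all(vtp$ad_ref == 0))
  # d = 1, p = 8: mean alt fraction within 3 se of (1/8)(1-eps) + (7/8)eps
  set.seed(5)
  vt <- simulate_reads(matrix(1L, 10000, 1), 8L, sites, cfg, "s1")
  f <- (1 / 8) * (1 - 0.005) + (7 / 8) * 0.005
  frac <- vt$ad_alt[, 1] / vt$dp[, 1]
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - f), 3 * se)
  # dosage above ploidy is refused
  expect_error(simulate_reads(matrix(9L, 10, 1), 8L, sites[1:10, ], cfg, "s1"),
               "exceeds ploidy")
})

test_that("environmental tables carry the planted structure", {
  # zero-effect env SNPs leave the frequency gradient-independent:
  # dosage correlation with the gradient stays at noise level
  cfg <- small_cfg(env_assoc_snps = data.frame(site = 1:5, effect = 0),
                   seed = 13L)
  co <- simulate_cohort(cfg)
  cc <- sapply(1:5, function(s)
    stats::cor(co$truth$dosages[s, ] / co$truth$ploidy, co$truth$gradient))
  expect_true(all(abs(cc) < 0.5))
  # a large-effect SNP lands in the top ranks of |z| downstream
  cfg2 <- sim_config(n_sites = 400L, n_genes = 20L,
                     env_assoc_snps = data.frame(site = 200L, effect = 0.9),
                     n_accessions = c(speciesA = 20L, speciesB = 20L,
                                      hybrid = 20L, outgroup = 0L), seed = 14L)
  co2 <- simulate_cohort(cfg2)
  dm <- truth_dm(co2)
  pcs <- env_pca(co2$env, 3)
  flt <- eaa_filter(dm, call_rate_min = 0.9)
  Z <- latent_factor_association(flt$G, pcs$scores[, 1], K = 4, n_runs = 3,
                                 seed = 1)
  z <- abs(apply(Z, 1, stats::median))
  planted_col <- which(flt$site_index == 200L)
  expect_true(length(planted_col) == 1)
  expect_true(rank(-z)[planted_col] <= 10)
  # two latent factors with zero noise -> env table has rank 2
  cfg3 <- small_cfg(n_env_factors = 2L, env_noise_sd = 0, seed = 15L)
  co3 <- simulate_cohort(cfg3)
  pc3 <- env_pca(co3$env, 5)
  expect_gt(sum(pc3$var_explained[1:2]), 0.999)
})

test_that("planted sweep genes depress domesticated-species diversity downstream", {
  ok <- sapply(1:8, function(s) {
    set.seed(s)
    planted <- sprintf("gene%04d", sample(100, 5))
    cfg <- sim_config(n_sites = 1500L, n_genes = 100L,
                      sweep_genes = data.frame(gene_id = planted, reduction = 0.1),
                      n_accessions = c(speciesA = 15L, speciesB = 15L,
                                       hybrid = 0L, outgroup = 0L), seed = s)
    co <- simulate_cohort(cfg)
    dm <- truth_dm(co)
    af <- allele_frequencies(dm, split(co$meta$id, co$meta$group))
    regions <- data.frame(region_id = co$genes$genes$gene_id,
                          chrom = co$genes$genes$chrom,
                          start = co$genes$genes$start,
                          end = co$genes$genes$end)
    piA <- nucleotide_diversity(af, "speciesA", regions)
    piB <- nucleotide_diversity(af, "speciesB", regions)
    pr <- pi_ratio_scan(piA, piB, top_fraction = 0.05, min_sites = 3L)
    sel <- pr$region_id %in% planted
    median(pr$ratio[sel]) > median(pr$ratio[!sel])
  })
  expect_gte(sum(ok), 7)
})

test_that("cohorts write and read back through standard formats", {
  co <- simulate_cohort(small_cfg(seed = 16L))
  d <- tempfile()
  paths <- write_cohort(co, d)
  expect_true(all(file.exists(paths)))
  vt <- read_variant_table(paths["vcf"])
  expect_identical(vt$ad_ref, co$variants$ad_ref)
  gm <- read_gene_models(paths["gff"])
  expect_identical(gm$genes$gene_id, co$genes$genes$gene_id)
  cfg_back <- yaml::read_yaml(paths["config"])
  expect_equal(cfg_back$seed, 16L)
  expect_equal(cfg_back$n_sites, 200L)
})
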