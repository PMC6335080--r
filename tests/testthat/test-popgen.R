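test_that("allele frequencies are dosage-weighted allele-copy counts", {
  D <- matrix(c(2L, 0L, 1L), 1, 3)
  dm <- toy_dm(D, stats::setNames(rep(8L, 3), paste0("s", 1:3)))
  af <- allele_frequencies(dm, list(all = paste0("s", 1:3)))
  expect_equal(unname(af$freq[1, 1]), 3 / 24)     # 0.125
  expect_equal(unname(af$n[1, 1]), 24)
  # all missing at a site -> missing frequency
  dm2 <- toy_dm(matrix(NA_integer_, 1, 3), stats::setNames(rep(8L, 3), paste0("s", 1:3)))
  af2 <- allele_frequencies(dm2, list(all = paste0("s", 1:3)))
  expect_true(is.na(af2$freq[1, 1]))
  expect_error(allele_frequencies(dm, list(a = "s1", b = "s1")), "disjoint")
})

test_that("per-site pi applies the small-sample corrected heterozygosity", {
  D <- rbind(c(2L, 0L, 1L), c(0L, 0L, 0L))
  dm <- toy_dm(D, stats::setNames(rep(8L, 3), paste0("s", 1:3)))
  af <- allele_frequencies(dm, list(all = paste0("s", 1:3)))
  pis <- nucleotide_diversity(af, "all")
  expect_equal(pis[1], (24 / 23) * 2 * 0.125 * 0.875)   # ~0.22826
  expect_equal(pis[2], 0)                               # monomorphic
  # region aggregation under both denominator modes
  reg <- data.frame(region_id = "r1", chrom = "chr01", start = 0L, end = 1000L)
  expect_equal(nucleotide_diversity(af, "all", reg, mode = "site")$pi,
               mean(pis))
  expect_equal(nucleotide_diversity(af, "all", reg, mode = "bp")$pi,
               sum(pis) / 1000)
})

test_that("Nei Fst matches hand evaluation and stays within bounds", {
  D <- rbind(c(rep(0L, 3), rep(8L, 3)),        # fixed difference
             c(rep(2L, 3), rep(2L, 3)))        # identical frequencies
  dm <- toy_dm(D, stats::setNames(rep(8L, 6), paste0("s", 1:6)))
  af <- allele_frequencies(dm, list(x = paste0("s", 1:3), y = paste0("s", 4:6)))
  fs <- fst_nei(af, "x", "y", small_sample = FALSE)
  expect_equal(fs$per_site[1], 1)              # fixed difference
  expect_equal(fs$per_site[2], 0)              # identical frequencies
  # hand case: pX = 0.2, pY = 0.8 -> (0.5 - 0.32)/0.5 = 0.36
  af2 <- af
  af2$freq <- matrix(c(0.2, 0.8), 1, dimnames = list(NULL, c("x", "y")))
  af2$n <- matrix(24, 1, 2, dimnames = list(NULL, c("x", "y")))
  af2$sites <- af$sites[1, , drop = FALSE]
  expect_equal(fst_nei(af2, "x", "y", small_sample = FALSE)$fst, 0.36)
  expect_equal(fst_nei(af2, "x", "y", small_sample = FALSE)$per_site[1], 0.36)
  # identical frequencies everywhere -> 0
  af3 <- af2
  af3$freq[] <- 0.4
  expect_equal(fst_nei(af3, "x", "y", small_sample = FALSE)$fst, 0)
  # relabeling alleles (p -> 1-p in both populations) leaves Fst unchanged
  af4 <- af2; af4$freq <- 1 - af4$freq
  expect_equal(fst_nei(af4, "x", "y")$fst, fst_nei(af2, "x", "y")$fst)
})

test_that("dosage-fraction distance behaves as a normalized Manhattan distance", {
  D <- rbind(c(0L, 8L, 4L), c(0L, 8L, 4L))
  dm <- toy_dm(D, stats::setNames(rep(8L, 3), paste0("s", 1:3)))
  dmat <- pairwise_distance_matrix(dm, min_shared = 1L)
  expect_equal(unname(dmat$dist["s1", "s1"]), 0)
  expect_equal(unname(dmat$dist["s1", "s2"]), 1)   # opposite-fixed at every site
  expect_equal(unname(dmat$dist["s1", "s3"]), 0.5)
  expect_equal(dmat$dist, t(dmat$dist))
  # mixed ploidy pairs compare on fractions
  dm2 <- toy_dm(rbind(c(4L, 6L), c(8L, 12L)), c(s1 = 8L, s2 = 12L))
  d2 <- pairwise_distance_matrix(dm2, min_shared = 1L)
  expect_equal(unname(d2$dist["s1", "s2"]), 0)
  # pairs under the shared-site minimum are missing
  d3 <- pairwise_distance_matrix(dm, min_shared = 10L)
  expect_true(is.na(d3$dist["s1", "s2"]))
})

test_that("neighbour joining solves small trees exactly", {
  # 3 taxa: branch lengths are the three-point formulas
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(structure(list(dist = D), class = "distance_matrix"))
  bl <- sort(tr$edge.length)
  expect_equal(bl, sort(c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2, (4 + 5 - 3) / 2)))
  # additive 8-taxon matrices are reconstructed exactly
  set.seed(31)
  for (i in 1:3) {
    tr0 <- ape::rtree(8, br = function(n) runif(n, 0.5, 2))
    D0 <- cophenetic(tr0)
    tr1 <- nj_tree(structure(list(dist = D0), class = "distance_matrix"))
    expect_equal(cophenetic(tr1)[rownames(D0), colnames(D0)], D0,
                 tolerance = 1e-8)
  }
  # two identical accessions form a zero-length cherry
  D2 <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr2 <- nj_tree(structure(list(dist = D2), class = "distance_matrix"))
  tip_edges <- tr2$edge.length[tr2$edge[, 2] %in% match(c("a", "b"), tr2$tip.label)]
  expect_equal(tip_edges, c(0, 0))
  expect_error(nj_tree(structure(list(dist = matrix(c(0, NA, NA, 0), 2)),
                                 class = "distance_matrix")), "missing")
})

test_that("ancestry contributors rank progenitors by distance with support", {
  D <- matrix(0.5, 4, 4, dimnames = list(c("h1", "h2", "p1", "p2"),
                                         c("h1", "h2", "p1", "p2")))
  diag(D) <- 0
  D["h1", "p1"] <- D["p1", "h1"] <- 0      # hybrid identical to progenitor p1
  D["h2", "p2"] <- D["p2", "h2"] <- 0.1
  dmat <- structure(list(dist = D), class = "distance_matrix")
  ac <- ancestry_contributors(dmat, c("h1", "h2"), c("p1", "p2"), k = 5)
  r1 <- ac$per_hybrid[ac$per_hybrid$rank == 1, ]
  expect_equal(r1$progenitor[r1$hybrid == "h1"], "p1")
  expect_equal(r1$distance[r1$hybrid == "h1"], 0)
  # k larger than the panel returns every progenitor, ordered
  expect_equal(sum(ac$per_hybrid$hybrid == "h1"), 2L)
  expect_equal(ac$contributors$support, c(0.5, 0.5))
  expect_error(ancestry_contributors(dmat, character(0), "p1"), "")
})

test_that("snp density counts sites per window", {
  sites <- data.frame(chrom = "chr01", pos0 = c(10L, 20L, 1500L))
  d <- snp_density(sites, window_bp = 1000)
  expect_equal(d$n_snps[1:2], c(2L, 1L))
})
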