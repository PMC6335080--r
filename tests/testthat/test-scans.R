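freq_table <- function(freq, pos = NULL) {
  n <- nrow(freq)
  list(freq = freq, n = matrix(200, n, ncol(freq), dimnames = dimnames(freq)),
       sites = data.frame(chrom = "chr01",
                          pos0 = if (is.null(pos)) seq_len(n) * 1000L else pos))
}

test_that("PBS is zero for identical populations and maximal on the target branch", {
  f <- matrix(runif(200, 0.1, 0.9), 100, 2)
  af <- freq_table(cbind(t = f[, 1], s = f[, 1], o = f[, 1]))
  tr <- window_branch_score(af, "t", "s", "o", stride = 20L)
  expect_true(all(abs(tr$score) < 1e-12))
  # target fixed-different, sister == outgroup: PBS = T_ts = T_to
  af2 <- freq_table(cbind(t = rep(1, 100), s = rep(0, 100), o = rep(0, 100)))
  tr2 <- window_branch_score(af2, "t", "s", "o", stride = 20L, fst_cap = 0.999)
  expect_equal(tr2$score, rep(-log1p(-0.999), 5), tolerance = 1e-12)
  # central SNP of each 20-SNP window is recorded
  expect_equal(tr2$central_snp, c(10L, 30L, 50L, 70L, 90L))
})

test_that("the three branch statistics sum to the total branch length", {
  set.seed(71)
  f <- matrix(runif(300, 0.05, 0.95), 100, 3,
              dimnames = list(NULL, c("t", "s", "o")))
  af <- freq_table(f)
  nei <- function(p1, p2) {
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    ht <- 2 * ((p1 + p2) / 2) * (1 - (p1 + p2) / 2)
    ifelse(ht > 0, (ht - hs) / ht, 0)
  }
  tr_t <- window_branch_score(af, "t", "s", "o", stride = 10L)
  tr_s <- window_branch_score(af, "s", "t", "o", stride = 10L)
  tr_o <- window_branch_score(af, "o", "t", "s", stride = 10L)
  tt <- -log1p(-pmin(nei(f[, "t"], f[, "s"]), 1 - 1e-4))
  tto <- -log1p(-pmin(nei(f[, "t"], f[, "o"]), 1 - 1e-4))
  tso <- -log1p(-pmin(nei(f[, "s"], f[, "o"]), 1 - 1e-4))
  total <- (tt + tto + tso) / 2
  win_total <- colMeans(matrix(total, 10))
  expect_equal(tr_t$score + tr_s$score + tr_o$score, win_total, tolerance = 1e-10)
})

test_that("top-fraction selection honours ties and merges adjacent windows", {
  tr <- data.frame(chrom = "chr01", start = (0:99) * 1000L,
                   end = (0:99) * 1000L + 900L, score = 1:100)
  sel <- select_top_fraction_windows(tr, 0.01)
  expect_equal(nrow(sel), 1L)            # exactly the score-100 window
  expect_equal(sel$max_score, 100)
  # two adjacent selected windows merge into one interval
  tr2 <- tr; tr2$score[50:51] <- c(1000, 999)
  sel2 <- select_top_fraction_windows(tr2, 0.02)
  expect_equal(nrow(sel2), 1L)
  expect_equal(sel2$n_windows, 2L)
  expect_equal(c(sel2$start, sel2$end), c(49000, 50900))
  # all scores equal -> every window selected, with a warning
  tr3 <- tr; tr3$score <- 5
  expect_warning(sel3 <- select_top_fraction_windows(tr3, 0.01), "all windows")
  expect_equal(sum(sel3$n_windows), 100L)
  # smaller fraction selects a subset (threshold monotonicity)
  s5 <- select_top_fraction_windows(tr, 0.05)
  s1 <- select_top_fraction_windows(tr, 0.01)
  expect_true(all(s1$start %in% seq(s5$start, s5$end, 1000) |
                    s1$start >= s5$start))
  expect_gte(attr(s1, "threshold"), attr(s5, "threshold"))
  expect_error(select_top_fraction_windows(tr, 0), "fraction")
})

test_that("pi-ratio flags the top quantile with inclusive ties", {
  mk <- function(pi, n = 10L) data.frame(region_id = sprintf("g%03d", seq_along(pi)),
                                         pi = pi, n_sites = n)
  # 100 genes, one huge ratio: flagged set = ties at/above the 95th percentile
  pi1 <- c(100e-3, rep(1e-3, 99)); pi2 <- rep(1e-3, 100)
  pr <- pi_ratio_scan(mk(pi1), mk(pi2), top_fraction = 0.05)
  orc_cut <- stats::quantile(pr$ratio, 0.95, names = FALSE)
  expect_identical(pr$flagged, pr$ratio >= orc_cut)
  expect_true(pr$flagged[pr$region_id == "g001"])
  # equal diversities give ratio 1, unflagged when others exceed the cutoff
  expect_equal(pr$ratio[2], 1, tolerance = 1e-9)
  # pseudocount keeps zero-diversity genes rankable
  pr2 <- pi_ratio_scan(mk(c(1e-3, 0)), mk(c(0, 1e-3)), top_fraction = 0.5)
  expect_true(all(is.finite(pr2$ratio)))
  expect_equal(attr(pr2, "pseudocount"), 1e-3)
  # genes under the site minimum are excluded and counted
  pr3 <- pi_ratio_scan(mk(pi1, n = c(1L, rep(10L, 99))), mk(pi2),
                       top_fraction = 0.05, min_sites = 5L)
  expect_equal(attr(pr3, "n_excluded"), 1L)
  expect_false("g001" %in% pr3$region_id)
  # flags are invariant under a monotone transform of the ratio
  expect_identical(pr$flagged, rank(pr$ratio) >= sort(rank(pr$ratio))[96])
})

test_that("interval/gene overlap and curated bins are reported", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr01",
                      start = c(100L, 5000L, 9000L),
                      end = c(600L, 5600L, 9600L), strand = "+",
                      complete = TRUE)
  gm <- gene_model_set(genes, data.frame(gene_id = character(),
                                         type = character(), start = integer(),
                                         end = integer(), phase = integer()))
  iv <- data.frame(chrom = "chr01", start = 0L, end = 1000L)
  ov <- interval_gene_overlap(iv, gm,
                              gene_sets = list(a = c("g1", "g2"), b = c("g2", "g3"),
                                               c = "g2"),
                              curated = data.frame(gene_id = "c1", chrom = "chr01",
                                                   start = 55000L, end = 56000L),
                              flank = 50000L)
  expect_equal(ov$genes_in_intervals, "g1")
  expect_equal(ov$intersections[["a&b"]], 1L)
  expect_equal(ov$intersections[["a&b&c"]], 1L)
  # gene 40 kb away falls inside the 50 kb curated bin
  expect_true("g3" %in% ov$curated_hits$candidate)
  expect_false("g1" %in% ov$curated_hits$candidate)
  # disjoint sets -> zero intersections
  ov2 <- interval_gene_overlap(NULL, gm, gene_sets = list(a = "g1", b = "g2"))
  expect_equal(ov2$intersections[["a&b"]], 0L)
  expect_error(interval_gene_overlap(data.frame(chrom = "chrX", start = 1L,
                                                end = 2L), gm),
               "absent")
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  uni <- sprintf("g%03d", 1:100)
  cand <- uni[1:5]
  res <- enrichment_test(cand, list(t1 = uni[1:5], t2 = uni[6:20]), uni)
  expect_equal(res$p[res$term == "t1"], 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$p[res$term == "t2"], 1)    # no candidate members
  # exact enumeration oracle on a universe of 12 genes
  uni2 <- letters[1:12]; cand2 <- letters[1:4]; term <- letters[c(1, 2, 5, 6, 7)]
  k <- length(intersect(term, cand2))
  combos <- utils::combn(12, 4)
  orc <- mean(apply(combos, 2, function(ix)
    length(intersect(uni2[ix], term)) >= k))
  expect_equal(enrichment_test(cand2, list(t = term), uni2)$p, orc,
               tolerance = 1e-12)
  expect_error(enrichment_test(c(cand, "zz"), list(t1 = uni), uni), "universe")
  # permutation null: rejection rate at 0.05 matches its exact discrete level
  set.seed(72)
  term_map <- list(t = uni[1:20])
  exact_level <- sum(dhyper(0:10, 20, 80, 10) *
                       (phyper(0:10 - 1, 20, 80, 10, lower.tail = FALSE) < 0.05))
  hits <- replicate(400, {
    enrichment_test(sample(uni, 10), term_map, uni)$p < 0.05
  })
  se <- sqrt(exact_level * (1 - exact_level) / 400)
  expect_lt(abs(mean(hits) - exact_level), 3 * se + 0.01)
})
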