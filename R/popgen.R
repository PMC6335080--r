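# Core dosage-based population statistics.

#' Dosage-weighted allele frequencies per population
#'
#' The alternate-allele frequency in a population is the sum of called
#' dosages divided by the sum of ploidies over non-missing members, i.e.
#' allele copies are counted, so mixed-ploidy populations are handled
#' naturally.
#'
#' @param dm a [dosage_matrix()].
#' @param populations named list of accession id (or index) vectors; must
#'   reference disjoint accession sets.
#' @return list of class `allele_freq_table` with matrices `freq` and `n`
#'   (allele-copy sample sizes), both sites x populations, and the site table.
#' @export
allele_frequencies <- function(dm, populations) {
  stopifnot(inherits(dm, "dosage_matrix"), length(populations) >= 1)
  idx <- lapply(populations, function(p)
    if (is.character(p)) match(p, dm$samples) else as.integer(p))
  if (anyNA(unlist(idx))) stop("unknown accession id in populations")
  if (anyDuplicated(unlist(idx))) stop("populations must be disjoint")
  ns <- nrow(dm$dosage)
  freq <- n <- matrix(NA_real_, ns, length(populations),
                      dimnames = list(NULL, names(populations)))
  for (k in seq_along(idx)) {
    D <- dm$dosage[, idx[[k]], drop = FALSE]
    pl <- matrix(rep(dm$ploidy[idx[[k]]], each = ns), ns)
    pl[is.na(D)] <- NA
    ncop <- rowSums(pl, na.rm = TRUE)
    f <- rowSums(D, na.rm = TRUE) / ncop
    f[ncop == 0] <- NA
    freq[, k] <- f
    n[, k] <- ncop
  }
  structure(list(freq = freq, n = n, sites = dm$sites),
            class = "allele_freq_table")
}

#' Nucleotide diversity per site and per region
#'
#' Per-site diversity is the small-sample-corrected expected heterozygosity
#' `pi = n/(n-1) * 2 p (1-p)` with `n` the allele-copy sample size. Regional
#' diversity aggregates over a region's genotyped variant sites under one of
#' two denominator modes: `"bp"` (sum of site pi divided by the region's
#' targeted length - diversity per covered base pair, the default, which is
#' what makes capture data comparable across regions) or `"site"` (mean pi
#' per variant site).
#'
#' @param af an `allele_freq_table` from [allele_frequencies()].
#' @param population column name or index of `af`.
#' @param regions optional data.frame (`region_id`, `chrom`, `start`, `end`,
#'   0-based half-open) over which to aggregate.
#' @param mode denominator mode, `"bp"` or `"site"`.
#' @param min_n sites with fewer allele copies are skipped (counted in
#'   attribute `n_skipped`).
#' @return if `regions` is NULL, numeric vector of per-site pi; otherwise a
#'   data.frame (`region_id`, `pi`, `n_sites`).
#' @export
nucleotide_diversity <- function(af, population = 1, regions = NULL,
                                 mode = c("bp", "site"), min_n = 2) {
  mode <- match.arg(mode)
  p <- af$freq[, population]
  n <- af$n[, population]
  ok <- !is.na(p) & n >= min_n
  pi_site <- rep(NA_real_, length(p))
  pi_site[ok] <- (n[ok] / (n[ok] - 1)) * 2 * p[ok] * (1 - p[ok])
  if (is.null(regions)) {
    attr(pi_site, "n_skipped") <- sum(!ok)
    return(pi_site)
  }
  res <- regions[, "region_id", drop = FALSE]
  res$pi <- NA_real_
  res$n_sites <- 0L
  for (i in seq_len(nrow(regions))) {
    sel <- which(af$sites$chrom == regions$chrom[i] &
                   af$sites$pos0 >= regions$start[i] &
                   af$sites$pos0 < regions$end[i] & ok)
    res$n_sites[i] <- length(sel)
    if (!length(sel)) next
    res$pi[i] <- if (mode == "bp")
      sum(pi_site[sel]) / (regions$end[i] - regions$start[i])
    else mean(pi_site[sel])
  }
  res
}

#' Nei fixation index between two populations
#'
#' Per site, `Hs` is the mean of the two subpopulation expected
#' heterozygosities `2p(1-p)` and `Ht = 2 pbar (1-pbar)` with `pbar` the
#' mean frequency; `Fst = (Ht - Hs)/Ht`. The genome-wide value is the ratio
#' of sums `sum(Ht - Hs)/sum(Ht)` over sites with `Ht > 0` (variance-
#' stabilised, as opposed to a mean of per-site ratios).
#'
#' With `small_sample = TRUE` (default) the genome-wide estimate uses
#' unbiased moment estimators of the subpopulation and pooled
#' heterozygosities (each `2p(1-p)` rescaled by `n/(n-1)` allele copies,
#' `Ht` augmented by the sampling variance of the mean frequency), removing
#' the upward finite-sample bias of the plain ratio; the per-site values
#' always use the plain definition.
#'
#' @param af an `allele_freq_table` covering both populations.
#' @param pop_x,pop_y population columns.
#' @param small_sample apply the allele-copy sample-size correction to the
#'   genome-wide estimate.
#' @return list with `fst` (genome-wide), `per_site` (vector, NA where
#'   `Ht = 0` or a frequency is missing) and `n_sites` used.
#' @export
fst_nei <- function(af, pop_x, pop_y, small_sample = TRUE) {
  px <- af$freq[, pop_x]; py <- af$freq[, pop_y]
  ok <- !is.na(px) & !is.na(py)
  hs <- (2 * px * (1 - px) + 2 * py * (1 - py)) / 2
  pbar <- (px + py) / 2
  ht <- 2 * pbar * (1 - pbar)
  if (small_sample) {
    nx <- pmax(af$n[, pop_x], 2); ny <- pmax(af$n[, pop_y], 2)
    hx <- 2 * px * (1 - px) * nx / (nx - 1)
    hy <- 2 * py * (1 - py) * ny / (ny - 1)
    hs_c <- (hx + hy) / 2
    ht_c <- 2 * pbar * (1 - pbar) + (hx / nx + hy / ny) / 4
  } else {
    hs_c <- hs; ht_c <- ht
  }
  per_site <- unname(ifelse(ok & ht > 0, (ht - hs) / ht, NA_real_))
  use <- ok & ht > 0
  if (!any(use)) {
    warning("no shared polymorphic sites; Fst undefined")
    return(list(fst = NA_real_, per_site = per_site, n_sites = 0L))
  }
  list(fst = sum(ht_c[use] - hs_c[use]) / sum(ht_c[use]),
       per_site = per_site, n_sites = sum(use))
}

#' Pairwise dosage-fraction distance matrix
#'
#' `d(i, j)` is the mean over shared non-missing sites of
#' `|d_i/p_i - d_j/p_j|` (Manhattan distance on dosage fractions), which
#' keeps mixed-ploidy accessions comparable. Pairs sharing fewer than
#' `min_shared` genotyped sites get a missing distance.
#'
#' @param dm a [dosage_matrix()].
#' @param min_shared minimum shared non-missing sites per pair.
#' @return list of class `distance_matrix` with symmetric `dist` and
#'   `shared` (site-count) matrices.
#' @export
pairwise_distance_matrix <- function(dm, min_shared = 100L) {
  X <- dm$dosage / rep(dm$ploidy, each = nrow(dm$dosage))
  na <- length(dm$samples)
  D <- matrix(0, na, na, dimnames = list(dm$samples, dm$samples))
  S <- matrix(nrow(X), na, na, dimnames = dimnames(D))
  for (i in seq_len(na - 1)) {
    js <- (i + 1):na
    dif <- abs(X[, js, drop = FALSE] - X[, i])
    sh <- colSums(!is.na(dif))
    d <- colMeans(dif, na.rm = TRUE)
    d[sh < min_shared] <- NA_real_
    d[sh == 0] <- NA_real_
    D[i, js] <- D[js, i] <- d
    S[i, js] <- S[js, i] <- sh
  }
  diag(S) <- colSums(!is.na(X))
  structure(list(dist = D, shared = S, min_shared = min_shared),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix:", nrow(x$dist), "accessions;",
      sum(is.na(x$dist[upper.tri(x$dist)])), "pairs below",
      x$min_shared, "shared sites\n")
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (via \pkg{ape}); negative branch-length
#' estimates are clamped to zero and logged in attribute `n_clamped`.
#'
#' @param dmat a `distance_matrix` from [pairwise_distance_matrix()].
#' @return an `ape` `phylo` object.
#' @export
nj_tree <- function(dmat) {
  D <- if (inherits(dmat, "distance_matrix")) dmat$dist else as.matrix(dmat)
  if (anyNA(D))
    stop("distance matrix has missing entries; subset accessions or impute first")
  tr <- ape::nj(stats::as.dist(D))
  ncl <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "n_clamped") <- ncl
  tr
}

#' Rank candidate ancestry contributors for hybrids
#'
#' For every hybrid accession, the `k` nearest progenitor accessions by
#' genetic distance. Group-level contributors are the progenitors that are
#' rank 1 for at least one hybrid, reported with support counts (the
#' fraction of hybrids for which they are nearest).
#'
#' @param dmat a `distance_matrix`.
#' @param hybrids,progenitors accession id vectors (non-empty, present in
#'   the matrix).
#' @param k number of nearest progenitors per hybrid.
#' @return list with `per_hybrid` (data.frame `hybrid`, `rank`,
#'   `progenitor`, `distance`) and `contributors` (data.frame `progenitor`,
#'   `n_rank1`, `support`).
#' @export
ancestry_contributors <- function(dmat, hybrids, progenitors, k = 3L) {
  stopifnot(length(hybrids) > 0, length(progenitors) > 0)
  D <- dmat$dist
  miss <- setdiff(c(hybrids, progenitors), rownames(D))
  if (length(miss)) stop("accessions absent from distance matrix: ",
                         paste(miss, collapse = ", "))
  k <- min(k, length(progenitors))
  rows <- lapply(hybrids, function(h) {
    d <- D[h, progenitors]
    o <- order(d)[seq_len(k)]
    data.frame(hybrid = h, rank = seq_len(k), progenitor = progenitors[o],
               distance = unname(d[o]))
  })
  per_hybrid <- do.call(rbind, rows)
  r1 <- per_hybrid$progenitor[per_hybrid$rank == 1]
  tab <- sort(table(r1), decreasing = TRUE)
  contributors <- data.frame(progenitor = names(tab),
                             n_rank1 = as.integer(tab),
                             support = as.integer(tab) / length(hybrids))
  list(per_hybrid = per_hybrid, contributors = contributors)
}

#' SNP density per genomic window
#'
#' @param sites site data.frame (`chrom`, `pos0`).
#' @param window_bp window size.
#' @param chrom_lengths named vector of chromosome lengths (bp); default the
#'   last site position per chromosome.
#' @return data.frame (`chrom`, `start`, `end`, `n_snps`, `snps_per_kbp`).
#' @export
snp_density <- function(sites, window_bp = 1e6, chrom_lengths = NULL) {
  out <- lapply(unique(sites$chrom), function(ch) {
    pos <- sites$pos0[sites$chrom == ch]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(pos) + 1
    brk <- seq(0, len + window_bp, by = window_bp)
    cnt <- table(cut(pos, brk, right = FALSE))
    data.frame(chrom = ch, start = utils::head(brk, -1), end = brk[-1],
               n_snps = as.integer(cnt),
               snps_per_kbp = as.integer(cnt) / (window_bp / 1000))
  })
  do.call(rbind, out)
}
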