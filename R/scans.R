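# Selective-sweep scanning and domestication/selection gene discovery.

.nei_fst_per_site <- function(p1, p2) {
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  ifelse(ht > 0, (ht - hs) / ht, 0)
}

#' Population-branch-statistic window score track
#'
#' Per site, the three pairwise Nei Fst values among target, sister and
#' outgroup are transformed to branch lengths `T = -log(1 - Fst)` and the
#' target's branch is `PBS = (T_ts + T_to - T_so) / 2`. Scores are averaged
#' over consecutive non-overlapping windows of `stride` SNPs, each window
#' reported at its central SNP with both its SNP-index and bp span (SNP-count
#' windows have variable physical extent). Fst values of 1 are capped so the
#' branch transform stays finite (capped sites are counted in attribute
#' `n_capped`).
#'
#' @param af an `allele_freq_table` over at least the three populations.
#' @param target,sister,outgroup population column names of `af`.
#' @param stride SNPs per window (one window per stride).
#' @param fst_cap cap applied to per-site Fst before the log transform.
#' @return data.frame of class `window_score_track`: `chrom`, `start`,
#'   `end` (bp span, 0-based half-open), `first_snp`, `central_snp`,
#'   `last_snp` (site row indices), `n_snps`, `score`.
#' @export
window_branch_score <- function(af, target, sister, outgroup, stride = 20L,
                                fst_cap = 1 - 1e-4) {
  f_t <- af$freq[, target]; f_s <- af$freq[, sister]; f_o <- af$freq[, outgroup]
  fst_ts <- .nei_fst_per_site(f_t, f_s)
  fst_to <- .nei_fst_per_site(f_t, f_o)
  fst_so <- .nei_fst_per_site(f_s, f_o)
  n_capped <- sum(c(fst_ts, fst_to, fst_so) > fst_cap, na.rm = TRUE)
  tr <- function(f) -log1p(-pmin(f, fst_cap))
  pbs <- (tr(fst_ts) + tr(fst_to) - tr(fst_so)) / 2
  rows <- list()
  for (ch in unique(af$sites$chrom)) {
    idx <- which(af$sites$chrom == ch)
    nw <- length(idx) %/% stride
    if (nw == 0) next
    for (w in seq_len(nw)) {
      wi <- idx[((w - 1) * stride + 1):(w * stride)]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch,
        start = af$sites$pos0[wi[1]],
        end = af$sites$pos0[wi[length(wi)]] + 1L,
        first_snp = wi[1],
        central_snp = wi[ceiling(stride / 2)],
        last_snp = wi[length(wi)],
        n_snps = length(wi),
        score = mean(pbs[wi], na.rm = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_capped") <- n_capped
  attr(out, "stride") <- stride
  class(out) <- c("window_score_track", "data.frame")
  out
}

#' Select the top-scoring fraction of windows and merge into sweep intervals
#'
#' The threshold is the `(1 - fraction)` empirical quantile of window
#' scores; windows scoring at or above it are selected (ties at the
#' threshold all included), and selected windows that are adjacent in window
#' order or physically overlapping are merged into candidate sweep
#' intervals.
#'
#' @param track a `window_score_track` (or any data.frame with `chrom`,
#'   `start`, `end`, `score`, e.g. externally computed scan scores read from
#'   TSV).
#' @param fraction top fraction to select, in (0, 1).
#' @return data.frame of class `sweep_interval_set`: `chrom`, `start`,
#'   `end`, `max_score`, `n_windows`; threshold kept as attribute.
#' @export
select_top_fraction_windows <- function(track, fraction = 0.01) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (nrow(track) < 100 && fraction <= 0.01)
    warning("fewer than 100 windows: top-", fraction, " selection is coarse")
  thr <- stats::quantile(track$score, 1 - fraction, na.rm = TRUE, names = FALSE)
  sel <- which(track$score >= thr)
  if (length(sel) == nrow(track))
    warning("all windows selected (tied scores)")
  rows <- list()
  for (ch in unique(track$chrom[sel])) {
    w <- sel[track$chrom[sel] == ch]
    w <- w[order(track$start[w])]
    cur <- track[w[1], ]
    nwin <- 1L
    flush <- function(cur, nwin)
      data.frame(chrom = ch, start = cur$start, end = cur$end,
                 max_score = cur$score, n_windows = nwin)
    for (i in seq_along(w)[-1]) {
      nxt <- track[w[i], ]
      adjacent <- (w[i] - w[i - 1] == 1L) || (nxt$start <= cur$end)
      if (adjacent) {
        cur$end <- max(cur$end, nxt$end)
        cur$score <- max(cur$score, nxt$score)
        nwin <- nwin + 1L
      } else {
        rows[[length(rows) + 1]] <- flush(cur, nwin)
        cur <- nxt; nwin <- 1L
      }
    }
    rows[[length(rows) + 1]] <- flush(cur, nwin)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  max_score = numeric(), n_windows = integer())
  attr(out, "threshold") <- thr
  attr(out, "fraction") <- fraction
  class(out) <- c("sweep_interval_set", "data.frame")
  out
}

#' Per-gene nucleotide-diversity ratio scan
#'
#' Flags genes whose diversity ratio `(pi_1 + c) / (pi_2 + c)` reaches the
#' top `top_fraction` quantile (ties at the cutoff all included). The
#' pseudocount `c` is the smallest positive per-gene pi observed across both
#' populations, which keeps zero-diversity genes rankable without letting
#' them dominate; it is recorded as an attribute.
#'
#' @param pi1,pi2 per-gene diversity tables from [nucleotide_diversity()]
#'   (`region_id`, `pi`, `n_sites`), numerator and denominator populations.
#' @param top_fraction flagged fraction.
#' @param min_sites genes with fewer genotyped sites in either population
#'   are excluded (count reported in attribute `n_excluded`).
#' @return data.frame of class `pi_ratio_table`: `region_id`, `pi1`, `pi2`,
#'   `ratio`, `flagged`.
#' @export
pi_ratio_scan <- function(pi1, pi2, top_fraction = 0.05, min_sites = 5L) {
  m <- merge(pi1, pi2, by = "region_id", suffixes = c("_1", "_2"))
  ok <- !is.na(m$pi_1) & !is.na(m$pi_2) &
    m$n_sites_1 >= min_sites & m$n_sites_2 >= min_sites
  n_excluded <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) stop("no gene passes the site minimum")
  pos <- c(m$pi_1[m$pi_1 > 0], m$pi_2[m$pi_2 > 0])
  cc <- if (length(pos)) min(pos) else 1e-9
  ratio <- (m$pi_1 + cc) / (m$pi_2 + cc)
  cutoff <- stats::quantile(ratio, 1 - top_fraction, names = FALSE)
  out <- data.frame(region_id = m$region_id, pi1 = m$pi_1, pi2 = m$pi_2,
                    ratio = ratio, flagged = ratio >= cutoff)
  attr(out, "pseudocount") <- cc
  attr(out, "cutoff") <- cutoff
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("pi_ratio_table", "data.frame")
  out
}

#' Overlap report: sweep intervals, candidate gene sets, curated orthologs
#'
#' Reports (i) genes overlapping sweep intervals, (ii) pairwise and
#' three-way intersection counts among up to three candidate gene sets and
#' (iii) candidate genes falling within curated-ortholog bins (curated gene
#' span extended by `flank` on both sides).
#'
#' @param intervals sweep intervals (`chrom`, `start`, `end`) or NULL.
#' @param gm a [gene_model_set()].
#' @param gene_sets named list of candidate gene-id vectors (<= 3 used for
#'   intersection counts).
#' @param curated optional data.frame (`gene_id`, `chrom`, `start`, `end`)
#'   of curated ortholog positions.
#' @param flank bin extension in bp.
#' @return list with `genes_in_intervals`, `intersections` (named counts)
#'   and `curated_hits` (data.frame `candidate`, `curated`).
#' @export
interval_gene_overlap <- function(intervals = NULL, gm, gene_sets = list(),
                                  curated = NULL, flank = 50000L) {
  res <- list()
  gr_genes <- GenomicRanges::GRanges(gm$genes$chrom,
                                     IRanges::IRanges(gm$genes$start + 1L, gm$genes$end),
                                     gene_id = gm$genes$gene_id)
  if (!is.null(intervals) && nrow(intervals)) {
    bad <- setdiff(unique(intervals$chrom), unique(gm$genes$chrom))
    if (length(bad)) stop("interval chromosomes absent from gene models: ",
                          paste(bad, collapse = ", "))
    gr_iv <- GenomicRanges::GRanges(intervals$chrom,
                                    IRanges::IRanges(intervals$start + 1L, intervals$end))
    ov <- GenomicRanges::findOverlaps(gr_genes, gr_iv)
    res$genes_in_intervals <- unique(gm$genes$gene_id[S4Vectors::queryHits(ov)])
  } else res$genes_in_intervals <- character(0)
  if (length(gene_sets)) {
    ns <- names(gene_sets)
    counts <- vapply(gene_sets, length, 1L)
    names(counts) <- ns
    inter <- list()
    if (length(gene_sets) >= 2) {
      cmb <- utils::combn(seq_along(gene_sets), 2)
      for (c1 in seq_len(ncol(cmb))) {
        i <- cmb[1, c1]; j <- cmb[2, c1]
        inter[[paste(ns[i], ns[j], sep = "&")]] <-
          length(intersect(gene_sets[[i]], gene_sets[[j]]))
      }
    }
    if (length(gene_sets) >= 3)
      inter[[paste(ns[1:3], collapse = "&")]] <-
        length(Reduce(intersect, gene_sets[1:3]))
    res$intersections <- c(as.list(counts), inter)
  } else res$intersections <- list()
  if (!is.null(curated) && nrow(curated)) {
    gr_bin <- GenomicRanges::GRanges(curated$chrom,
                                     IRanges::IRanges(pmax(1L, curated$start + 1L - flank),
                                                      curated$end + flank))
    cand <- unique(unlist(gene_sets, use.names = FALSE))
    gsel <- gr_genes[gm$genes$gene_id %in% cand]
    ov <- GenomicRanges::findOverlaps(gsel, gr_bin)
    res$curated_hits <- data.frame(
      candidate = gsel$gene_id[S4Vectors::queryHits(ov)],
      curated = curated$gene_id[S4Vectors::subjectHits(ov)])
  } else res$curated_hits <- data.frame(candidate = character(),
                                        curated = character())
  res
}

#' Hypergeometric term-enrichment test with FDR control
#'
#' Upper-tail hypergeometric p per term (probability of drawing at least the
#' observed number of term members among the candidates) with
#' Benjamini-Hochberg adjustment across terms. A stand-in for GO-category
#' enrichment when a full annotation stack is unavailable.
#'
#' @param candidates candidate gene ids (subset of `universe`).
#' @param term_map named list: term -> gene-id vector.
#' @param universe background gene ids.
#' @return data.frame (`term`, `n_term`, `n_hit`, `p`, `fdr`), ordered by p.
#' @export
enrichment_test <- function(candidates, term_map, universe) {
  if (!all(candidates %in% universe)) stop("candidates must be within universe")
  N <- length(unique(universe))
  n <- length(unique(candidates))
  rows <- lapply(names(term_map), function(tm) {
    K <- length(intersect(term_map[[tm]], universe))
    if (K == 0) return(NULL)
    k <- length(intersect(term_map[[tm]], candidates))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_term = K, n_hit = k, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term with universe members")
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
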