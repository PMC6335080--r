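# Dosage-based linkage disequilibrium: r^2 pairs, decay curves, decay distance.

#' Filter and thin SNPs for LD analysis
#'
#' Applies MAF and call-rate floors, then greedily thins sites left-to-right
#' per chromosome so kept sites are at least `spacing_bp` apart
#' (deterministic: the leftmost qualifying site always wins).
#'
#' @param dm a [dosage_matrix()].
#' @param maf_min pooled minor-allele-frequency floor.
#' @param call_rate_min site call-rate floor.
#' @param spacing_bp minimum spacing; 0 disables thinning.
#' @return integer vector of retained site indices.
#' @export
thin_snps <- function(dm, maf_min = 0.05, call_rate_min = 0.95, spacing_bp = 0) {
  keep <- which(dm$maf >= maf_min & dm$call_rate >= call_rate_min)
  if (spacing_bp <= 0 || !length(keep)) return(keep)
  out <- integer(0)
  for (ch in unique(dm$sites$chrom[keep])) {
    idx <- keep[dm$sites$chrom[keep] == ch]
    pos <- dm$sites$pos0[idx]
    last <- -Inf
    for (i in seq_along(idx)) {
      if (pos[i] - last >= spacing_bp) { out <- c(out, idx[i]); last <- pos[i] }
    }
  }
  out
}

#' Squared dosage correlation between two sites
#'
#' `r^2` is the squared Pearson correlation of the two dosage vectors over
#' pairwise-complete accessions - the standard genotype-level LD proxy for
#' polyploids, where haplotype phase is unavailable.
#'
#' @param dm a [dosage_matrix()].
#' @param i,j site indices.
#' @param min_n minimum accessions non-missing at both sites.
#' @return `r^2` in `[0, 1]`; NA when either site has zero variance or fewer
#'   than `min_n` shared calls.
#' @export
pairwise_r2 <- function(dm, i, j, min_n = 20L) {
  x <- dm$dosage[i, ]; y <- dm$dosage[j, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n) return(NA_real_)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' All within-chromosome LD pairs up to a maximum distance
#'
#' @param dm a [dosage_matrix()].
#' @param sites site indices (e.g. from [thin_snps()]).
#' @param max_dist maximum pair distance in bp.
#' @param min_n minimum shared non-missing accessions per pair.
#' @return data.frame of class `ld_pairs`: `site_i`, `site_j`, `dist_bp`,
#'   `r2`, `n`.
#' @export
ld_pairs <- function(dm, sites = seq_len(nrow(dm$dosage)), max_dist = 1e7,
                     min_n = 20L) {
  res <- list()
  for (ch in unique(dm$sites$chrom[sites])) {
    idx <- sites[dm$sites$chrom[sites] == ch]
    if (length(idx) < 2) next
    X <- t(dm$dosage[idx, , drop = FALSE])           # accessions x sites
    R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
    N <- crossprod(!is.na(X))
    pos <- dm$sites$pos0[idx]
    pr <- which(upper.tri(R), arr.ind = TRUE)
    dist <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- dist > 0 & dist <= max_dist
    pr <- pr[keep, , drop = FALSE]; dist <- dist[keep]
    r2 <- R[pr]^2
    n <- N[pr]
    r2[n < min_n] <- NA_real_
    res[[ch]] <- data.frame(site_i = idx[pr[, 1]], site_j = idx[pr[, 2]],
                            dist_bp = dist, r2 = r2, n = n)
  }
  out <- if (length(res)) do.call(rbind, res)
  else data.frame(site_i = integer(), site_j = integer(),
                  dist_bp = numeric(), r2 = numeric(), n = integer())
  rownames(out) <- NULL
  out <- out[!is.na(out$r2), , drop = FALSE]
  class(out) <- c("ld_pairs", "data.frame")
  out
}

#' Distance-binned LD decay curve
#'
#' Mean `r^2` per contiguous distance bin; bins holding fewer than
#' `min_pairs` pairs are masked (NA).
#'
#' @param pairs an `ld_pairs` table.
#' @param max_dist curve extent in bp.
#' @param bin_width bin width in bp.
#' @param min_pairs minimum pairs per bin.
#' @return data.frame of class `ld_decay_curve`: `bin_start`, `bin_end`,
#'   `mid`, `mean_r2`, `n_pairs`; binning parameters kept as attributes.
#' @export
ld_decay_curve <- function(pairs, max_dist = 1e7, bin_width = 5e4,
                           min_pairs = 50L) {
  if (nrow(pairs) == 0) stop("no LD pairs supplied")
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  bin <- findInterval(pairs$dist_bp, edges, rightmost.closed = TRUE)
  bin[bin < 1 | bin >= length(edges)] <- NA
  nb <- length(edges) - 1
  sums <- tapply(pairs$r2, factor(bin, levels = seq_len(nb)), sum)
  cnts <- tapply(pairs$r2, factor(bin, levels = seq_len(nb)), length)
  cnts[is.na(cnts)] <- 0
  mean_r2 <- as.numeric(sums) / as.numeric(cnts)
  mean_r2[cnts < min_pairs] <- NA_real_
  out <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                    mid = (edges[-length(edges)] + edges[-1]) / 2,
                    mean_r2 = mean_r2, n_pairs = as.integer(cnts))
  attr(out, "bin_width") <- bin_width
  attr(out, "min_pairs") <- min_pairs
  class(out) <- c("ld_decay_curve", "data.frame")
  out
}

#' Distance at which LD decays to a threshold
#'
#' First downward crossing of `threshold` by linear interpolation between
#' the midpoints of adjacent populated bins. Returns `Inf` when the curve
#' never drops below the threshold (censored at the curve extent); when
#' every populated bin is already below the threshold, the first populated
#' bin midpoint is returned with a warning.
#'
#' @param curve an `ld_decay_curve`.
#' @param threshold r^2 threshold (0.2 is the conventional reporting point).
#' @return distance in bp (possibly `Inf`).
#' @export
decay_distance_at <- function(curve, threshold = 0.2) {
  ok <- which(!is.na(curve$mean_r2))
  if (length(ok) < 2) stop("need at least two populated bins")
  m <- curve$mean_r2[ok]; x <- curve$mid[ok]
  if (m[1] < threshold) {
    warning("curve starts below threshold; returning first populated bin midpoint")
    return(x[1])
  }
  for (i in seq_len(length(ok) - 1)) {
    if (m[i] >= threshold && m[i + 1] < threshold) {
      return(x[i] + (m[i] - threshold) / (m[i] - m[i + 1]) * (x[i + 1] - x[i]))
    }
  }
  Inf
}
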