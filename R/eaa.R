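# Environmental association: PCA compression of the environment table,
# latent-factor-corrected per-SNP regression, multi-run z combination with
# genomic control, Bonferroni selection.

#' PCA of an environmental-variable table
#'
#' Variables are standardised to zero mean and unit variance (missing
#' values imputed by the variable mean, constant variables dropped with a
#' warning), then decomposed with [stats::prcomp()].
#'
#' @param env numeric matrix or data.frame, accessions x variables.
#' @param n_pcs number of components to return.
#' @return list of class `env_pcs`: `scores` (accessions x PCs),
#'   `loadings`, `var_explained` (fraction per returned PC),
#'   `standardization` (per-variable mean/sd), `n_imputed`, `dropped`.
#' @export
env_pca <- function(env, n_pcs = 5L) {
  X <- as.matrix(env)
  if (ncol(X) < 2 || nrow(X) < 3) stop("need >= 2 variables and >= 3 accessions")
  n_imputed <- sum(is.na(X))
  for (j in seq_len(ncol(X))) {
    mj <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mj
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant variable(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                 var_explained = ve[seq_len(n_pcs)],
                 standardization = data.frame(variable = colnames(X),
                                              mean = pc$center, sd = pc$scale),
                 n_imputed = n_imputed, dropped = dropped),
            class = "env_pcs")
}

#' @export
print.env_pcs <- function(x, ...) {
  cat("env_pcs:", nrow(x$scores), "accessions x", ncol(x$scores), "PCs;",
      "cumulative variance", round(100 * sum(x$var_explained), 1), "%\n")
  invisible(x)
}

#' SNP pre-filter for association scans
#'
#' Keeps biallelic sites passing MAF and call-rate floors and returns an
#' accessions x SNPs genotype matrix with residual missing dosages imputed
#' by the site mean.
#'
#' @param dm a [dosage_matrix()].
#' @param maf_min,call_rate_min filter floors (the conventional common-SNP
#'   filter is MAF >= 0.05 and call rate >= 0.95).
#' @return list: `G` (accessions x SNPs), `sites` (kept site rows),
#'   `site_index` (rows of `dm`).
#' @export
eaa_filter <- function(dm, maf_min = 0.05, call_rate_min = 0.95) {
  keep <- which(dm$maf >= maf_min & dm$call_rate >= call_rate_min &
                  !(dm$sites$multiallelic %||% FALSE))
  G <- t(dm$dosage[keep, , drop = FALSE]) * 1.0
  for (j in seq_len(ncol(G))) {
    mj <- mean(G[, j], na.rm = TRUE)
    G[is.na(G[, j]), j] <- mj
  }
  list(G = G, sites = dm$sites[keep, , drop = FALSE], site_index = keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residualise y (vector or matrix columns) on [1, U]
.residualize <- function(y, U) {
  M <- cbind(1, U)
  Q <- qr.Q(qr(M))
  y - Q %*% crossprod(Q, y)
}

#' Latent-factor association between SNPs and an environmental component
#'
#' Closed-form analogue of latent-factor mixed-model association: the
#' hidden population-structure factors are the top `K` left singular vectors
#' of the column-centred, scaled genotype matrix, and each SNP's dosage is
#' regressed on the environmental component plus the `K` factors and an
#' intercept; `z = effect / se` for the environmental term. Run-to-run
#' variation (needed for downstream z combination) comes from re-estimating
#' the factors on a seeded jackknife subset of accessions in each run and
#' projecting all accessions onto them; the regression itself always uses
#' every accession.
#'
#' @param G accessions x SNPs genotype matrix (from [eaa_filter()]).
#' @param env_pc numeric vector, one environmental component score per
#'   accession.
#' @param K number of latent factors (0 = plain regression). Must satisfy
#'   `K <= n - 3`.
#' @param n_runs number of jackknife factor re-estimations.
#' @param jackknife_frac fraction of accessions used to estimate factors in
#'   each run.
#' @param seed integer seed driving the jackknife resampling.
#' @return matrix of z-scores, SNPs x runs.
#' @export
latent_factor_association <- function(G, env_pc, K = 6L, n_runs = 10L,
                                      jackknife_frac = 0.9, seed = 1L) {
  G <- as.matrix(G)
  n <- nrow(G); m <- ncol(G)
  stopifnot(length(env_pc) == n)
  if (K < 0 || K >= n - 2) stop("K must satisfy 0 <= K <= n - 3")
  Gc <- scale(G)
  Gc[, attr(Gc, "scaled:scale") == 0] <- 0
  Z <- matrix(NA_real_, m, n_runs)
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }
  for (r in seq_len(n_runs)) {
    U <- NULL
    if (K > 0) {
      sub <- withr_seed(seed + 7919L * r, {
        sort(sample.int(n, max(K + 2L, floor(jackknife_frac * n))))
      })
      sv <- svd(Gc[sub, , drop = FALSE], nu = 0, nv = K)
      U <- Gc %*% sv$v            # project every accession onto run factors
      U <- qr.Q(qr(U))
    }
    if (is.null(U)) {
      e <- env_pc - mean(env_pc)
      Gres <- sweep(G, 2, colMeans(G))
      df <- n - 2
    } else {
      e <- .residualize(env_pc, U)
      Gres <- .residualize(sweep(G, 2, colMeans(G)), U)
      df <- n - 2 - K
    }
    s_e <- sum(e^2)
    if (s_e < 1e-12 * stats::var(env_pc) * n)
      warning("environmental component nearly collinear with latent factors")
    beta <- as.numeric(crossprod(Gres, e)) / s_e
    rss <- pmax(colSums(Gres^2) - beta^2 * s_e, 0)
    se <- sqrt(rss / df / s_e)
    Z[, r] <- ifelse(se > 0, beta / se, 0)
  }
  Z
}

#' Combine multi-run z-scores and calibrate p-values by genomic control
#'
#' The combined statistic is the per-SNP median across runs; the genomic
#' inflation factor is `lambda = median(z^2) / 0.456` (the chi-square-1
#' median) and calibrated p-values come from comparing `z^2 / lambda`
#' against chi-square with 1 df — the combination-and-recalibration
#' workflow used with multi-run latent-factor association programs.
#'
#' @param Z z matrix, SNPs x runs (a vector is treated as one run).
#' @return list: `z` (combined), `lambda`, `p` (calibrated).
#' @export
combine_zscores_calibrate <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 1) stop("need at least one run")
  z <- apply(Z, 1, stats::median)
  lambda <- stats::median(z^2) / stats::qchisq(0.5, df = 1)
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  p <- stats::pchisq(z^2 / lambda, df = 1, lower.tail = FALSE)
  list(z = z, lambda = lambda, p = p)
}

#' Bonferroni selection of significant SNPs with gene assignment
#'
#' Flags SNPs with `p <= alpha / m` and assigns each flagged SNP to its
#' containing gene (containment only by default; `window` extends gene
#' spans symmetrically).
#'
#' @param p calibrated p-values.
#' @param sites site table aligned with `p` (`chrom`, `pos0`).
#' @param alpha family-wise error target (the conventional reporting level
#'   is 0.01).
#' @param gm optional [gene_model_set()] for gene assignment.
#' @param window bp added to each side of gene spans when assigning.
#' @return list: `hits` (data.frame `chrom`, `pos0`, `p`, `gene_id`),
#'   `threshold`, `n_snps`, `n_genes`.
#' @export
bonferroni_select <- function(p, sites, alpha = 0.01, gm = NULL, window = 0L) {
  m <- length(p)
  if (m == 0) stop("no tests supplied")
  thr <- alpha / m
  sel <- which(p <= thr)
  hits <- data.frame(chrom = sites$chrom[sel], pos0 = sites$pos0[sel],
                     p = p[sel], gene_id = rep(NA_character_, length(sel)))
  if (!is.null(gm) && nrow(hits)) {
    gr_s <- GenomicRanges::GRanges(hits$chrom,
                                   IRanges::IRanges(hits$pos0 + 1L, width = 1L))
    gr_g <- GenomicRanges::GRanges(gm$genes$chrom,
                                   IRanges::IRanges(pmax(1L, gm$genes$start + 1L - window),
                                                    gm$genes$end + window))
    ov <- GenomicRanges::findOverlaps(gr_s, gr_g, select = "first")
    hits$gene_id <- ifelse(is.na(ov), NA_character_, gm$genes$gene_id[ov])
  }
  list(hits = hits, threshold = thr, n_snps = nrow(hits),
       n_genes = length(unique(stats::na.omit(hits$gene_id))))
}
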