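# Allele-dosage genotyping from read depths.
#
# At a biallelic site, an accession of ploidy p carrying d alternate copies
# is expected to show an alternate-read fraction
#     f_d = (d/p) (1 - eps) + (1 - d/p) eps
# where eps is the per-read miscall rate. The caller maximises the binomial
# likelihood Binom(alt; ref + alt, f_d) over d in 0..p and reports the
# natural-log likelihood ratio between the best and second-best class as the
# call confidence.

.dosage_freqs <- function(p, error_rate) {
  d <- 0:p
  (d / p) * (1 - error_rate) + (1 - d / p) * error_rate
}

#' Call integer allele dosage from allele depths
#'
#' Maximum-likelihood dosage under a binomial read-sampling model with a
#' flat prior over dosage classes. Ties are broken toward the smaller dosage
#' and carry confidence 0. Zero total depth yields a missing call.
#'
#' Vectorised over `ref_depth`/`alt_depth` (ploidy and error rate are
#' scalar per call batch).
#'
#' @param ref_depth,alt_depth non-negative integer vectors of reference and
#'   alternate read counts.
#' @param ploidy even integer in 2..12.
#' @param error_rate per-read miscall probability, in `[0, 0.5)`.
#' @return data.frame with columns `dosage` (integer, NA when missing),
#'   `confidence` (log-likelihood ratio best vs second best, >= 0) and
#'   `missing`.
#' @examples
#' call_dosage(80, 0, ploidy = 8)            # dosage 0
#' call_dosage(70, 10, ploidy = 8)           # single dose
#' @export
call_dosage <- function(ref_depth, alt_depth, ploidy, error_rate = 0.005) {
  stopifnot(length(ploidy) == 1, ploidy %% 2 == 0, ploidy >= 2, ploidy <= 12,
            all(ref_depth >= 0, na.rm = TRUE), all(alt_depth >= 0, na.rm = TRUE))
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  ref_depth[is.na(ref_depth)] <- 0L
  alt_depth[is.na(alt_depth)] <- 0L
  n <- ref_depth + alt_depth
  fd <- .dosage_freqs(ploidy, error_rate)
  # log-likelihood per class, with 0*log(0) := 0 for the eps = 0 edge
  ll <- vapply(fd, function(f) {
    la <- ifelse(alt_depth == 0, 0, alt_depth * log(f))
    lr <- ifelse(ref_depth == 0, 0, ref_depth * log1p(-f))
    la + lr
  }, numeric(length(n)))
  ll <- matrix(ll, ncol = ploidy + 1)
  best <- max.col(ll, ties.method = "first")    # smallest dosage on ties
  ll_best <- ll[cbind(seq_along(n), best)]
  ll2 <- ll
  ll2[cbind(seq_along(n), best)] <- -Inf
  second <- do.call(pmax, as.data.frame(ll2))
  conf <- ll_best - second
  conf[!is.finite(conf)] <- Inf
  conf[conf < 0] <- 0
  miss <- n == 0
  data.frame(dosage = ifelse(miss, NA_integer_, best - 1L),
             confidence = ifelse(miss, NA_real_, conf),
             missing = miss)
}

#' Construct a dosage matrix container
#'
#' @param dosage integer matrix (sites x accessions), NA for missing calls.
#' @param confidence matrix of per-call log-likelihood ratios.
#' @param ploidy named integer vector, one even ploidy per accession.
#' @param sites data.frame of site records (`chrom`, `pos0`, `ref`, `alt`).
#' @return Object of class `dosage_matrix` with per-site `call_rate` and
#'   pooled minor-allele frequency `maf`.
#' @export
dosage_matrix <- function(dosage, confidence, ploidy, sites) {
  stopifnot(ncol(dosage) == length(ploidy), nrow(dosage) == nrow(sites))
  if (any(dosage > rep(ploidy, each = nrow(dosage)), na.rm = TRUE))
    stop("dosage exceeds ploidy")
  colnames(dosage) <- names(ploidy)
  obj <- structure(list(dosage = dosage, confidence = confidence,
                        ploidy = ploidy, sites = sites,
                        samples = names(ploidy)),
                   class = "dosage_matrix")
  obj$call_rate <- rowMeans(!is.na(dosage))
  obj$maf <- .pooled_maf(obj)
  obj
}

.pooled_maf <- function(dm) {
  pl <- matrix(rep(dm$ploidy, each = nrow(dm$dosage)), nrow = nrow(dm$dosage))
  pl[is.na(dm$dosage)] <- NA
  p_hat <- rowSums(dm$dosage, na.rm = TRUE) / rowSums(pl, na.rm = TRUE)
  pmin(p_hat, 1 - p_hat)
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosage), "sites x", length(x$samples),
      "accessions; mean call rate", round(mean(x$call_rate), 3), "\n")
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosage)

#' Subset a dosage matrix by site and/or accession
#' @param dm a [dosage_matrix()].
#' @param sites integer or logical index over sites.
#' @param samples index or character vector over accessions.
#' @return a [dosage_matrix()].
#' @export
subset_dosage <- function(dm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(dm$dosage))
  if (is.null(samples)) samples <- seq_along(dm$samples)
  if (is.character(samples)) samples <- match(samples, dm$samples)
  dosage_matrix(dm$dosage[sites, samples, drop = FALSE],
                dm$confidence[sites, samples, drop = FALSE],
                dm$ploidy[samples], dm$sites[sites, , drop = FALSE])
}

#' Genotype a variant table
#'
#' Runs [call_dosage()] for every accession given its ploidy. Genotypes with
#' `DP` below `min_dp` are set missing before calling.
#'
#' @param vt a [variant_table()].
#' @param meta sample metadata (see [read_sample_metadata()]); must cover all
#'   samples of `vt`.
#' @param error_rate per-read miscall probability.
#' @param min_dp genotypes with total depth below this are missing.
#' @return a [dosage_matrix()].
#' @export
genotype_variants <- function(vt, meta, error_rate = 0.005, min_dp = 5L) {
  stopifnot(inherits(vt, "variant_table"))
  idx <- match(vt$samples, meta$id)
  if (anyNA(idx)) stop("metadata missing for: ",
                       paste(vt$samples[is.na(idx)], collapse = ", "))
  ploidy <- stats::setNames(as.integer(meta$ploidy[idx]), vt$samples)
  ns <- nrow(vt$sites)
  D <- matrix(NA_integer_, ns, length(vt$samples))
  C <- matrix(NA_real_, ns, length(vt$samples))
  for (j in seq_along(vt$samples)) {
    r <- vt$ad_ref[, j]; a <- vt$ad_alt[, j]
    low <- (r + a) < min_dp
    r[low] <- 0L; a[low] <- 0L
    cl <- call_dosage(r, a, ploidy[j], error_rate)
    D[, j] <- cl$dosage
    C[, j] <- cl$confidence
  }
  dosage_matrix(D, C, ploidy, vt$sites)
}

#' Two-level site/genotype filtering
#'
#' Level 1 keeps biallelic sites with mean depth and call rate above
#' thresholds (depth information is taken from `vt` when supplied). Level 2
#' additionally masks genotypes whose call confidence (log-likelihood ratio)
#' falls below `min_llr` and then drops sites whose call rate falls below
#' `site_call_rate`. An audit table reports the count removed by each rule.
#'
#' @param dm a [dosage_matrix()] from [genotype_variants()].
#' @param vt the originating [variant_table()] (optional; enables the mean
#'   depth rule).
#' @param min_mean_dp level-1 minimum site mean depth.
#' @param min_call_rate_l1 level-1 minimum site call rate.
#' @param min_llr level-2 minimum genotype confidence.
#' @param site_call_rate level-2 minimum site call rate after masking.
#' @param biallelic_only drop sites flagged multiallelic.
#' @return list with `level1` and `level2` [dosage_matrix()] views and an
#'   `audit` data.frame (`rule`, `removed`).
#' @export
apply_filters <- function(dm, vt = NULL, min_mean_dp = 10, min_call_rate_l1 = 0.5,
                          min_llr = 2, site_call_rate = 0.8,
                          biallelic_only = TRUE) {
  stopifnot(inherits(dm, "dosage_matrix"))
  ns <- nrow(dm$dosage)
  keep <- rep(TRUE, ns)
  audit <- data.frame(rule = character(), removed = integer())
  note <- function(rule, removed)
    rbind(audit, data.frame(rule = rule, removed = as.integer(removed)))
  if (biallelic_only && !is.null(dm$sites$multiallelic)) {
    drop <- keep & dm$sites$multiallelic
    audit <- note("multiallelic", sum(drop)); keep <- keep & !drop
  }
  if (!is.null(vt)) {
    drop <- keep & rowMeans(vt$dp) < min_mean_dp
    audit <- note("site-mean-depth", sum(drop)); keep <- keep & !drop
  }
  drop <- keep & dm$call_rate < min_call_rate_l1
  audit <- note("call-rate", sum(drop)); keep <- keep & !drop
  level1 <- subset_dosage(dm, sites = which(keep))
  if (nrow(level1$dosage) == 0) warning("level-1 filter removed every site")
  # level 2: confidence mask, then site call rate
  D <- level1$dosage
  mask <- !is.na(level1$confidence) & level1$confidence < min_llr
  D[mask] <- NA_integer_
  audit <- note("genotype-llr", sum(mask))
  cr <- rowMeans(!is.na(D))
  keep2 <- cr >= site_call_rate
  audit <- note("call-rate-post-mask", sum(!keep2))
  level2 <- dosage_matrix(D[keep2, , drop = FALSE],
                          level1$confidence[keep2, , drop = FALSE],
                          level1$ploidy, level1$sites[keep2, , drop = FALSE])
  if (nrow(level2$dosage) == 0) warning("level-2 filter removed every site")
  list(level1 = level1, level2 = level2, audit = audit)
}

#' Single-dose SNP fraction per accession
#'
#' Fraction of an accession's variant calls (dosage >= 1) that are
#' single-dose (dosage exactly 1); missing calls are excluded. In real
#' polyploid panels this fraction falls as ploidy rises.
#'
#' @param dm a [dosage_matrix()].
#' @param samples accessions to report (default all).
#' @return named numeric vector; NA where an accession has no variant calls.
#' @export
sd_fraction <- function(dm, samples = dm$samples) {
  if (is.character(samples)) samples <- match(samples, dm$samples)
  vapply(samples, function(j) {
    d <- dm$dosage[, j]
    nv <- sum(d >= 1, na.rm = TRUE)
    if (nv == 0) return(NA_real_)
    sum(d == 1, na.rm = TRUE) / nv
  }, numeric(1)) |> stats::setNames(dm$samples[samples])
}

#' Minimum depth to separate single-dose calls from homozygous reference
#'
#' Smallest read depth n at which the exact binomial likelihood-ratio
#' classifier between dosage 0 and dosage 1 has both misclassification
#' probabilities at most `alpha`, computed by exact enumeration over
#' alternate-read counts 0..n. Exposes the error model behind depth
#' requirements quoted for high-ploidy genotyping (the higher the ploidy,
#' the closer f_1 sits to f_0 and the deeper one must sequence).
#'
#' @param ploidy even integer 2..12.
#' @param error_rate per-read miscall probability.
#' @param alpha maximum tolerated misclassification probability, in (0, 0.5).
#' @param n_max search bound.
#' @return integer depth.
#' @export
min_depth_for_separation <- function(ploidy, error_rate = 0, alpha = 0.01,
                                     n_max = 10000L) {
  stopifnot(alpha > 0, alpha < 0.5)
  f0 <- error_rate
  f1 <- (1 / ploidy) * (1 - error_rate) + (1 - 1 / ploidy) * error_rate
  for (n in seq_len(n_max)) {
    k <- 0:n
    ll0 <- stats::dbinom(k, n, f0, log = TRUE)
    ll1 <- stats::dbinom(k, n, f1, log = TRUE)
    as1 <- ll1 > ll0                      # ties go to dosage 0
    err0 <- sum(stats::dbinom(k[as1], n, f0))
    err1 <- sum(stats::dbinom(k[!as1], n, f1))
    if (err0 <= alpha && err1 <= alpha) return(n)
  }
  stop("no depth <= ", n_max, " achieves alpha = ", alpha)
}

#' Write a dosage matrix as TSV
#'
#' Sites x accessions, `.` for missing, preceded by site columns.
#'
#' @param dm a [dosage_matrix()].
#' @param path output path.
#' @param provenance optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(dm, path, provenance = NULL) {
  D <- dm$dosage
  Dc <- matrix(as.character(D), nrow(D))
  Dc[is.na(Dc)] <- "."
  colnames(Dc) <- dm$samples
  out <- cbind(dm$sites[, c("chrom", "pos0", "ref", "alt")], as.data.frame(Dc))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste0("# ploidy: ",
                    paste(dm$samples, dm$ploidy, sep = "=", collapse = ",")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix written by [write_dosage_tsv()]
#' @param path input path.
#' @return a [dosage_matrix()] (confidence unavailable, set Inf).
#' @export
read_dosage_tsv <- function(path) {
  hdr <- readLines(path, n = 20)
  pl_line <- grep("^# ploidy:", hdr, value = TRUE)
  if (!length(pl_line)) stop("missing '# ploidy:' header")
  kv <- strsplit(strsplit(sub("^# ploidy: *", "", pl_line[1]), ",")[[1]], "=")
  ploidy <- stats::setNames(as.integer(vapply(kv, `[`, "", 2)),
                            vapply(kv, `[`, "", 1))
  x <- read_tsv(path)
  sites <- x[, c("chrom", "pos0", "ref", "alt")]
  D <- as.matrix(x[, -(1:4), drop = FALSE])
  D[D == "."] <- NA
  D <- matrix(as.integer(D), nrow(x), dimnames = list(NULL, colnames(D)))
  dosage_matrix(D, matrix(Inf, nrow(D), ncol(D)), ploidy[colnames(D)], sites)
}
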