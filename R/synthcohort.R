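# Synthetic polyploid cohort generator with known truth.
#
# Emulates the statistical structure of a deeply target-sequenced
# sugarcane-like germplasm panel: two progenitor species diverged under a
# Balding-Nichols model, mosaic inter-specific hybrids, even ploidies 4-12,
# negative-binomial capture depth around ~98x, genes with planted
# low-diversity (sweep) candidates, environmental clines tied to geography.
# Truth (dosages, hybrid composition, sweep genes, env-associated SNPs) is
# injected, not evolved, and returned alongside the data.

.NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                            c("TAA", "TAG", "TGA"))

#' Simulation configuration
#'
#' Defaults mirror the study panel this simulator emulates: representative
#' sub-populations of 40 wild (speciesA), 28 domesticated (speciesB) and 40
#' hybrid accessions; ploidy 8 for both progenitor species with hybrids at
#' 10-12; ~98x mean capture depth; hybrids drawing 55-80% of their genome
#' from the domesticated parent; pairwise species Fst 0.084.
#'
#' @param n_chromosomes,chrom_length_bp genome layout.
#' @param n_sites total SNP sites.
#' @param site_spacing_model `"clustered-in-genes"` places ~89% of sites
#'   inside gene spans (target capture enriches genic space); `"uniform"`
#'   spreads sites evenly.
#' @param n_accessions named counts for `speciesA`, `speciesB`, `hybrid`,
#'   `outgroup`.
#' @param ploidy named even ploidies per group; the hybrid entry may be a
#'   vector, recycled over hybrid accessions.
#' @param divergence_fst target pairwise Nei Fst between the two species, in
#'   (0, 1). Internally each species is drawn by the Balding-Nichols
#'   construction with parameter `2F/(1+F)` so that the expected pairwise
#'   Nei Fst equals `F`.
#' @param outgroup_fst target Nei Fst between each species and the outgroup.
#' @param ancestral_freq_params Beta shape pair for ancestral frequencies.
#' @param hybrid_composition range (or single value) of the genome fraction
#'   each hybrid draws from speciesB.
#' @param ancestry_block_length_bp mean ancestry-block length of the hybrid
#'   mosaic.
#' @param n_genes,gene_length_bp gene models (UTR5 300, CDS 600, intron 600,
#'   CDS 900, UTR3 600 within each 3000 bp gene by default).
#' @param n_fixed_diff sites forced to a fixed allelic difference between
#'   the species (planted diagnostic markers; 0 = none).
#' @param hybrid_parent_pairs optional data.frame (`parentA`, `parentB`,
#'   1-based indices into the speciesA and speciesB accessions, recycled
#'   over hybrids). When given, hybrids are bred from those designated
#'   parents by gamete subsampling (half the hybrid's chromosome copies
#'   drawn without replacement from each parent's copies) instead of the
#'   frequency-mosaic model, and the pairing is recorded as truth.
#' @param sweep_genes data.frame (`gene_id`, `reduction`) of genes whose
#'   speciesB minor-allele frequencies are shrunk by `reduction`
#'   (diversity-reduction factor), or NULL.
#' @param env_assoc_snps data.frame (`site`, `effect`) of sites whose
#'   allele frequency shifts along the latitudinal gradient by `effect`
#'   across the gradient's range, or NULL.
#' @param n_env_vars,n_env_factors,env_noise_sd environmental table: number
#'   of variables, latent factors generating them (the first two factors are
#'   the standardised latitude and longitude), and residual noise sd.
#' @param mean_depth,depth_dispersion negative-binomial read depth (mean and
#'   size parameter; smaller size = more overdispersion, `Inf` = every
#'   genotype at exactly `mean_depth`).
#' @param error_rate per-read miscall probability.
#' @param seed integer; identical seeds give bit-identical cohorts.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length_bp = 5e7,
                       n_sites = 2000L,
                       site_spacing_model = c("clustered-in-genes", "uniform"),
                       n_accessions = c(speciesA = 40L, speciesB = 28L,
                                        hybrid = 40L, outgroup = 0L),
                       ploidy = list(speciesA = 8L, speciesB = 8L,
                                     hybrid = c(10L, 12L), outgroup = 8L),
                       divergence_fst = 0.084, outgroup_fst = 0.3,
                       ancestral_freq_params = c(0.8, 0.8),
                       hybrid_composition = c(0.55, 0.80),
                       ancestry_block_length_bp = 2e6,
                       n_genes = 200L, gene_length_bp = 3000L,
                       n_fixed_diff = 0L, hybrid_parent_pairs = NULL,
                       sweep_genes = NULL,
                       env_assoc_snps = NULL,
                       n_env_vars = 104L, n_env_factors = 5L,
                       env_noise_sd = 0.3,
                       mean_depth = 98, depth_dispersion = 8,
                       error_rate = 0.005, seed = 1L) {
  site_spacing_model <- match.arg(site_spacing_model)
  cfg <- as.list(environment())
  # tolerate YAML round trips: named lists back to named integer vectors
  cfg$n_accessions <- vapply(unlist(n_accessions), as.integer, 1L)
  if (is.null(names(cfg$n_accessions)) ||
      !all(c("speciesA", "speciesB", "hybrid") %in% names(cfg$n_accessions)))
    stop("n_accessions must be named with speciesA/speciesB/hybrid (+ outgroup)")
  cfg$ploidy <- lapply(ploidy, as.integer)
  if (!is.null(sweep_genes) && !is.data.frame(sweep_genes))
    cfg$sweep_genes <- sweep_genes <- as.data.frame(sweep_genes)
  if (!is.null(env_assoc_snps) && !is.data.frame(env_assoc_snps))
    cfg$env_assoc_snps <- env_assoc_snps <- as.data.frame(env_assoc_snps)
  for (g in names(cfg$ploidy)) {
    p <- cfg$ploidy[[g]]
    if (any(p %% 2 != 0 | p < 2 | p > 12))
      stop("ploidy for ", g, " must be even and within 2-12")
  }
  if (divergence_fst <= 0 || divergence_fst >= 1)
    stop("divergence_fst must lie in (0, 1)")
  if (outgroup_fst <= 0 || outgroup_fst >= 1)
    stop("outgroup_fst must lie in (0, 1)")
  if (any(hybrid_composition < 0 | hybrid_composition > 1))
    stop("hybrid_composition fractions must lie in [0, 1]")
  if (ancestry_block_length_bp <= 0)
    stop("ancestry_block_length_bp must be positive")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must lie in [0, 0.5)")
  if (!is.null(sweep_genes))
    stopifnot(all(c("gene_id", "reduction") %in% names(sweep_genes)),
              all(sweep_genes$reduction >= 0 & sweep_genes$reduction <= 1))
  if (!is.null(env_assoc_snps))
    stopifnot(all(c("site", "effect") %in% names(env_assoc_snps)),
              all(env_assoc_snps$site >= 1 & env_assoc_snps$site <= n_sites))
  structure(cfg, class = "sim_config")
}

# deterministic gene layout: genes evenly spread over chromosomes,
# alternating strand; structure UTR5/CDS/intron/CDS/UTR3 scaled to length
.sim_genes <- function(cfg) {
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  per_chr <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  genes <- features <- list()
  gi <- 0
  L <- cfg$gene_length_bp
  # feature template scaled from the canonical 3000 bp layout
  seg <- round(L * c(0.1, 0.2, 0.2, 0.3, 0.2))
  seg[5] <- L - sum(seg[1:4])
  cds_len <- seg[2] + seg[4]
  trim <- cds_len %% 3          # keep total CDS length divisible by 3
  seg[4] <- seg[4] - trim
  types <- c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR")
  for (c1 in seq_len(cfg$n_chromosomes)) {
    ng <- per_chr[c1]
    if (ng == 0) next
    starts <- round(seq(from = cfg$chrom_length_bp * 0.02,
                        to = cfg$chrom_length_bp * 0.98 - L,
                        length.out = ng))
    for (k in seq_len(ng)) {
      gi <- gi + 1
      id <- sprintf("gene%04d", gi)
      strand <- if (gi %% 2 == 1) "+" else "-"
      s0 <- starts[k]
      bounds <- s0 + cumsum(c(0, seg))
      fe <- data.frame(gene_id = id, type = types,
                       start = bounds[1:5], end = bounds[2:6],
                       phase = NA_integer_)
      cds <- which(fe$type == "CDS")
      if (strand == "+") {
        fe$phase[cds[1]] <- 0L
        fe$phase[cds[2]] <- (3 - (fe$end[cds[1]] - fe$start[cds[1]]) %% 3) %% 3
      } else {
        fe$phase[cds[2]] <- 0L
        fe$phase[cds[1]] <- (3 - (fe$end[cds[2]] - fe$start[cds[2]]) %% 3) %% 3
      }
      genes[[gi]] <- data.frame(gene_id = id, chrom = chroms[c1],
                                start = s0, end = s0 + sum(seg),
                                strand = strand, complete = TRUE)
      features[[gi]] <- fe
    }
  }
  gene_model_set(do.call(rbind, genes), do.call(rbind, features))
}

# random CDS without internal stops, per gene
.sim_cds <- function(gm) {
  ids <- gm$genes$gene_id
  out <- vapply(ids, function(id) {
    cds <- gm$features[gm$features$gene_id == id & gm$features$type == "CDS", ]
    ncod <- sum(cds$end - cds$start) / 3
    paste(sample(.NON_STOP_CODONS, ncod, replace = TRUE), collapse = "")
  }, "")
  stats::setNames(out, ids)
}

# site positions; ~89% genic under clustered-in-genes
.sim_sites <- function(cfg, gm) {
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  per_chr <- diff(round(seq(0, cfg$n_sites, length.out = cfg$n_chromosomes + 1)))
  pos <- lapply(seq_len(cfg$n_chromosomes), function(c1) {
    n <- per_chr[c1]
    if (cfg$site_spacing_model == "uniform") {
      p <- sort(sample.int(cfg$chrom_length_bp, n))
    } else {
      n_genic <- round(0.89 * n)
      gsel <- gm$genes[gm$genes$chrom == chroms[c1], , drop = FALSE]
      gidx <- sample.int(nrow(gsel), n_genic, replace = TRUE)
      off <- floor(stats::runif(n_genic) * (gsel$end[gidx] - gsel$start[gidx]))
      p_genic <- gsel$start[gidx] + off
      p_inter <- sample.int(cfg$chrom_length_bp, n - n_genic)
      p <- sort(c(p_genic, p_inter))
    }
    while (anyDuplicated(p)) p <- sort(p + cumsum(duplicated(p)))
    data.frame(chrom = chroms[c1], pos0 = as.integer(p))
  })
  sites <- do.call(rbind, pos)
  rownames(sites) <- NULL
  sites
}

# attach ref/alt alleles consistent with CDS sequences (strand-aware)
.sim_alleles <- function(sites, gm, cds_seqs) {
  n <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    cds <- gm$features[gm$features$gene_id == g$gene_id &
                         gm$features$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    sel <- which(sites$chrom == g$chrom &
                   sites$pos0 >= g$start & sites$pos0 < g$end)
    for (s in sel) {
      pos <- sites$pos0[s]
      ci <- which(cds$start <= pos & pos < cds$end)
      if (!length(ci)) next
      offset <- if (g$strand == "+") {
        sum(cds$end[seq_len(ci - 1)] - cds$start[seq_len(ci - 1)]) + (pos - cds$start[ci])
      } else {
        after <- which(seq_len(nrow(cds)) > ci)
        sum(cds$end[after] - cds$start[after]) + (cds$end[ci] - 1L - pos)
      }
      b <- substr(cds_seqs[[g$gene_id]], offset + 1, offset + 1)
      ref[s] <- if (g$strand == "+") b else .comp[[b]]
    }
  }
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  sites$ref <- ref
  sites$alt <- unname(alt)
  sites
}

#' Draw progenitor species frequencies and dosages
#'
#' Ancestral allele frequencies come from the configured Beta; each species'
#' per-site frequency is drawn by the Balding-Nichols construction
#' (calibrated so the expected pairwise Nei Fst equals
#' `config$divergence_fst`); each progenitor accession's dosage is
#' `Binomial(ploidy, species frequency)`. Sites inside planted sweep genes
#' have the domesticated species' minor-allele frequency multiplied by the
#' gene's diversity-reduction factor (pinning it near fixation); planted
#' fixed differences are set to frequency 1 in one species and 0 in the
#' other, alternating direction.
#'
#' Uses the current RNG state; [simulate_cohort()] seeds it from the config.
#'
#' @param cfg a [sim_config()].
#' @param sites site table with `gene_id` column (from the internal layout).
#' @param gm gene models (for sweep-gene site lookup).
#' @return list: `freq` (sites x `c(ancestral, speciesA, speciesB,
#'   outgroup)`), `fixed_diff_sites`, `sweep_sites`.
#' @keywords internal
.sim_species_freqs <- function(cfg, sites, gm) {
  n <- nrow(sites)
  a <- cfg$ancestral_freq_params
  p0 <- stats::rbeta(n, a[1], a[2])
  bn <- function(p, F) {
    th <- 2 * F / (1 + F)
    stats::rbeta(length(p), p * (1 - th) / th, (1 - p) * (1 - th) / th)
  }
  fA <- bn(p0, cfg$divergence_fst)
  fB <- bn(p0, cfg$divergence_fst)
  fO <- bn(p0, cfg$outgroup_fst)
  sweep_sites <- integer(0)
  if (!is.null(cfg$sweep_genes)) {
    for (k in seq_len(nrow(cfg$sweep_genes))) {
      g <- gm$genes[gm$genes$gene_id == cfg$sweep_genes$gene_id[k], ]
      if (!nrow(g)) stop("sweep gene not in gene models: ",
                         cfg$sweep_genes$gene_id[k])
      sel <- which(sites$chrom == g$chrom & sites$pos0 >= g$start &
                     sites$pos0 < g$end)
      r <- cfg$sweep_genes$reduction[k]
      fB[sel] <- ifelse(fB[sel] <= 0.5, fB[sel] * r, 1 - (1 - fB[sel]) * r)
      sweep_sites <- c(sweep_sites, sel)
    }
  }
  fixed <- integer(0)
  if (cfg$n_fixed_diff > 0) {
    fixed <- round(seq(1, n, length.out = cfg$n_fixed_diff))
    toA <- seq_along(fixed) %% 2 == 1
    fA[fixed[toA]] <- 1; fB[fixed[toA]] <- 0
    fA[fixed[!toA]] <- 0; fB[fixed[!toA]] <- 1
    fO[fixed] <- 0
  }
  list(freq = cbind(ancestral = p0, speciesA = fA, speciesB = fB,
                    outgroup = fO),
       fixed_diff_sites = fixed, sweep_sites = unique(sweep_sites))
}

# dosages for one group: Binomial(ploidy, per-site freq), sites x n matrix
.draw_dosages <- function(freq, ploidies) {
  n <- length(ploidies)
  m <- length(freq)
  matrix(stats::rbinom(n * m, rep(ploidies, each = m), rep(freq, n)), m, n)
}

#' Simulate mosaic hybrid dosages
#'
#' Each hybrid is a two-state mosaic along every chromosome: ancestry
#' alternates between speciesA and speciesB segments with exponentially
#' distributed lengths whose state-specific means are `2 L c` (speciesB)
#' and `2 L (1-c)` (speciesA), so the expected speciesB genome fraction is
#' the hybrid's target composition `c` and the mean block length is `L`.
#' The block state applies to all homologous copies at a site (segment-level
#' inheritance); within a block, dosage is `Binomial(ploidy, that species'
#' frequency)`. The realised fraction of speciesB-ancestry sites is recorded
#' as truth.
#'
#' @param cfg a [sim_config()].
#' @param sites site table.
#' @param freq species frequency matrix from the progenitor step.
#' @param ploidies integer vector, one per hybrid.
#' @param compositions target speciesB fractions, one per hybrid.
#' @return list: `dosage` (sites x hybrids), `ancestryB` (logical matrix),
#'   `true_composition` (data.frame `fracA`, `fracB`).
#' @keywords internal
.sim_hybrids <- function(cfg, sites, freq, ploidies, compositions) {
  L <- cfg$ancestry_block_length_bp
  nh <- length(ploidies)
  ns <- nrow(sites)
  D <- matrix(0L, ns, nh)
  AB <- matrix(FALSE, ns, nh)
  chroms <- unique(sites$chrom)
  for (h in seq_len(nh)) {
    cB <- compositions[h]
    mB <- max(2 * L * cB, 1); mA <- max(2 * L * (1 - cB), 1)
    stateB <- logical(ns)
    for (ch in chroms) {
      sel <- which(sites$chrom == ch)
      len <- cfg$chrom_length_bp
      brk <- numeric(0); st <- logical(0)
      cur <- stats::runif(1) < cB
      at <- 0
      while (at < len) {
        step <- stats::rexp(1, rate = 1 / (if (cur) mB else mA))
        at <- at + step
        brk <- c(brk, at); st <- c(st, cur)
        cur <- !cur
      }
      stateB[sel] <- st[findInterval(sites$pos0[sel], c(0, brk),
                                     rightmost.closed = FALSE)]
    }
    fh <- ifelse(stateB, freq[, "speciesB"], freq[, "speciesA"])
    D[, h] <- stats::rbinom(ns, ploidies[h], fh)
    AB[, h] <- stateB
  }
  fracB <- colMeans(AB)
  list(dosage = D, ancestryB = AB,
       true_composition = data.frame(fracA = 1 - fracB, fracB = fracB))
}

#' Simulate read depths from true dosages
#'
#' Total depth per genotype is negative-binomial (mean `mean_depth`, size
#' `depth_dispersion`); alternate reads are `Binomial(depth, f)` with
#' `f = (d/p)(1-eps) + (1-d/p) eps`. Zero depth yields a missing-genotype
#' record.
#'
#' @param true_dosages sites x accessions integer matrix.
#' @param ploidies integer vector per accession.
#' @param sites site table (`chrom`, `pos0`, `ref`, `alt`).
#' @param cfg a [sim_config()] (depth and error parameters).
#' @param samples accession ids.
#' @return a [variant_table()].
#' @export
simulate_reads <- function(true_dosages, ploidies, sites, cfg, samples) {
  ns <- nrow(true_dosages); na <- ncol(true_dosages)
  if (any(true_dosages > rep(ploidies, each = ns)))
    stop("dosage exceeds ploidy")
  dp <- if (is.finite(cfg$depth_dispersion))
    matrix(stats::rnbinom(ns * na, size = cfg$depth_dispersion,
                          mu = cfg$mean_depth), ns, na)
  else matrix(round(cfg$mean_depth), ns, na)   # Inf dispersion = fixed depth
  fr <- true_dosages / rep(ploidies, each = ns)
  f <- fr * (1 - cfg$error_rate) + (1 - fr) * cfg$error_rate
  alt <- matrix(stats::rbinom(ns * na, as.vector(dp), as.vector(f)), ns, na)
  variant_table(sites, dp - alt, alt, dp, samples)
}

#' Simulate the environmental table and planted clines
#'
#' Accession origins carry a latitudinal gradient that differs between
#' groups (structure-confounded, as in real germplasm panels). The
#' environmental variables are generated from `n_env_factors` latent
#' factors — the first two being standardised latitude and longitude — with
#' random loadings plus Gaussian noise. For each planted env-SNP the
#' accession-specific allele frequency is shifted along the gradient by its
#' effect size (total shift across the gradient range), from a baseline of
#' 0.5, and dosages are redrawn; shifts pushing frequencies outside
#' `[0.005, 0.995]` are clamped and counted.
#'
#' @param cfg a [sim_config()].
#' @param meta metadata with `lon`, `lat` filled in.
#' @return list: `env` (accessions x variables matrix), `gradient`
#'   (standardised latitude), `n_clamped`.
#' @keywords internal
.sim_environment <- function(cfg, meta) {
  n <- nrow(meta)
  K <- max(2L, cfg$n_env_factors)
  Fmat <- matrix(stats::rnorm(n * K), n, K)
  Fmat[, 1] <- as.numeric(scale(meta$lat))
  Fmat[, 2] <- as.numeric(scale(meta$lon))
  # decreasing factor weights: climate tables are dominated by a few broad
  # gradients (geography first), not K equal-variance axes
  w <- seq(2, 0.5, length.out = K)
  Fmat <- sweep(Fmat, 2, w, `*`)
  Lo <- matrix(stats::rnorm(cfg$n_env_vars * K), K, cfg$n_env_vars)
  env <- Fmat %*% Lo + cfg$env_noise_sd * matrix(stats::rnorm(n * cfg$n_env_vars),
                                                 n, cfg$n_env_vars)
  colnames(env) <- sprintf("env%03d", seq_len(cfg$n_env_vars))
  rownames(env) <- meta$id
  list(env = env, gradient = Fmat[, 1])
}

#' Simulate a full synthetic cohort
#'
#' Orchestrates genome layout, progenitor divergence, hybrid mosaics,
#' read simulation and the environmental table, and packages ground truth.
#' Bit-identical for identical configs (the config seed drives all
#' randomness).
#'
#' @param cfg a [sim_config()].
#' @return list of class `syn_cohort`: `config`, `meta`, `genes`
#'   ([gene_model_set()]), `cds` (named CDS sequences), `variants`
#'   ([variant_table()]), `truth` (list: `dosages`, `ploidy`,
#'   `composition`, `sweep_genes`, `sweep_sites`, `fixed_diff_sites`,
#'   `env_snps`, `species_freq`, `gradient`), `env`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gm <- .sim_genes(cfg)
  cds <- .sim_cds(gm)
  sites <- .sim_sites(cfg, gm)
  sites <- .sim_alleles(sites, gm, cds)
  sites$multiallelic <- FALSE
  sf <- .sim_species_freqs(cfg, sites, gm)
  na <- cfg$n_accessions
  groups <- rep(c("speciesA", "speciesB", "hybrid", "outgroup"),
                c(na["speciesA"], na["speciesB"], na["hybrid"],
                  if (is.na(na["outgroup"])) 0L else na["outgroup"]))
  ids <- sprintf("acc%03d", seq_along(groups))
  pl <- integer(length(groups))
  for (g in unique(groups))
    pl[groups == g] <- rep_len(cfg$ploidy[[g]], sum(groups == g))
  # group-shifted origins (structure-confounded gradient) with wide
  # within-group dispersion: germplasm collections span both hemispheres
  lat_mean <- c(speciesA = -5, speciesB = 12, hybrid = 5, outgroup = -15)
  lat <- stats::rnorm(length(groups), lat_mean[groups], 12)
  lon <- stats::rnorm(length(groups), 100, 15)
  meta <- data.frame(id = ids, group = groups, ploidy = pl,
                     lon = round(lon, 4), lat = round(lat, 4))
  D <- matrix(0L, nrow(sites), length(ids))
  for (g in c("speciesA", "speciesB", "outgroup")) {
    sel <- which(groups == g)
    if (!length(sel)) next
    D[, sel] <- .draw_dosages(sf$freq[, g], pl[sel])
  }
  hyb <- which(groups == "hybrid")
  comp_tab <- NULL
  parent_tab <- NULL
  if (length(hyb) && !is.null(cfg$hybrid_parent_pairs)) {
    pp <- cfg$hybrid_parent_pairs
    iA <- which(groups == "speciesA"); iB <- which(groups == "speciesB")
    pa <- iA[rep_len(pp$parentA, length(hyb))]
    pb <- iB[rep_len(pp$parentB, length(hyb))]
    ns <- nrow(sites)
    for (k in seq_along(hyb)) {
      h <- hyb[k]
      half <- pl[h] %/% 2L
      gA <- stats::rhyper(ns, D[, pa[k]], pl[pa[k]] - D[, pa[k]], half)
      gB <- stats::rhyper(ns, D[, pb[k]], pl[pb[k]] - D[, pb[k]], pl[h] - half)
      D[, h] <- gA + gB
    }
    parent_tab <- data.frame(id = ids[hyb], parentA = ids[pa], parentB = ids[pb])
  } else if (length(hyb)) {
    hc <- cfg$hybrid_composition
    compositions <- if (length(hc) == 2) stats::runif(length(hyb), hc[1], hc[2])
    else rep_len(hc, length(hyb))
    hres <- .sim_hybrids(cfg, sites, sf$freq, pl[hyb], compositions)
    D[, hyb] <- hres$dosage
    comp_tab <- cbind(data.frame(id = ids[hyb]), hres$true_composition,
                      target_fracB = compositions)
  }
  envres <- .sim_environment(cfg, meta)
  env_truth <- NULL
  n_clamped <- 0L
  if (!is.null(cfg$env_assoc_snps) && nrow(cfg$env_assoc_snps)) {
    # gradient position as ECDF rank in [0, 1]: the planted shift spans the
    # panel's gradient range robustly (not hostage to two outlier origins)
    u <- (rank(envres$gradient) - 1) / (length(envres$gradient) - 1)
    for (k in seq_len(nrow(cfg$env_assoc_snps))) {
      s <- cfg$env_assoc_snps$site[k]
      b <- cfg$env_assoc_snps$effect[k]
      fi <- 0.5 + b * (u - 0.5)
      cl <- fi < 0.005 | fi > 0.995
      n_clamped <- n_clamped + sum(cl)
      fi <- pmin(pmax(fi, 0.005), 0.995)
      D[s, ] <- stats::rbinom(length(fi), pl, fi)
    }
    if (n_clamped > 0)
      message(n_clamped, " env-SNP frequencies clamped to [0.005, 0.995]")
    env_truth <- cfg$env_assoc_snps
  }
  vt <- simulate_reads(D, pl, sites, cfg, ids)
  structure(list(config = cfg, meta = meta, genes = gm, cds = cds,
                 variants = vt,
                 truth = list(dosages = D, ploidy = stats::setNames(pl, ids),
                              composition = comp_tab,
                              hybrid_parents = parent_tab,
                              sweep_genes = cfg$sweep_genes,
                              sweep_sites = sf$sweep_sites,
                              fixed_diff_sites = sf$fixed_diff_sites,
                              env_snps = env_truth,
                              species_freq = sf$freq,
                              gradient = envres$gradient,
                              n_env_clamped = n_clamped),
                 env = envres$env),
            class = "syn_cohort")
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat("syn_cohort:", nrow(x$variants$sites), "sites x", nrow(x$meta),
      "accessions (", paste(table(x$meta$group), collapse = "/"), ");",
      "seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits VCF (AD/DP), metadata TSV, gene models GFF3, CDS FASTA,
#' environment TSV, truth tables (dosage TSV, composition TSV, sweep/env
#' site TSVs) and the resolved config as YAML.
#'
#' @param cohort a `syn_cohort`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- paste0("polycane simulate seed=", cohort$config$seed)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             meta = file.path(dir, "meta.tsv"),
             gff = file.path(dir, "genes.gff3"),
             cds = file.path(dir, "cds.fasta"),
             env = file.path(dir, "env.tsv"),
             truth_dosage = file.path(dir, "truth_dosage.tsv"),
             truth_comp = file.path(dir, "truth_composition.tsv"),
             config = file.path(dir, "config.yaml"))
  write_variant_table(cohort$variants, paths["vcf"], provenance = pv)
  write_tsv(cohort$meta, paths["meta"], provenance = pv)
  write_gene_models(cohort$genes, paths["gff"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$cds), paths["cds"])
  write_tsv(data.frame(id = rownames(cohort$env), cohort$env,
                       check.names = FALSE), paths["env"], provenance = pv)
  tdm <- dosage_matrix(cohort$truth$dosages,
                       matrix(Inf, nrow(cohort$truth$dosages),
                              ncol(cohort$truth$dosages)),
                       cohort$truth$ploidy, cohort$variants$sites)
  write_dosage_tsv(tdm, paths["truth_dosage"], provenance = pv)
  comp <- cohort$truth$composition
  if (is.null(comp)) comp <- data.frame(id = character(), fracA = numeric(),
                                        fracB = numeric())
  write_tsv(comp, paths["truth_comp"], provenance = pv)
  cfg <- cohort$config
  yaml::write_yaml(.yamlify(unclass(cfg)), paths["config"])
  invisible(paths)
}

#' Draw the progenitor layer of a cohort
#'
#' Standalone wrapper around the progenitor step: genome layout, ancestral
#' and species frequencies, progenitor dosages. Seeds the RNG from the
#' config.
#'
#' @param cfg a [sim_config()].
#' @return list: `genes`, `sites`, `freq` (sites x populations),
#'   `dosages` (list per species, sites x accessions),
#'   `fixed_diff_sites`, `sweep_sites`.
#' @export
simulate_progenitor_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gm <- .sim_genes(cfg)
  cds <- .sim_cds(gm)
  sites <- .sim_alleles(.sim_sites(cfg, gm), gm, cds)
  sf <- .sim_species_freqs(cfg, sites, gm)
  na <- cfg$n_accessions
  dos <- list(
    speciesA = .draw_dosages(sf$freq[, "speciesA"],
                             rep_len(cfg$ploidy$speciesA, na[["speciesA"]])),
    speciesB = .draw_dosages(sf$freq[, "speciesB"],
                             rep_len(cfg$ploidy$speciesB, na[["speciesB"]])))
  list(genes = gm, sites = sites, freq = sf$freq, dosages = dos,
       fixed_diff_sites = sf$fixed_diff_sites, sweep_sites = sf$sweep_sites)
}

#' Draw mosaic hybrids against existing progenitor frequencies
#'
#' Standalone wrapper around the hybrid-mosaic step (see
#' [simulate_cohort()] for the block model). Uses the current RNG state.
#'
#' @param cfg a [sim_config()].
#' @param sites site table from [simulate_progenitor_populations()].
#' @param freq species frequency matrix.
#' @param n_hybrids number of hybrids to draw.
#' @return list: `dosage`, `ancestryB`, `true_composition`.
#' @export
simulate_hybrids <- function(cfg, sites, freq, n_hybrids = cfg$n_accessions[["hybrid"]]) {
  pl <- rep_len(cfg$ploidy$hybrid, n_hybrids)
  hc <- cfg$hybrid_composition
  comp <- if (length(hc) == 2) stats::runif(n_hybrids, hc[1], hc[2])
  else rep_len(hc, n_hybrids)
  .sim_hybrids(cfg, sites, freq, pl, comp)
}

#' Simulate the environmental table for a metadata frame
#'
#' Standalone wrapper around the environment step (latent factors anchored
#' on geography). Uses the current RNG state.
#'
#' @param cfg a [sim_config()].
#' @param meta metadata with `lon`/`lat`.
#' @return list: `env`, `gradient`.
#' @export
simulate_environment <- function(cfg, meta) .sim_environment(cfg, meta)
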