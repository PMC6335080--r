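# Pipeline orchestration: run the stages in dependency order from one
# config, with seeded reproducibility and provenance-stamped outputs.

.PIPELINE_KEYS <- c("out_dir", "seed", "sim", "genotype", "stats",
                    "composition", "ld", "scan", "eaa", "stages")

# YAML-safe representation: maps for named vectors, lists for data.frames
.yamlify <- function(x) {
  if (is.data.frame(x)) return(lapply(as.list(x), .yamlify))
  if (is.list(x)) return(lapply(x, .yamlify))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages execute in dependency order: `simulate` -> `genotype` ->
#' `stats` / `composition` / `ld` / `scan` / `eaa`. Every output file
#' carries a provenance header (stage, parameters, seed — no timestamps, so
#' reruns with the same config are byte-identical). Unknown config keys are
#' rejected before any stage runs, and a resolved copy of the config is
#' written beside the outputs.
#'
#' @param config either a YAML path or a list. Recognised keys: `out_dir`,
#'   `seed`, `stages` (subset to run), and per-stage parameter blocks
#'   `sim` (arguments of [sim_config()]), `genotype` (`error_rate`,
#'   `min_dp`, `min_llr`, `site_call_rate`, `min_mean_dp`,
#'   `min_call_rate_l1`), `ld` (`population`, `maf_min`, `call_rate_min`,
#'   `spacing_bp`, `max_dist`, `bin_width`, `min_pairs`, `threshold`),
#'   `scan` (`stride`, `top_fraction_windows`, `top_fraction_genes`,
#'   `min_sites`), `eaa` (`n_pcs`, `k`, `n_runs`, `alpha`, `maf_min`,
#'   `call_rate_min`).
#' @return list of stage results (invisible), with `paths` naming every
#'   file written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stop("config needs out_dir")
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||%
    c("simulate", "genotype", "stats", "composition", "ld", "scan", "eaa")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  simargs <- config$sim %||% list()
  bad <- setdiff(names(simargs), names(formals(sim_config)))
  if (length(bad)) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
  simargs$seed <- seed
  res <- list(paths = character(0))
  pv <- function(stage, ...) paste0("polycane ", stage, " seed=", seed,
                                    " ", paste(..., collapse = " "))
  note <- function(p) res$paths <<- c(res$paths, p)
  need <- function(x, st) if (is.null(x))
    stop("stage '", st, "' needs an upstream result; run its parent stage first")

  cohort <- NULL; fl <- NULL
  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(do.call(sim_config, simargs))
    note(write_cohort(cohort, file.path(out, "sim")))
    res$cohort <- cohort
  }
  gcfg <- config$genotype %||% list()
  if ("genotype" %in% stages) {
    need(cohort, "genotype")
    dm0 <- genotype_variants(cohort$variants, cohort$meta,
                             error_rate = gcfg$error_rate %||% 0.005,
                             min_dp = gcfg$min_dp %||% 5L)
    fl <- apply_filters(dm0, cohort$variants,
                        min_mean_dp = gcfg$min_mean_dp %||% 10,
                        min_call_rate_l1 = gcfg$min_call_rate_l1 %||% 0.5,
                        min_llr = gcfg$min_llr %||% 2,
                        site_call_rate = gcfg$site_call_rate %||% 0.8)
    note(write_dosage_tsv(fl$level2, file.path(out, "dosage.tsv"),
                          provenance = pv("genotype",
                                          paste0("llr>=", gcfg$min_llr %||% 2))))
    note(write_tsv(fl$audit, file.path(out, "filter_audit.tsv"),
                   provenance = pv("genotype")))
    res$filters <- fl
  }
  pops <- NULL
  mkpops <- function() {
    m <- cohort$meta
    sp <- split(m$id, m$group)
    sp[order(names(sp))]
  }
  if ("stats" %in% stages) {
    need(fl, "stats")
    dm <- fl$level2
    pops <- mkpops()
    af <- allele_frequencies(dm, pops)
    regions <- data.frame(region_id = cohort$genes$genes$gene_id,
                          chrom = cohort$genes$genes$chrom,
                          start = cohort$genes$genes$start,
                          end = cohort$genes$genes$end)
    pis <- lapply(stats::setNames(colnames(af$freq), colnames(af$freq)),
                  function(g) nucleotide_diversity(af, g, regions))
    fsts <- list()
    cmb <- utils::combn(colnames(af$freq), 2)
    for (k in seq_len(ncol(cmb)))
      fsts[[paste(cmb[1, k], cmb[2, k], sep = "_vs_")]] <-
        fst_nei(af, cmb[1, k], cmb[2, k])$fst
    dmat <- pairwise_distance_matrix(dm)
    tree <- if (!anyNA(dmat$dist)) nj_tree(dmat) else NULL
    sdf <- sd_fraction(dm)
    gene_pi <- Reduce(function(a, b) merge(a, b, by = "region_id"),
                      Map(function(p, nm) stats::setNames(p[, c("region_id", "pi")],
                                                          c("region_id", paste0("pi_", nm))),
                          pis, names(pis)))
    note(write_tsv(gene_pi, file.path(out, "gene_pi.tsv"), provenance = pv("stats")))
    note(write_tsv(data.frame(pair = names(fsts), fst = unlist(fsts)),
                   file.path(out, "fst.tsv"), provenance = pv("stats")))
    note(write_tsv(data.frame(id = names(sdf), sd_fraction = sdf),
                   file.path(out, "sd_fraction.tsv"), provenance = pv("stats")))
    if (!is.null(tree)) note(write_newick(tree, file.path(out, "nj.nwk")))
    res$stats <- list(af = af, pi = pis, fst = fsts, dist = dmat,
                      tree = tree, sd_fraction = sdf)
  }
  if ("composition" %in% stages) {
    need(fl, "composition")
    dm <- fl$level2
    pops <- pops %||% mkpops()
    if (all(c("speciesA", "speciesB", "hybrid") %in% names(pops))) {
      mk <- find_diagnostic_snps(dm, pops$speciesA, pops$speciesB)
      comp <- genome_composition(dm, mk, pops$hybrid)
      note(write_bed(data.frame(chrom = mk$chrom, start = mk$pos0,
                                end = mk$pos0 + 1L, name = paste0(mk$direction,
                                                                  "_", mk$allele)),
                     file.path(out, "diagnostic_markers.bed")))
      note(write_tsv(comp, file.path(out, "composition.tsv"),
                     provenance = pv("composition")))
      res$composition <- list(markers = mk, composition = comp)
    } else message("composition stage skipped: need speciesA/speciesB/hybrid groups")
  }
  lcfg <- config$ld %||% list()
  if ("ld" %in% stages) {
    need(fl, "ld")
    dm <- fl$level2
    pops <- pops %||% mkpops()
    popname <- lcfg$population %||% "hybrid"
    dmp <- subset_dosage(dm, samples = pops[[popname]])
    keep <- thin_snps(dmp, lcfg$maf_min %||% 0.05,
                      lcfg$call_rate_min %||% 0.95, lcfg$spacing_bp %||% 0)
    pairs <- ld_pairs(dmp, keep, max_dist = lcfg$max_dist %||% 1e7,
                      min_n = lcfg$min_n %||% 20L)
    if (nrow(pairs) == 0) {
      message("ld stage: no usable pairs (population too small or sites too sparse)")
    } else {
      curve <- ld_decay_curve(pairs, max_dist = lcfg$max_dist %||% 1e7,
                              bin_width = lcfg$bin_width %||% 5e4,
                              min_pairs = lcfg$min_pairs %||% 50L)
      dd <- tryCatch(decay_distance_at(curve, lcfg$threshold %||% 0.2),
                     error = function(e) NA_real_)
      note(write_tsv(curve, file.path(out, "ld_curve.tsv"),
                     provenance = pv("ld", popname)))
      note(write_tsv(data.frame(population = popname,
                                threshold = lcfg$threshold %||% 0.2,
                                decay_bp = dd),
                     file.path(out, "ld_decay.tsv"), provenance = pv("ld")))
      res$ld <- list(curve = curve, decay_bp = dd, n_sites = length(keep))
    }
  }
  scfg <- config$scan %||% list()
  if ("scan" %in% stages) {
    need(fl, "scan")
    dm <- fl$level2
    pops <- pops %||% mkpops()
    af <- if (!is.null(res$stats)) res$stats$af else allele_frequencies(dm, pops)
    if ("outgroup" %in% colnames(af$freq)) {
      track <- window_branch_score(af, "speciesB", "speciesA", "outgroup",
                                   stride = scfg$stride %||% 20L)
      sweeps <- select_top_fraction_windows(track,
                                            scfg$top_fraction_windows %||% 0.01)
      note(write_bed(data.frame(chrom = sweeps$chrom, start = sweeps$start,
                                end = sweeps$end, score = sweeps$max_score),
                     file.path(out, "sweep_intervals.bed")))
      res$scan$sweeps <- sweeps
      res$scan$track <- track
    } else message("PBS scan skipped: no outgroup population")
    if (!is.null(res$stats)) {
      piA <- res$stats$pi$speciesA; piB <- res$stats$pi$speciesB
      pr <- pi_ratio_scan(piA, piB, scfg$top_fraction_genes %||% 0.05,
                          scfg$min_sites %||% 5L)
      note(write_tsv(pr, file.path(out, "pi_ratio.tsv"), provenance = pv("scan")))
      res$scan$pi_ratio <- pr
    }
  }
  ecfg <- config$eaa %||% list()
  if ("eaa" %in% stages) {
    need(cohort, "eaa"); need(fl, "eaa")
    dm <- fl$level2
    pc <- env_pca(cohort$env, ecfg$n_pcs %||% 5L)
    flt <- eaa_filter(dm, ecfg$maf_min %||% 0.05, ecfg$call_rate_min %||% 0.95)
    hits_all <- list()
    lambdas <- numeric(0)
    for (j in seq_len(ncol(pc$scores))) {
      Z <- latent_factor_association(flt$G, pc$scores[, j],
                                     K = ecfg$k %||% 6L,
                                     n_runs = ecfg$n_runs %||% 10L,
                                     seed = seed + 1000L * j)
      cz <- combine_zscores_calibrate(Z)
      lambdas[paste0("PC", j)] <- cz$lambda
      bs <- bonferroni_select(cz$p, flt$sites, ecfg$alpha %||% 0.01,
                              cohort$genes)
      if (nrow(bs$hits))
        hits_all[[j]] <- cbind(pc = paste0("PC", j), bs$hits)
    }
    hits <- if (length(hits_all)) do.call(rbind, hits_all)
    else data.frame(pc = character(), chrom = character(), pos0 = integer(),
                    p = numeric(), gene_id = character())
    note(write_tsv(hits, file.path(out, "eaa_hits.tsv"), provenance = pv("eaa")))
    note(write_tsv(data.frame(pc = names(lambdas), lambda = lambdas),
                   file.path(out, "eaa_lambda.tsv"), provenance = pv("eaa")))
    res$eaa <- list(hits = hits, lambda = lambdas, env_pcs = pc)
  }
  cfg_resolved <- config
  cfg_resolved$seed <- seed
  cfg_resolved$out_dir <- NULL    # implied by location; keeps reruns byte-identical
  yaml::write_yaml(.yamlify(cfg_resolved), file.path(out, "config_resolved.yaml"))
  note(file.path(out, "config_resolved.yaml"))
  invisible(res)
}
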