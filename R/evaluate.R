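# Simulation studies used to validate the pipeline against its own truth
# sets: detection power, threshold calibration, and the multivariate (PC
# trait) gain.  These drive both the test suite and the reproduction script.

#' QTL detection power and localization study
#'
#' Replicates a two-chromosome RIL panel with one planted QTL of known
#' theoretical PVE, scans the affected trait with a permutation threshold,
#' and scores detection, peak localization error, support-interval coverage,
#' and PVE recovery.
#'
#' @param n_rep number of replicates.
#' @param n_ril RILs per replicate (default 250).
#' @param pve theoretical percent variance explained of the planted QTL
#'   (default 15).
#' @param true_cM QTL position on chromosome 1 (default 40).
#' @param chrom_len_cM map length of each of the two chromosomes.
#' @param n_markers markers per chromosome for the truth-derived marker map.
#' @param n_perm permutations per replicate.
#' @param alpha significance level.
#' @param seed base seed; replicate r uses sub-stream `seed + r`.
#' @return data frame, one row per replicate: `detected`, `peak_err_cM`,
#'   `ci_covers`, `pve_est`, `lod`.
#' @export
qtl_power_study <- function(n_rep = 100L, n_ril = 250L, pve = 15,
                            true_cM = 40, chrom_len_cM = 100,
                            n_markers = 51L, n_perm = 100L, alpha = 0.05,
                            seed = 1L) {
  a <- sqrt(pve / (100 - pve))
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_ril = n_ril, n_chrom = 2, chrom_len_bp = 30e6,
                      chrom_len_cM = chrom_len_cM, n_snp_per_chrom = 10,
                      elements = c("Cd", "Zn"),
                      qtl_spec = list(planted_qtl(1, true_cM, "Cd", a)),
                      seed = substream_seed(seed, 500L + r))
    truth <- simulate_ril_genomes(cfg)
    bm <- truth_bin_matrix(truth, n_markers = n_markers)
    lm_ <- build_linkage_map(bm, "kosambi")
    probs <- genotype_probs(bm, lm_)
    ph <- simulate_phenotypes(truth, cfg)
    trait <- stats::setNames(ph$tables$env1$Cd, ph$tables$env1$ril_id)
    res <- scan_trait(probs, trait, "Cd", n_perm = n_perm, alpha = alpha,
                      seed = substream_seed(seed, 900L + r))
    # the QTL's location expressed in the estimated map's coordinates
    true_est <- stats::approx(seq(0, chrom_len_cM, length.out = n_markers),
                              lm_$pos_cM[lm_$lg == 1], xout = true_cM)$y
    pk <- res$peaks[res$peaks$lg == 1, , drop = FALSE]
    if (nrow(pk)) {
      best <- pk[which.min(abs(pk$peak_cM - true_est)), ]
      rows[[r]] <- data.frame(detected = TRUE,
                              peak_err_cM = abs(best$peak_cM - true_est),
                              ci_covers = best$ci_lo_cM <= true_est &
                                best$ci_hi_cM >= true_est,
                              pve_est = best$pve_pct, lod = best$lod)
    } else {
      rows[[r]] <- data.frame(detected = FALSE, peak_err_cM = NA_real_,
                              ci_covers = NA, pve_est = NA_real_,
                              lod = max(res$curve$lod))
    }
  }
  do.call(rbind, rows)
}

#' Genome-wide type-I error calibration of the permutation threshold
#'
#' On one fixed simulated marker map, scans many independent pure-noise
#' traits, each against its own permutation threshold, and reports the
#' fraction whose genome-wide maximum LOD reaches the threshold.
#'
#' @param n_traits number of null traits (default 200).
#' @param n_ril panel size (default 200).
#' @param n_perm permutations per trait (default 300).
#' @param alpha nominal level (default 0.05).
#' @param n_chrom,chrom_len_cM,n_markers genome shape for the fixed map.
#' @param seed base seed.
#' @return list `rejected` (logical per trait), `fp_rate`, `alpha`, and the
#'   95% binomial CI half-width.
#' @export
threshold_calibration_study <- function(n_traits = 200L, n_ril = 200L,
                                        n_perm = 300L, alpha = 0.05,
                                        n_chrom = 2L, chrom_len_cM = 100,
                                        n_markers = 51L, seed = 1L) {
  cfg <- sim_config(n_ril = n_ril, n_chrom = n_chrom, chrom_len_bp = 30e6,
                    chrom_len_cM = chrom_len_cM, n_snp_per_chrom = 10,
                    elements = c("Cd", "Zn"),
                    seed = substream_seed(seed, 700L))
  truth <- simulate_ril_genomes(cfg)
  bm <- truth_bin_matrix(truth, n_markers = n_markers)
  lm_ <- build_linkage_map(bm, "kosambi")
  probs <- genotype_probs(bm, lm_)
  set.seed(substream_seed(seed, 701L))
  trait_seeds <- sample.int(2^30, n_traits)
  rejected <- logical(n_traits)
  for (k in seq_len(n_traits)) {
    set.seed(trait_seeds[k])
    y <- stats::rnorm(n_ril)
    names(y) <- bm$ril_ids
    curve <- hk_scan(probs, y)
    thr <- permute_threshold(probs, y, n_perm = n_perm, alpha = alpha,
                             seed = trait_seeds[k])
    rejected[k] <- max(curve$lod) >= thr$threshold
  }
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_traits)
  list(rejected = rejected, fp_rate = mean(rejected), alpha = alpha,
       ci_half_width = half)
}

#' Multivariate gain study: PC-trait scans and three-class clusters
#'
#' Replicates a panel with one pleiotropic QTL spread over three correlated
#' elements at small per-element PVE, runs elemental, within-environment PC
#' and across-environment aPC scans in two environments, and scores whether
#' (i) a PC-score scan detects the locus, (ii) the co-localization stage
#' emits a three-class cluster there, and (iii) a cluster member's top-5
#' loading list contains all three planted elements.
#'
#' @param n_rep replicates (default 50).
#' @param n_ril panel size (default 250).
#' @param per_element_pve theoretical per-element PVE in percent (default 5).
#' @param noise_corr residual correlation among the three affected elements.
#' @param true_cM QTL position on chromosome 1.
#' @param n_perm permutations per trait.
#' @param alpha significance level.
#' @param seed base seed.
#' @return data frame per replicate: `pc_detected`, `cluster_found`,
#'   `top5_all3`, `n_pc_qtl`, `n_apc_qtl`, `n_elemental_qtl`.
#' @export
pc_gain_study <- function(n_rep = 50L, n_ril = 250L, per_element_pve = 5,
                          noise_corr = 0.6, true_cM = 40, n_perm = 100L,
                          alpha = 0.05, seed = 1L) {
  elements <- c("Ca", "Sr", "Cd", "Cu", "Fe", "K", "Mo", "Zn")
  affected <- c("Ca", "Sr", "Cd")
  a <- sqrt(per_element_pve / (100 - per_element_pve))
  S <- diag(length(elements))
  ia <- match(affected, elements)
  S[ia, ia] <- noise_corr
  diag(S) <- 1
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_ril = n_ril, n_chrom = 2, chrom_len_bp = 30e6,
                      chrom_len_cM = 100, n_snp_per_chrom = 10,
                      n_env = 2, elements = elements,
                      qtl_spec = list(planted_qtl(1, true_cM, affected, a)),
                      element_corr_noise = S,
                      seed = substream_seed(seed, 1500L + r))
    truth <- simulate_ril_genomes(cfg)
    bm <- truth_bin_matrix(truth, n_markers = 51L)
    lm_ <- build_linkage_map(bm, "kosambi")
    probs <- genotype_probs(bm, lm_)
    ph <- simulate_phenotypes(truth, cfg)
    k <- 0L
    sseed <- function() substream_seed(seed, 2000L + 97L * r + k)
    records <- empty_qtl_records()
    for (e in names(ph$tables)) {
      tab <- ph$tables[[e]]
      for (el in elements) {
        k <- k + 1L
        res <- scan_trait(probs, stats::setNames(tab[[el]], tab$ril_id),
                          el, n_perm = n_perm, alpha = alpha, seed = sseed())
        if (nrow(res$peaks))
          records <- rbind(records, qtl_records(res$peaks, "elemental",
                                                env = e, element = el))
      }
      model <- pca_within(tab, scope = e)
      for (pc in seq_along(elements)) {
        k <- k + 1L
        res <- scan_trait(probs,
                          stats::setNames(model$scores[, pc],
                                          model$rows$ril_id),
                          sprintf("%s_PC%d", e, pc), n_perm = n_perm,
                          alpha = alpha, seed = sseed())
        if (nrow(res$peaks))
          records <- rbind(records, qtl_records(
            res$peaks, "PC", env = e,
            top5 = top_loading_elements(model, pc)$element))
      }
    }
    amodel <- pca_across(ph$tables, names(ph$tables), scope = "ALL")
    for (tn in names(apc_score_traits(amodel))) {
      k <- k + 1L
      pc <- as.integer(sub(".*_aPC", "", tn))
      res <- scan_trait(probs, apc_score_traits(amodel)[[tn]], tn,
                        n_perm = n_perm, alpha = alpha, seed = sseed())
      if (nrow(res$peaks))
        records <- rbind(records, qtl_records(
          res$peaks, "aPC", env = sub("_aPC.*", "", sub("^ALL_", "", tn)),
          top5 = top_loading_elements(amodel, pc)$element))
    }
    true_est <- stats::approx(seq(0, 100, length.out = 51L),
                              lm_$pos_cM[lm_$lg == 1], xout = true_cM)$y
    at_locus <- function(rr) rr$lg == 1 & rr$lo_cM <= true_est &
      rr$hi_cM >= true_est
    pcs <- records[records$qtl_class == "PC", , drop = FALSE]
    cl <- find_clusters(records)
    cl_loc <- Filter(function(x) x$lg == 1 && x$lo_cM <= true_est &&
                       x$hi_cM >= true_est, cl)
    top5_all3 <- any(vapply(cl_loc, function(x) {
      lists <- x$members$top5[!is.na(x$members$top5)]
      any(vapply(strsplit(lists, ";", fixed = TRUE),
                 function(s) all(affected %in% s), logical(1)))
    }, logical(1)))
    rows[[r]] <- data.frame(
      pc_detected = any(at_locus(pcs)),
      cluster_found = length(cl_loc) > 0,
      top5_all3 = top5_all3,
      n_pc_qtl = nrow(pcs),
      n_apc_qtl = sum(records$qtl_class == "aPC"),
      n_elemental_qtl = sum(records$qtl_class == "elemental"))
  }
  do.call(rbind, rows)
}

#' Bin-map recovery study against the simulation truth
#'
#' Runs the full genotyping chain (SNP observation, window calling, block
#' segmentation, bin map) on one simulated chromosome and scores crossover
#' recovery and (RIL, bin) genotype accuracy against the truth tracks.
#'
#' @param n_ril panel size (default 100).
#' @param n_snp SNP sites (default 5000).
#' @param mean_depth per-site depth (e.g. 50 for effectively full coverage,
#'   2 for the low-coverage regime).
#' @param genotyping_error per-call error probability.
#' @param chrom_len_cM,chrom_len_bp chromosome dimensions.
#' @param seed seed.
#' @return list: `accuracy` ((RIL, bin) genotype agreement at bin midpoints),
#'   `xo_total`, `xo_resolvable` (true crossovers whose nearest same-RIL
#'   neighbor is > 15 observed SNPs away), `xo_recovered_15snp` (fraction of
#'   resolvable crossovers matched by a called breakpoint within 15 observed
#'   SNPs), `n_bins`, `het_population`.
#' @export
binmap_recovery_study <- function(n_ril = 100L, n_snp = 5000L,
                                  mean_depth = 50, genotyping_error = 0,
                                  chrom_len_cM = 150, chrom_len_bp = 30e6,
                                  seed = 1L) {
  cfg <- sim_config(n_ril = n_ril, n_chrom = 1, chrom_len_bp = chrom_len_bp,
                    chrom_len_cM = chrom_len_cM, n_snp_per_chrom = n_snp,
                    mean_depth = mean_depth,
                    genotyping_error = genotyping_error,
                    elements = c("Cd", "Zn"), seed = seed)
  truth <- simulate_ril_genomes(cfg)
  obs <- simulate_snp_observations(truth, cfg)
  snps <- filter_snps(obs)
  span <- data.frame(chrom = 1L, start_bp = min(snps$sites$pos),
                     end_bp = max(snps$sites$pos))
  blocks <- lapply(seq_len(n_ril), function(i)
    call_blocks(call_windows(snps, i), span = span))
  bins <- build_bin_map(blocks, ril_ids = snps$ril_ids)
  mids <- (bins$bins$start_bp + bins$bins$end_bp) / 2
  acc <- mean(vapply(seq_len(n_ril), function(i)
    mean(bins$geno[, i] == truth_genotype_at(truth, i, 1, mids),
         na.rm = TRUE), numeric(1)))
  snp_pos <- snps$sites$pos
  snp_rank <- function(x) findInterval(x, snp_pos)
  n_snp_retained <- length(snp_pos)
  xo_total <- 0L; xo_res <- 0L; xo_hit <- 0L
  for (i in seq_len(n_ril)) {
    seg <- truth$genomes[[i]][[1]]
    tb <- seg$end_bp[-nrow(seg)]
    if (!length(tb)) next
    xo_total <- xo_total + length(tb)
    bb <- blocks[[i]]$end_bp[-nrow(blocks[[i]])]
    for (j in seq_along(tb)) {
      rk <- snp_rank(tb[j])
      # resolvable: both flanking parental segments span at least two full
      # windows of observed SNPs, and the crossover is not at the span edge
      gap_ok <- (length(tb) == 1L ||
                   min(abs(snp_rank(tb[-j]) - rk)) > 30L) &&
        rk > 15L && rk < n_snp_retained - 15L
      if (!gap_ok) next
      xo_res <- xo_res + 1L
      if (length(bb) &&
          min(abs(snp_rank(bb) - snp_rank(tb[j]))) <= 15L)
        xo_hit <- xo_hit + 1L
    }
  }
  het <- suppressWarnings(heterozygosity(bins))
  list(accuracy = acc, xo_total = xo_total, xo_resolvable = xo_res,
       xo_recovered_15snp = if (xo_res) xo_hit / xo_res else NA_real_,
       n_bins = nrow(bins$bins), het_population = het$population)
}
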