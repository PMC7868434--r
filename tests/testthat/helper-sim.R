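# Shared fixture builders.  Everything is generated in code at test time.

# small, fast simulated panel: 1-2 chromosomes, one pleiotropic QTL
small_cfg <- function(seed = 7, n_ril = 60, n_chrom = 1,
                      chrom_len_cM = 100, n_snp = 800, mean_depth = 2,
                      genotyping_error = 0.005, n_env = 1,
                      elements = c("Ca", "Sr", "Cd", "Zn"),
                      qtl_spec = list()) {
  sim_config(n_ril = n_ril, n_chrom = n_chrom, chrom_len_bp = 5e6,
             chrom_len_cM = chrom_len_cM, n_snp_per_chrom = n_snp,
             mean_depth = mean_depth, genotyping_error = genotyping_error,
             n_env = n_env, elements = elements, qtl_spec = qtl_spec,
             seed = seed)
}

# run the genotyping chain truth -> snp table -> blocks -> bin map
sim_bin_map <- function(cfg, min_bin_bp = 20000L) {
  truth <- simulate_ril_genomes(cfg)
  obs <- simulate_snp_observations(truth, cfg)
  snps <- filter_snps(obs)
  span <- do.call(rbind, lapply(unique(snps$sites$chrom), function(cc) {
    p <- snps$sites$pos[snps$sites$chrom == cc]
    data.frame(chrom = cc, start_bp = min(p), end_bp = max(p))
  }))
  blocks <- lapply(seq_along(snps$ril_ids), function(i)
    call_blocks(call_windows(snps, i), span = span))
  bins <- build_bin_map(blocks, min_bin_bp = min_bin_bp,
                        ril_ids = snps$ril_ids)
  list(truth = truth, obs = obs, snps = snps, blocks = blocks, bins = bins)
}

# hand-built snp table: one chromosome, explicit calls matrix
manual_snp_table <- function(pos, calls, p1 = "A", p2 = "C",
                             p1_depth = 30L, p2_depth = 30L, depth = NULL) {
  n <- length(pos)
  calls <- as.matrix(calls)
  if (is.null(depth)) depth <- matrix(10L, n, ncol(calls))
  sites <- data.frame(chrom = 1L, pos = pos,
                      parent1_allele = rep_len(p1, n),
                      parent2_allele = rep_len(p2, n),
                      parent1_depth = rep_len(p1_depth, n),
                      parent2_depth = rep_len(p2_depth, n))
  ril_ids <- sprintf("RIL%03d", seq_len(ncol(calls)))
  colnames(calls) <- colnames(depth) <- ril_ids
  ionqtl:::new_snp_table(sites, calls, depth, ril_ids)
}

# bin matrix straight from genotype columns (bins of equal length)
manual_bin_matrix <- function(geno, chrom = 1L, bin_bp = 1e5) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  bins <- data.frame(chrom = chrom,
                     start_bp = (seq_len(n) - 1) * bin_bp,
                     end_bp = seq_len(n) * bin_bp)
  ril_ids <- sprintf("RIL%03d", seq_len(ncol(geno)))
  colnames(geno) <- ril_ids
  ionqtl:::new_bin_matrix(bins, geno, ril_ids)
}

# closed-form single-marker regression LOD: independent oracle for hk_scan
marker_lod_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  fit <- lm(y ~ x)
  rss1 <- sum(residuals(fit)^2)
  (n / 2) * log10(rss0 / rss1)
}

# a QTL record row for colocal tests
rec <- function(class, lg, lo, hi, element = NA, trait = "t",
                env = "e1", top5 = NA_character_, lod = 5) {
  data.frame(id = NA_character_, qtl_class = class, trait = trait,
             element = element, env = env, lg = lg, lo_cM = lo, hi_cM = hi,
             peak_cM = (lo + hi) / 2, lod = lod, pve = 10, top5 = top5,
             stringsAsFactors = FALSE)
}
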