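#' Default element panel
#'
#' The 16 elements measured in the grain/shoot/root ionome, in fixed order.
#' This order is also the tie-break order for loading ranks.
#' @export
ION_ELEMENTS <- c("As", "Ca", "Cd", "Co", "Cu", "Fe", "K", "Mg",
                  "Mn", "Mo", "Ni", "P", "Rb", "S", "Sr", "Zn")

#' Describe a planted QTL for the simulator
#'
#' @param chrom integer chromosome id.
#' @param position_cM map position of the causal locus in cM.
#' @param affected_elements character vector of element names the locus
#'   affects (pleiotropy = length > 1).
#' @param additive_effects numeric, per affected element, effect of the
#'   TQ allele in residual-SD units (recycled if length 1).
#' @param environments integer ids of environments where the QTL is active
#'   (NULL = all environments).
#' @return a `planted_qtl` list.
#' @export
planted_qtl <- function(chrom, position_cM, affected_elements,
                        additive_effects, environments = NULL) {
  stopifnot(length(affected_elements) >= 1, position_cM >= 0)
  additive_effects <- rep_len(additive_effects, length(affected_elements))
  structure(list(chrom = as.integer(chrom),
                 position_cM = as.numeric(position_cM),
                 affected_elements = as.character(affected_elements),
                 additive_effects = as.numeric(additive_effects),
                 environments = if (is.null(environments)) NULL
                                else as.integer(environments)),
            class = "planted_qtl")
}

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: an F_20 RIL panel
#' from two fully homozygous parents, sequenced at ~2x mean depth, phenotyped
#' for 16 elements in several environments/tissues.
#'
#' @param n_ril number of RILs (the sequenced panel had 257).
#' @param n_chrom number of chromosomes.
#' @param chrom_len_bp physical length per chromosome (bp), recycled.
#' @param chrom_len_cM map length per chromosome (cM), recycled.
#' @param n_snp_per_chrom number of parent-divergent SNP sites per chromosome.
#' @param generation selfing generation (F_t); default 20.
#' @param mean_depth mean sequencing depth per RIL per site; default 2.
#' @param genotyping_error probability an observed call reports the wrong
#'   parent allele; default 0.005.
#' @param n_env number of environments/tissues phenotyped.
#' @param elements element names (defaults to the 16-element panel).
#' @param qtl_spec list of [planted_qtl()] objects.
#' @param element_corr_noise residual correlation matrix among elements
#'   (unit diagonal, positive semi-definite); default identity.
#' @param env_effect_sd SD of per-(environment, element) additive mean
#'   shifts, in residual-SD units; default 0.5.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_ril = 257, n_chrom = 12,
                       chrom_len_bp = 30e6, chrom_len_cM = 150,
                       n_snp_per_chrom = 5000, generation = 20,
                       mean_depth = 2.0, genotyping_error = 0.005,
                       n_env = 2, elements = ION_ELEMENTS,
                       qtl_spec = list(),
                       element_corr_noise = NULL,
                       env_effect_sd = 0.5, seed = 1L) {
  n_el <- length(elements)
  if (is.null(element_corr_noise)) element_corr_noise <- diag(n_el)
  cfg <- list(n_ril = as.integer(n_ril), n_chrom = as.integer(n_chrom),
              chrom_len_bp = rep_len(as.numeric(chrom_len_bp), n_chrom),
              chrom_len_cM = rep_len(as.numeric(chrom_len_cM), n_chrom),
              n_snp_per_chrom = as.integer(n_snp_per_chrom),
              generation = as.integer(generation),
              mean_depth = as.numeric(mean_depth),
              genotyping_error = as.numeric(genotyping_error),
              n_env = as.integer(n_env), elements = as.character(elements),
              qtl_spec = qtl_spec,
              element_corr_noise = as.matrix(element_corr_noise),
              env_effect_sd = as.numeric(env_effect_sd),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_ril < 2) stop("n_ril must be >= 2")
  if (cfg$generation < 2) stop("generation must be >= 2")
  if (cfg$mean_depth <= 0) stop("mean_depth must be > 0")
  if (any(cfg$chrom_len_cM <= 0)) stop("chromosome map length must be > 0")
  if (any(cfg$chrom_len_bp <= 0)) stop("chromosome physical length must be > 0")
  S <- cfg$element_corr_noise
  n_el <- length(cfg$elements)
  if (!isTRUE(all.equal(dim(S), c(n_el, n_el))))
    stop("element_corr_noise must be ", n_el, " x ", n_el)
  if (max(abs(S - t(S))) > 1e-8) stop("element_corr_noise must be symmetric")
  if (max(abs(diag(S) - 1)) > 1e-8)
    stop("element_corr_noise must have unit diagonal")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("element_corr_noise must be positive semi-definite")
  for (q in cfg$qtl_spec) {
    if (q$chrom < 1 || q$chrom > cfg$n_chrom) stop("planted QTL chrom out of range")
    if (q$position_cM > cfg$chrom_len_cM[q$chrom])
      stop("planted QTL position beyond chromosome map length")
    if (!all(q$affected_elements %in% cfg$elements))
      stop("planted QTL affects unknown element")
  }
  invisible(cfg)
}

# --- haplotype machinery ----------------------------------------------------
# A haplotype on one chromosome is a step function of parental origin along
# the cM axis: list(bp = interior breakpoints (cM, ascending), org = origin
# codes, length(bp) + 1, values in {GENO_LM, GENO_TQ}).

.hap_at <- function(hap, x) hap$org[findInterval(x, hap$bp) + 1L]

.hap_compress <- function(bp, org) {
  if (length(org) > 1L) {
    keep <- org[-1L] != org[-length(org)]
    bp <- bp[keep]
    org <- org[c(TRUE, keep)]
  }
  list(bp = bp, org = org)
}

# One meiosis: recombine two haplotypes into a gamete.  Crossover count is
# Poisson(map length in Morgans), positions uniform -- no interference
# (Haldane model, consistent with the map functions used downstream).
.gamete <- function(h1, h2, len_cM) {
  n_xo <- stats::rpois(1L, len_cM / 100)
  xo <- sort(stats::runif(n_xo, 0, len_cM))
  start <- sample.int(2L, 1L)
  cuts <- sort(unique(c(xo, h1$bp, h2$bp)))
  mids <- if (length(cuts)) (c(0, cuts) + c(cuts, len_cM)) / 2 else len_cM / 2
  which_chromatid <- (start - 1L + findInterval(mids, xo)) %% 2L + 1L
  org <- ifelse(which_chromatid == 1L, .hap_at(h1, mids), .hap_at(h2, mids))
  out <- .hap_compress(cuts, as.integer(org))
  out$n_xo <- n_xo
  out
}

#' Simulate RIL genomes by single-seed descent
#'
#' Starting from the F1 (one LM and one TQ haplotype per chromosome), each
#' line is selfed for `generation - 1` rounds of meiosis with Poisson
#' crossovers and no interference, producing parental-origin tracks and the
#' complete truth set.
#'
#' @param config a [sim_config()] object.
#' @return a `truth_set`: per-RIL per-chromosome genotype segments
#'   (cM and bp coordinates, codes LM/TQ/HET), crossover positions,
#'   the planted QTL list, and meiosis bookkeeping.
#' @export
simulate_ril_genomes <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, 1L))
  n_meioses <- 0L
  n_xo_total <- 0L
  genomes <- vector("list", config$n_ril)
  for (i in seq_len(config$n_ril)) {
    chroms <- vector("list", config$n_chrom)
    for (cc in seq_len(config$n_chrom)) {
      L <- config$chrom_len_cM[cc]
      h1 <- list(bp = numeric(0), org = GENO_LM)
      h2 <- list(bp = numeric(0), org = GENO_TQ)
      for (g in seq_len(config$generation - 1L)) {
        g1 <- .gamete(h1, h2, L)
        g2 <- .gamete(h1, h2, L)
        n_meioses <- n_meioses + 2L
        n_xo_total <- n_xo_total + g1$n_xo + g2$n_xo
        h1 <- g1[c("bp", "org")]
        h2 <- g2[c("bp", "org")]
      }
      cuts <- sort(unique(c(h1$bp, h2$bp)))
      mids <- if (length(cuts)) (c(0, cuts) + c(cuts, L)) / 2 else L / 2
      o1 <- .hap_at(h1, mids)
      o2 <- .hap_at(h2, mids)
      geno <- ifelse(o1 == o2, o1, GENO_HET)
      seg <- .hap_compress(cuts, as.integer(geno))
      bp_per_cM <- config$chrom_len_bp[cc] / L
      start_cM <- c(0, seg$bp)
      end_cM <- c(seg$bp, L)
      chroms[[cc]] <- data.frame(
        start_cM = start_cM, end_cM = end_cM,
        start_bp = round(start_cM * bp_per_cM),
        end_bp = round(end_cM * bp_per_cM),
        geno = seg$org)
    }
    genomes[[i]] <- chroms
  }
  structure(list(config = config, genomes = genomes,
                 planted_qtls = config$qtl_spec,
                 n_meioses = n_meioses, n_crossovers = n_xo_total),
            class = "truth_set")
}

#' True parental genotype at arbitrary positions
#'
#' @param truth a truth set from [simulate_ril_genomes()].
#' @param ril RIL index.
#' @param chrom chromosome index.
#' @param pos positions (bp by default, cM if `unit = "cM"`).
#' @param unit `"bp"` or `"cM"`.
#' @return integer genotype codes (1 = LM, 2 = TQ, 3 = HET).
#' @export
truth_genotype_at <- function(truth, ril, chrom, pos, unit = c("bp", "cM")) {
  unit <- match.arg(unit)
  seg <- truth$genomes[[ril]][[chrom]]
  breaks <- if (unit == "bp") seg$end_bp else seg$end_cM
  idx <- findInterval(pos, breaks[-length(breaks)]) + 1L
  seg$geno[idx]
}

#' Per-RIL heterozygous genome fraction from the truth tracks
#' @param truth a truth set.
#' @return numeric vector, one cM-weighted HET fraction per RIL.
#' @export
truth_het_fraction <- function(truth) {
  vapply(truth$genomes, function(chroms) {
    len <- het <- 0
    for (seg in chroms) {
      w <- seg$end_cM - seg$start_cM
      len <- len + sum(w)
      het <- het + sum(w[seg$geno == GENO_HET])
    }
    het / len
  }, numeric(1))
}

#' Simulate low-coverage SNP observations
#'
#' SNP sites are placed uniformly along each chromosome; parents are opposite
#' homozygotes at every site (the post-filter SNP set is parent-divergent by
#' construction).  Per RIL per site, depth ~ Poisson(mean_depth); zero-depth
#' sites are missing; covered sites report the true parental allele, flipped
#' with probability `genotyping_error` (a true HET site reports either allele
#' with equal probability).  Parents are observed at high depth, error-free.
#'
#' @param truth a truth set from [simulate_ril_genomes()].
#' @param config the same [sim_config()].
#' @return a `snp_table`: `sites` data frame (chrom, pos, alleles, parental
#'   depths), `calls` and `depth` matrices (sites x RILs), `ril_ids`.
#' @export
simulate_snp_observations <- function(truth, config = truth$config) {
  set.seed(substream_seed(config$seed, 2L))
  bases <- c("A", "C", "G", "T")
  sites_list <- vector("list", config$n_chrom)
  for (cc in seq_len(config$n_chrom)) {
    pos <- sort(sample.int(config$chrom_len_bp[cc], config$n_snp_per_chrom))
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    sites_list[[cc]] <- data.frame(
      chrom = cc, pos = pos, parent1_allele = ref, parent2_allele = alt,
      parent1_depth = pmax(stats::rpois(length(pos), 60), 10L),
      parent2_depth = pmax(stats::rpois(length(pos), 60), 10L),
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites_list)
  rownames(sites) <- NULL
  n_site <- nrow(sites)
  n_ril <- config$n_ril
  calls <- matrix(NA_integer_, n_site, n_ril)
  depth <- matrix(0L, n_site, n_ril)
  for (i in seq_len(n_ril)) {
    truegeno <- integer(n_site)
    for (cc in seq_len(config$n_chrom)) {
      sel <- sites$chrom == cc
      truegeno[sel] <- truth_genotype_at(truth, i, cc, sites$pos[sel])
    }
    d <- stats::rpois(n_site, config$mean_depth)
    obs <- truegeno
    het <- obs == GENO_HET
    if (any(het))
      obs[het] <- sample(c(GENO_LM, GENO_TQ), sum(het), replace = TRUE)
    if (config$genotyping_error > 0) {
      flip <- stats::runif(n_site) < config$genotyping_error
      obs[flip] <- 3L - obs[flip]
    }
    obs[d == 0L] <- NA_integer_
    calls[, i] <- obs
    depth[, i] <- d
  }
  ril_ids <- sprintf("RIL%03d", seq_len(n_ril))
  colnames(calls) <- colnames(depth) <- ril_ids
  new_snp_table(sites, calls, depth, ril_ids)
}

new_snp_table <- function(sites, calls, depth, ril_ids) {
  stopifnot(nrow(sites) == nrow(calls))
  structure(list(sites = sites, calls = calls, depth = depth,
                 ril_ids = ril_ids),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat("snp_table:", nrow(x$sites), "sites x", length(x$ril_ids), "RILs,",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Simulate multi-environment element phenotypes
#'
#' For environment e and element j,
#' \deqn{y = \sum_q a_{qj} x_q + \mu_{ej} + \epsilon,}
#' with \eqn{x_q \in \{-1, +1\}} the parental genotype at planted QTL q
#' (HET contributes 0; negligible at F_20), \eqn{a_{qj}} the additive effect
#' in residual-SD units (active only in the QTL's environments), \eqn{\mu_{ej}}
#' a per-environment mean shift, and \eqn{\epsilon} multivariate normal with
#' unit variances and correlation `element_corr_noise`.  With this scaling a
#' single QTL's theoretical PVE is \eqn{a^2 / (a^2 + \sigma^2_{rest})}.
#'
#' @param truth a truth set.
#' @param config the same [sim_config()].
#' @return list with `tables` (named list of per-environment data frames,
#'   `ril_id` + one column per element) and `realized_pve` (per QTL, element,
#'   environment: theoretical and realized percent variance explained).
#' @export
simulate_phenotypes <- function(truth, config = truth$config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, 3L))
  n_ril <- config$n_ril
  n_el <- length(config$elements)
  ril_ids <- sprintf("RIL%03d", seq_len(n_ril))
  qtls <- config$qtl_spec
  # genotype scores x in {-1, +1, 0=HET} at each planted QTL
  xs <- lapply(qtls, function(q) {
    pos_bp <- q$position_cM / config$chrom_len_cM[q$chrom] *
      config$chrom_len_bp[q$chrom]
    g <- vapply(seq_len(n_ril), function(i)
      truth_genotype_at(truth, i, q$chrom, pos_bp), integer(1))
    ifelse(g == GENO_TQ, 1, ifelse(g == GENO_LM, -1, 0))
  })
  mu <- matrix(stats::rnorm(config$n_env * n_el, 0, config$env_effect_sd),
               config$n_env, n_el)
  tables <- vector("list", config$n_env)
  pve_rows <- list()
  for (e in seq_len(config$n_env)) {
    eps <- MASS::mvrnorm(n_ril, mu = rep(0, n_el),
                         Sigma = config$element_corr_noise)
    Y <- sweep(eps, 2L, -mu[e, ])
    gvar <- numeric(n_el)  # total additive variance per element in this env
    active <- vapply(qtls, function(q)
      is.null(q$environments) || e %in% q$environments, logical(1))
    for (k in seq_along(qtls)) {
      if (!active[k]) next
      q <- qtls[[k]]
      j <- match(q$affected_elements, config$elements)
      Y[, j] <- Y[, j] + outer(xs[[k]], q$additive_effects)
      gvar[j] <- gvar[j] + q$additive_effects^2
    }
    for (k in seq_along(qtls)) {
      if (!active[k]) next
      q <- qtls[[k]]
      for (m in seq_along(q$affected_elements)) {
        j <- match(q$affected_elements[m], config$elements)
        a2 <- q$additive_effects[m]^2
        pve_theory <- 100 * a2 / (gvar[j] + 1)
        fit <- stats::lm.fit(cbind(1, xs[[k]]), Y[, j])
        pve_real <- 100 * (1 - sum(fit$residuals^2) /
                             sum((Y[, j] - mean(Y[, j]))^2))
        pve_rows[[length(pve_rows) + 1L]] <- data.frame(
          qtl = k, element = q$affected_elements[m], env = e,
          additive_effect = q$additive_effects[m],
          pve_theory = pve_theory, pve_realized = pve_real)
      }
    }
    tab <- data.frame(ril_id = ril_ids, Y)
    names(tab) <- c("ril_id", config$elements)
    tables[[e]] <- tab
  }
  names(tables) <- sprintf("env%d", seq_len(config$n_env))
  realized <- if (length(pve_rows)) do.call(rbind, pve_rows) else
    data.frame(qtl = integer(0), element = character(0), env = integer(0),
               additive_effect = numeric(0), pve_theory = numeric(0),
               pve_realized = numeric(0))
  list(tables = tables, realized_pve = realized)
}

#' Write a simulated fixture to disk
#'
#' Emits a VCF 4.2 (two parents + RILs, GT and DP), one phenotype CSV per
#' environment (`ril_id,<element>,...`), and a truth-set JSON.  Output is
#' byte-stable for a given seed.
#'
#' @param truth truth set.
#' @param observations `snp_table` from [simulate_snp_observations()].
#' @param phenotypes result of [simulate_phenotypes()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(truth, observations, phenotypes, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(outdir, "genotypes.vcf"),
             truth = file.path(outdir, "truth.json"))
  write_vcf(observations, paths[["vcf"]],
            chrom_len_bp = truth$config$chrom_len_bp)
  for (e in names(phenotypes$tables)) {
    p <- file.path(outdir, paste0("phenotype_", e, ".csv"))
    utils::write.csv(phenotypes$tables[[e]], p, row.names = FALSE)
    paths[[paste0("pheno_", e)]] <- p
  }
  write_truth_json(truth, paths[["truth"]])
  invisible(paths)
}

#' Serialize a truth set to JSON
#' @param truth truth set.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  cfg <- unclass(truth$config)
  cfg$qtl_spec <- lapply(cfg$qtl_spec, unclass)
  obj <- list(config = cfg,
              genomes = truth$genomes,
              n_meioses = truth$n_meioses,
              n_crossovers = truth$n_crossovers)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a truth set back from JSON
#' @param path file written by [write_truth_json()].
#' @return a `truth_set`.
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- obj$config
  qtls <- lapply(cfg$qtl_spec, function(q)
    planted_qtl(q$chrom, q$position_cM, q$affected_elements,
                q$additive_effects, q$environments))
  cfg <- sim_config(n_ril = cfg$n_ril, n_chrom = cfg$n_chrom,
                    chrom_len_bp = cfg$chrom_len_bp,
                    chrom_len_cM = cfg$chrom_len_cM,
                    n_snp_per_chrom = cfg$n_snp_per_chrom,
                    generation = cfg$generation, mean_depth = cfg$mean_depth,
                    genotyping_error = cfg$genotyping_error,
                    n_env = cfg$n_env, elements = cfg$elements,
                    qtl_spec = qtls,
                    element_corr_noise = cfg$element_corr_noise,
                    env_effect_sd = cfg$env_effect_sd, seed = cfg$seed)
  genomes <- lapply(obj$genomes, function(chroms)
    lapply(chroms, function(seg) as.data.frame(seg)))
  structure(list(config = cfg, genomes = genomes,
                 planted_qtls = cfg$qtl_spec,
                 n_meioses = obj$n_meioses, n_crossovers = obj$n_crossovers),
            class = "truth_set")
}
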