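#' Marker matrix taken directly from a simulation truth set
#'
#' Places `n_markers` equally spaced markers per chromosome and reads each
#' RIL's true parental genotype at them, bypassing the sequencing and
#' window-calling layers.  Used to study the mapping stages in isolation
#' from genotyping noise.
#'
#' @param truth a truth set from [simulate_ril_genomes()].
#' @param n_markers markers per chromosome (default 151).
#' @return a `bin_matrix` whose bins are the markers' surrounding intervals.
#' @export
truth_bin_matrix <- function(truth, n_markers = 151L) {
  cfg <- truth$config
  bins_list <- geno_list <- list()
  for (cc in seq_len(cfg$n_chrom)) {
    L_bp <- cfg$chrom_len_bp[cc]
    pos_cM <- seq(0, cfg$chrom_len_cM[cc], length.out = n_markers)
    pos_bp <- pos_cM / cfg$chrom_len_cM[cc] * L_bp
    cuts <- (pos_bp[-1] + pos_bp[-n_markers]) / 2
    G <- vapply(seq_len(cfg$n_ril), function(i)
      truth_genotype_at(truth, i, cc, pos_bp), integer(n_markers))
    bins_list[[cc]] <- data.frame(chrom = cc,
                                  start_bp = c(0, cuts),
                                  end_bp = c(cuts, L_bp))
    geno_list[[cc]] <- G
  }
  geno <- do.call(rbind, geno_list)
  ril_ids <- sprintf("RIL%03d", seq_len(cfg$n_ril))
  colnames(geno) <- ril_ids
  new_bin_matrix(do.call(rbind, bins_list), geno, ril_ids)
}

#' Scan one trait: curve, permutation threshold, peaks
#'
#' Convenience wrapper chaining [hk_scan()], [permute_threshold()] and
#' [find_peaks()].
#'
#' @inheritParams hk_scan
#' @inheritParams permute_threshold
#' @inheritParams find_peaks
#' @return list `curve`, `perm`, `peaks`.
#' @export
scan_trait <- function(probs, trait, trait_id = "trait", n_perm = 1000L,
                       alpha = 0.05, seed = 1L, min_sep_cM = 10.0,
                       lod_drop = 1.5, map = NULL) {
  curve <- hk_scan(probs, trait, trait_id = trait_id)
  perm <- permute_threshold(probs, trait, n_perm = n_perm, alpha = alpha,
                            seed = seed)
  peaks <- find_peaks(curve, perm, min_sep_cM = min_sep_cM,
                      lod_drop = lod_drop, map = map)
  list(curve = curve, perm = perm, peaks = peaks)
}

#' Pipeline configuration
#'
#' @param vcf path to the genotype VCF.
#' @param phenotypes named list: environment label -> phenotype CSV path or
#'   data frame (`ril_id` + element columns).
#' @param outdir output directory.
#' @param env_sets named list of environment-label vectors for
#'   across-environment PCA / aPC scans (e.g. `list(F = c(...), U = c(...))`);
#'   sets of fewer than 2 present environments are skipped with a message.
#' @param ls_mean_sets named list of environment sets for LS-mean traits.
#' @param seed global seed; every stage derives its own sub-stream from it.
#' @param n_perm permutations per trait (default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param window,majority window-calling parameters.
#' @param min_bin_bp,exempt_chroms bin-map filter parameters.
#' @param map_function `"kosambi"` or `"haldane"`.
#' @param step_cM scan grid step.
#' @param min_sep_cM,lod_drop peak parameters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, phenotypes, outdir,
                            env_sets = list(), ls_mean_sets = list(),
                            seed = 1L, n_perm = 1000L, alpha = 0.05,
                            window = 15L, majority = 11L,
                            min_bin_bp = 20000L, exempt_chroms = 4L,
                            map_function = "kosambi", step_cM = 1.0,
                            min_sep_cM = 10.0, lod_drop = 1.5) {
  if (anyDuplicated(names(phenotypes)))
    stop("environment labels must be unique")
  structure(list(vcf = vcf, phenotypes = phenotypes, outdir = outdir,
                 env_sets = env_sets, ls_mean_sets = ls_mean_sets,
                 seed = as.integer(seed), n_perm = as.integer(n_perm),
                 alpha = alpha, window = as.integer(window),
                 majority = as.integer(majority),
                 min_bin_bp = as.integer(min_bin_bp),
                 exempt_chroms = exempt_chroms,
                 map_function = map_function, step_cM = step_cM,
                 min_sep_cM = min_sep_cM, lod_drop = lod_drop),
            class = "pipeline_config")
}

.load_pheno <- function(x) {
  if (is.character(x)) utils::read.csv(x, check.names = FALSE) else x
}

#' Run the full ionomic QTL pipeline
#'
#' Chains SNP filtering, window genotype calling, bin-map and linkage-map
#' construction, phenotype statistics and PCA, univariate elemental scans,
#' LS-mean trait scans, PC-score scans per environment, aPC-score scans per
#' environment set, and QTL co-localization/cluster detection.  All tables
#' are written under `config$outdir` together with a manifest (parameters,
#' seed, file checksums); a rerun with the same config and seed reproduces
#' every output byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every intermediate object and the peak /
#'   cluster tables.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  params <- window_call_params(window_snps = config$window,
                               majority_threshold = config$majority)

  snps <- stage("read_vcf", read_vcf(config$vcf))
  snps <- stage("filter_snps", filter_snps(snps))

  span <- stage("span", {
    do.call(rbind, lapply(unique(snps$sites$chrom), function(cc) {
      p <- snps$sites$pos[snps$sites$chrom == cc]
      data.frame(chrom = cc, start_bp = min(p), end_bp = max(p))
    }))
  })
  blocks <- stage("window_calling", lapply(seq_along(snps$ril_ids),
    function(i) call_blocks(call_windows(snps, i, params), span = span)))
  bins <- stage("bin_map", build_bin_map(blocks,
                                         min_bin_bp = config$min_bin_bp,
                                         exempt_chroms = config$exempt_chroms,
                                         ril_ids = snps$ril_ids))
  lmap <- stage("linkage_map",
                build_linkage_map(bins, map_function = config$map_function))
  probs <- stage("genotype_probs",
                 genotype_probs(bins, lmap, step_cM = config$step_cM))

  tables <- stage("phenotypes", lapply(config$phenotypes, .load_pheno))
  stats_rep <- stage("phenotype_stats", {
    stacked <- do.call(rbind, lapply(names(tables), function(e)
      cbind(env = e, tables[[e]])))
    phenotype_stats(stacked)
  })

  trait_seed <- function(k) substream_seed(config$seed, 100L + k)
  scan1 <- function(trait, trait_id, k)
    scan_trait(probs, trait, trait_id = trait_id, n_perm = config$n_perm,
               alpha = config$alpha, seed = trait_seed(k),
               min_sep_cM = config$min_sep_cM, lod_drop = config$lod_drop,
               map = lmap)

  records <- empty_qtl_records()
  k <- 0L
  # elemental scans per environment
  for (e in names(tables)) {
    tab <- tables[[e]]
    for (el in setdiff(names(tab), c("ril_id", "env"))) {
      k <- k + 1L
      trait <- stats::setNames(tab[[el]], tab$ril_id)
      res <- scan1(trait, el, k)
      if (nrow(res$peaks))
        records <- rbind(records, qtl_records(res$peaks, "elemental",
                                              env = e, element = el))
    }
  }
  # LS-mean traits
  for (s in names(config$ls_mean_sets)) {
    envs <- intersect(config$ls_mean_sets[[s]], names(tables))
    if (length(envs) < 2L) {
      message("LS-mean set ", s, ": fewer than 2 environments; skipped")
      next
    }
    lsm <- stage("ls_means", ls_means(tables, envs))
    for (el in setdiff(names(lsm), "ril_id")) {
      k <- k + 1L
      trait <- stats::setNames(lsm[[el]], lsm$ril_id)
      res <- scan1(trait, el, k)
      if (nrow(res$peaks))
        records <- rbind(records, qtl_records(res$peaks, "elemental",
                                              env = paste0(s, "_mean"),
                                              element = el))
    }
  }
  # PC-score scans within each environment
  pca_models <- list()
  for (e in names(tables)) {
    model <- stage("pca_within", pca_within(tables[[e]], scope = e))
    pca_models[[e]] <- model
    for (pc in seq_len(ncol(model$scores))) {
      if (model$var_fraction[pc] == 0) next
      k <- k + 1L
      trait <- stats::setNames(model$scores[, pc], model$rows$ril_id)
      res <- scan1(trait, sprintf("%s_PC%d", e, pc), k)
      if (nrow(res$peaks))
        records <- rbind(records, qtl_records(
          res$peaks, "PC", env = e,
          top5 = top_loading_elements(model, pc)$element))
    }
  }
  # aPC-score scans per environment set
  apc_models <- list()
  for (s in names(config$env_sets)) {
    envs <- intersect(config$env_sets[[s]], names(tables))
    if (length(envs) < 2L) {
      message("environment set ", s,
              ": fewer than 2 environments present; aPC scans skipped")
      next
    }
    model <- stage("pca_across", pca_across(tables, envs, scope = s))
    apc_models[[s]] <- model
    traits <- apc_score_traits(model)
    for (tn in names(traits)) {
      pc <- as.integer(sub(".*_aPC", "", tn))
      if (model$var_fraction[pc] == 0) next
      k <- k + 1L
      res <- scan1(traits[[tn]], tn, k)
      if (nrow(res$peaks))
        records <- rbind(records, qtl_records(
          res$peaks, "aPC", env = sub("_aPC.*", "", sub("^[^_]*_", "", tn)),
          top5 = top_loading_elements(model, pc)$element))
    }
  }

  records <- .assign_ids(records)
  unique_elemental <- stage("merge_unique", merge_unique(records))
  overlap <- if (length(unique(records$qtl_class)) >= 2L)
    stage("overlap_classes", overlap_classes(records)) else NULL
  clusters <- stage("find_clusters", find_clusters(records))
  concord <- stage("concordance", concordance_top5(records))

  # ---- outputs + manifest --------------------------------------------------
  paths <- c(bins = file.path(config$outdir, "bins.csv"),
             map = file.path(config$outdir, "linkage_map.csv"),
             qtl = file.path(config$outdir, "qtl_records.csv"),
             unique_qtl = file.path(config$outdir, "unique_elemental_qtl.csv"),
             clusters = file.path(config$outdir, "clusters.json"))
  write_bin_csv(bins, paths[["bins"]])
  utils::write.csv(as.data.frame(lmap), paths[["map"]], row.names = FALSE)
  utils::write.csv(records, paths[["qtl"]], row.names = FALSE)
  utils::write.csv(unique_elemental, paths[["unique_qtl"]], row.names = FALSE)
  jsonlite::write_json(lapply(clusters, function(cl)
    list(cluster_id = cl$cluster_id, lg = cl$lg, lo_cM = cl$lo_cM,
         hi_cM = cl$hi_cM, concordant = cl$concordant,
         members = cl$members)),
    paths[["clusters"]], digits = NA, auto_unbox = TRUE,
    dataframe = "columns")
  manifest <- list(
    package = "ionqtl",
    version = as.character(utils::packageVersion("ionqtl")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("vcf", "phenotypes", "outdir"))],
    n_bins = nrow(bins$bins),
    total_map_cM = attr(lmap, "total_cM"),
    n_qtl_records = nrow(records),
    n_clusters = length(clusters),
    checksums = as.list(stats::setNames(unname(tools::md5sum(unname(paths))),
                                        names(paths))))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE)
  invisible(list(snps = snps, bins = bins, linkage_map = lmap,
                 probs = probs, stats = stats_rep, pca_models = pca_models,
                 apc_models = apc_models, records = records,
                 unique_elemental = unique_elemental, overlap = overlap,
                 clusters = clusters, concordance = concord,
                 manifest = manifest, paths = c(paths,
                                                manifest = manifest_path)))
}
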