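# small fully observed marker panel + map + probs, shared across tests
scan_fixture <- function(seed = 91, n_ril = 80, n_markers = 21,
                         chrom_len_cM = 100) {
  cfg <- sim_config(n_ril = n_ril, n_chrom = 1, chrom_len_bp = 5e6,
                    chrom_len_cM = chrom_len_cM, n_snp_per_chrom = 10,
                    elements = c("Ca", "Sr"), seed = seed)
  truth <- simulate_ril_genomes(cfg)
  bm <- truth_bin_matrix(truth, n_markers = n_markers)
  lm_ <- build_linkage_map(bm, "kosambi")
  list(truth = truth, bm = bm, map = lm_,
       probs = genotype_probs(bm, lm_))
}

test_that("conditional genotype probabilities honor observed markers", {
  fx <- scan_fixture()
  probs <- fx$probs
  lgp <- probs$lgs[[1]]
  mpos <- fx$map$pos_cM
  pt_idx <- match(mpos, lgp$points)
  for (k in c(1, 5, 10, length(mpos))) {
    g <- fx$bm$geno[fx$map$bin[k], ]
    p <- lgp$P[, pt_idx[k]]
    expect_equal(unname(p[g == GENO_TQ]),
                 rep(1, sum(g == GENO_TQ)), tolerance = 1e-6)
    expect_equal(unname(p[g == GENO_LM]),
                 rep(0, sum(g == GENO_LM)), tolerance = 1e-6)
  }
  expect_true(all(lgp$P >= 0 & lgp$P <= 1))
})

test_that("midpoint probability between two like markers matches the 3-point chain", {
  # two markers 2 cM apart, both LM; closed form for the midpoint:
  # P(TQ) = R^2 / ((1-R)^2 + R^2) with R the 1-cM RIL-level step
  g <- matrix(GENO_LM, 2, 6)
  bm <- manual_bin_matrix(g)
  map <- build_linkage_map(bm, "kosambi")
  map$pos_cM <- c(0, 2)  # impose the 2 cM spacing
  probs <- genotype_probs(bm, map, step_cM = 1)
  lgp <- probs$lgs[[1]]
  mid <- which(lgp$points == 1)
  R <- ril_expand(inverse_map_distance(1, "kosambi"))
  # exhaustive enumeration over the hidden state at the midpoint
  p_exp <- R^2 / ((1 - R)^2 + R^2)
  expect_equal(unname(lgp$P[, mid]), rep(p_exp, 6), tolerance = 1e-9)
  expect_lt(p_exp, 0.01)
  # an all-missing RIL sits at the uninformative prior everywhere
  g2 <- g; g2[, 6] <- NA_integer_
  bm2 <- manual_bin_matrix(g2)
  probs2 <- genotype_probs(bm2, map)
  expect_equal(unname(probs2$lgs[[1]]$P[6, ]),
               rep(0.5, length(probs2$lgs[[1]]$points)))
})

test_that("HK LOD equals the closed-form marker regression at marker loci", {
  set.seed(5)
  for (seed in c(101, 102, 103, 104, 105)) {
    fx <- scan_fixture(seed = seed, n_ril = 60)
    x5 <- ifelse(fx$bm$geno[fx$map$bin[8], ] == GENO_TQ, 1, -1)
    y <- 0.6 * x5 + rnorm(60)
    names(y) <- fx$bm$ril_ids
    curve <- hk_scan(fx$probs, y)
    idx <- match(fx$map$pos_cM, curve$pos_cM)
    for (k in seq_along(idx)) {
      x <- ifelse(fx$bm$geno[fx$map$bin[k], ] == GENO_TQ, 1, -1)
      expect_equal(curve$lod[idx[k]], marker_lod_oracle(x, y),
                   tolerance = 1e-8)
    }
    expect_true(all(curve$lod >= 0))
  }
})

test_that("imputation scan degenerates to HK under full observation and is seeded", {
  fx <- scan_fixture(seed = 106, n_ril = 50)
  set.seed(2)
  y <- rnorm(50) + ifelse(fx$bm$geno[fx$map$bin[10], ] == GENO_TQ, 0.8, -0.8)
  names(y) <- fx$bm$ril_ids
  hk <- hk_scan(fx$probs, y)
  im <- imputation_scan(fx$probs, y, n_imputations = 8, seed = 3)
  idx <- match(fx$map$pos_cM, hk$pos_cM)
  expect_equal(im$lod[idx], hk$lod[idx], tolerance = 1e-8)
  im2 <- imputation_scan(fx$probs, y, n_imputations = 8, seed = 3)
  expect_identical(im$lod, im2$lod)
})

test_that("imputation and HK agree on sparse panels", {
  fix <- sim_bin_map(small_cfg(seed = 107, n_ril = 60, n_snp = 700))
  lm_ <- build_linkage_map(fix$bins)
  probs <- genotype_probs(fix$bins, lm_)
  set.seed(4)
  g <- ifelse(fix$bins$geno[10, ] == GENO_TQ, 1,
              ifelse(fix$bins$geno[10, ] == GENO_LM, -1, 0))
  y <- 0.7 * g + rnorm(60)
  names(y) <- fix$bins$ril_ids
  hk <- hk_scan(probs, y)
  im <- imputation_scan(probs, y, n_imputations = 64, seed = 9)
  expect_lt(max(abs(hk$lod - im$lod)), 0.5)
})

test_that("permutation thresholds are seeded quantiles of the null maximum", {
  fx <- scan_fixture(seed = 108, n_ril = 60)
  set.seed(6)
  y <- rnorm(60)
  names(y) <- fx$bm$ril_ids
  p1 <- permute_threshold(fx$probs, y, n_perm = 150, seed = 10)
  p2 <- permute_threshold(fx$probs, y, n_perm = 150, seed = 10)
  expect_identical(p1$threshold, p2$threshold)
  expect_gt(p1$threshold, 0)
  # alpha = 1 gives the minimum of the max-LOD distribution
  pmin_ <- permute_threshold(fx$probs, y, n_perm = 150, alpha = 1, seed = 10)
  expect_equal(pmin_$threshold, min(p1$max_lods))
  # a pure-noise trait rarely clears its own threshold
  expect_lt(min(p1$max_lods), p1$threshold)
  expect_warning(permute_threshold(fx$probs, y, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("peak finding merges close maxima and reports 1.5-LOD support", {
  pos <- 0:100
  lod <- pmax(0, 5 - 0.3 * abs(pos - 40))
  lod[pos == 44] <- 4.2  # secondary local maximum 4 cM from the main peak
  curve <- structure(data.frame(lg = 1L, pos_cM = pos, lod = lod,
                                slope = 0.5),
                     class = c("lod_curve", "data.frame"),
                     trait = "toy", n_used = 250L)
  pk <- find_peaks(curve, threshold = 3, min_sep_cM = 10)
  expect_equal(nrow(pk), 1L)  # the 4-cM-apart maxima merge into the higher
  expect_equal(pk$peak_cM, 40)
  # support interval: contiguous region with LOD >= peak - 1.5 (3.5)
  expect_equal(c(pk$ci_lo_cM, pk$ci_hi_cM), c(35, 45))
  # flat curve below threshold -> nothing
  curve0 <- structure(data.frame(lg = 1L, pos_cM = pos, lod = 0.2,
                                 slope = 0),
                      class = c("lod_curve", "data.frame"),
                      trait = "toy", n_used = 250L)
  expect_equal(nrow(find_peaks(curve0, threshold = 3)), 0L)
  # PVE-LOD identity
  expect_equal(pve_from_lod(3, 250), 100 * (1 - 10^(-6 / 250)))
  expect_equal(pve_from_lod(3, 250), 5.38, tolerance = 0.005)
  pv <- seq(1, 60, by = 3.7)
  expect_equal(pve_from_lod(lod_from_pve(pv, 250), 250), pv,
               tolerance = 1e-12)
})

test_that("LS means equal per-RIL means when balanced, normal equations otherwise", {
  set.seed(8)
  rils <- sprintf("RIL%03d", 1:20)
  mk <- function(shift) data.frame(ril_id = rils, Ca = rnorm(20) + shift,
                                   Sr = rnorm(20) - shift)
  tabs <- list(e1 = mk(1), e2 = mk(-2), e3 = mk(0.5))
  lsm <- ls_means(tabs)
  bal <- rowMeans(cbind(tabs$e1$Ca, tabs$e2$Ca, tabs$e3$Ca))
  expect_equal(lsm$Ca, bal, tolerance = 1e-10)
  # single environment: identity
  one <- ls_means(tabs, "e2")
  expect_equal(one$Ca, tabs$e2$Ca)
  # unbalanced: independent normal-equations oracle with sum-coded envs
  tabs$e3 <- tabs$e3[1:12, ]
  lsu <- ls_means(tabs)
  stacked <- do.call(rbind, lapply(names(tabs), function(e)
    cbind(env = e, tabs[[e]])))
  R <- outer(stacked$ril_id, rils, "==") * 1
  E <- outer(stacked$env, c("e1", "e2", "e3"), "==") * 1
  Es <- E[, 1:2] - E[, 3]  # sum-to-zero coding
  X <- cbind(R, Es)
  beta <- solve(t(X) %*% X, t(X) %*% stacked$Ca)
  expect_equal(lsu$Ca, as.numeric(beta[1:20]), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(lsu$Ca, bal)))  # adjustment matters
})

test_that("scan rejects degenerate traits", {
  fx <- scan_fixture(seed = 109, n_ril = 30)
  y <- rep(1, 30)
  names(y) <- fx$bm$ril_ids
  expect_error(hk_scan(fx$probs, y), "constant")
  y2 <- rnorm(30)
  expect_error(hk_scan(fx$probs, y2[1:10]), "length")
})
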