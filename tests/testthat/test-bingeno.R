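test_that("window rule is exhaustive and matches the majority/HET decisions", {
  params <- window_call_params()
  # every composition with c_tq + c_lm <= 15 maps to exactly one label
  for (ct in 0:15) {
    for (cl in 0:(15 - ct)) {
      lab <- classify_window(ct, cl, params)
      expected <- if (ct > 11) GENO_TQ
      else if (cl > 11) GENO_LM
      else if (ct >= 4 && cl >= 4) GENO_HET
      else NA_integer_
      expect_identical(lab, expected)
    }
  }
  # spotlighted compositions
  expect_identical(classify_window(12L, 3L), GENO_TQ)
  expect_identical(classify_window(0L, 15L), GENO_LM)
  expect_identical(classify_window(8L, 7L), GENO_HET)
})

test_that("snp filters drop close pairs, monomorphic and low-depth sites", {
  calls <- matrix(GENO_LM, 6, 3)
  tab <- manual_snp_table(pos = c(100, 200, 203, 400, 500, 600), calls)
  tab$sites$parent2_allele[4] <- tab$sites$parent1_allele[4]  # monomorphic
  tab$sites$parent1_depth[5] <- 3L                            # low parent depth
  out <- filter_snps(tab)
  expect_equal(out$sites$pos, c(100, 600))
  rm <- attr(out, "removed")
  expect_equal(unname(rm["adjacency"]), 2L)          # 200 & 203 both removed
  expect_equal(unname(rm["parent_not_polymorphic"]), 1L)
  expect_equal(unname(rm["parent_depth"]), 1L)

  # indel adjacency
  out2 <- filter_snps(manual_snp_table(pos = c(100, 600), calls[1:2, ]),
                      indels = data.frame(chrom = 1L, pos = 598L))
  expect_equal(out2$sites$pos, 100)

  # clean table passes through unchanged
  clean <- manual_snp_table(pos = c(100, 600, 1200), calls[1:3, ])
  out3 <- filter_snps(clean)
  expect_equal(out3$sites, clean$sites)
  expect_equal(out3$calls, clean$calls)

  # unsorted input rejected
  bad <- manual_snp_table(pos = c(600, 100), calls[1:2, ])
  expect_error(filter_snps(bad), "sorted")
})

test_that("windows slide over observed calls and anchor at the median SNP", {
  # RIL 1: 20 observed TQ then 20 LM, with missing sites interleaved
  calls <- matrix(NA_integer_, 60, 2)
  obs_idx <- seq(1, 60, by = 3) + 1  # 20 observed sites
  calls[obs_idx[1:10], 1] <- GENO_TQ
  calls[obs_idx[11:20], 1] <- GENO_LM
  calls[, 2] <- rep(c(GENO_TQ, NA), 30)
  tab <- manual_snp_table(pos = seq(1000, by = 1000, length.out = 60), calls)
  w <- call_windows(tab, 1)
  expect_equal(nrow(w), 20 - 15 + 1)
  expect_true(all(w$c_tq + w$c_lm == 15))
  # first window: 10 TQ + 5 LM -> HET zone by composition (neither > 11)
  expect_identical(w$label[1], GENO_HET)
  # anchors are the 8th observed SNP of each window
  expect_equal(w$anchor_bp[1], tab$sites$pos[obs_idx[8]])
  # RIL 2 has 30 observed, all TQ
  w2 <- call_windows(tab, 2)
  expect_true(all(w2$label == GENO_TQ))
  # too few observed calls yields no windows, with a warning
  calls3 <- matrix(NA_integer_, 60, 1)
  calls3[1:5, 1] <- GENO_TQ
  tab3 <- manual_snp_table(pos = seq(1000, by = 1000, length.out = 60), calls3)
  expect_warning(w3 <- call_windows(tab3, 1), "fewer than")
  expect_equal(nrow(w3), 0L)
})

test_that("blocks form from label runs with midpoint breakpoints", {
  # single transition TQ -> LM
  w <- data.frame(chrom = 1L,
                  anchor_bp = seq(1000, by = 100, length.out = 80),
                  c_tq = 0L, c_lm = 0L,
                  label = rep(c(GENO_TQ, GENO_LM), each = 40))
  b <- call_blocks(w)
  expect_equal(nrow(b), 2L)
  expect_equal(b$end_bp[1], (w$anchor_bp[40] + w$anchor_bp[41]) / 2)
  expect_equal(b$geno, c(GENO_TQ, GENO_LM))

  # all one genotype: single block, no breakpoints
  w2 <- transform(w, label = GENO_TQ)
  b2 <- call_blocks(w2)
  expect_equal(nrow(b2), 1L)

  # missing run absorbed when flanks agree, kept when they disagree
  w3 <- transform(w, label = c(rep(GENO_TQ, 30), rep(NA_integer_, 5),
                               rep(GENO_TQ, 45)))
  expect_equal(nrow(call_blocks(w3)), 1L)
  w4 <- transform(w, label = c(rep(GENO_TQ, 30), rep(NA_integer_, 20),
                               rep(GENO_LM, 30)))
  b4 <- call_blocks(w4)
  expect_equal(b4$geno, c(GENO_TQ, NA_integer_, GENO_LM))

  # short HET run between discordant flanks is a crossover transition
  w5 <- transform(w, label = c(rep(GENO_TQ, 36), rep(GENO_HET, 8),
                               rep(GENO_LM, 36)))
  b5 <- call_blocks(w5)
  expect_equal(b5$geno, c(GENO_TQ, GENO_LM))
  # a long HET run is a genuine heterozygous block
  w6 <- transform(w, label = c(rep(GENO_TQ, 20), rep(GENO_HET, 40),
                               rep(GENO_LM, 20)))
  expect_equal(call_blocks(w6)$geno, c(GENO_TQ, GENO_HET, GENO_LM))
})

test_that("bin boundaries are the union of breakpoints and short bins merge", {
  blocks <- list(
    data.frame(chrom = 1L, start_bp = c(0, 1.0e6), end_bp = c(1.0e6, 3e6),
               geno = c(GENO_TQ, GENO_LM)),
    data.frame(chrom = 1L, start_bp = c(0, 1.5e6), end_bp = c(1.5e6, 3e6),
               geno = c(GENO_TQ, GENO_LM)))
  bins <- build_bin_map(blocks)
  expect_equal(nrow(bins$bins), 3L)
  expect_equal(bins$bins$start_bp, c(0, 1.0e6, 1.5e6))
  expect_equal(unname(bins$geno[, 1]), c(GENO_TQ, GENO_LM, GENO_LM))
  expect_equal(unname(bins$geno[, 2]), c(GENO_TQ, GENO_TQ, GENO_LM))

  # sub-20kb bin merges into the less-conflicting neighbor...
  blocks2 <- list(
    data.frame(chrom = 1L, start_bp = c(0, 1.00e6), end_bp = c(1.00e6, 3e6),
               geno = c(GENO_TQ, GENO_LM)),
    data.frame(chrom = 1L, start_bp = c(0, 1.01e6), end_bp = c(1.01e6, 3e6),
               geno = c(GENO_TQ, GENO_LM)))
  bins2 <- build_bin_map(blocks2)
  expect_equal(nrow(bins2$bins), 2L)
  expect_true(all(bins2$bins$end_bp - bins2$bins$start_bp >= 20000))
  # ...but survives on an exempt chromosome
  blocks3 <- lapply(blocks2, function(b) transform(b, chrom = 4L))
  bins3 <- build_bin_map(blocks3, exempt_chroms = 4L)
  expect_equal(nrow(bins3$bins), 3L)

  expect_error(build_bin_map(list()), "empty")
})

test_that("bin partition tiles each chromosome span, disjoint and ordered", {
  fix <- sim_bin_map(small_cfg(seed = 71, n_ril = 30, n_snp = 600))
  b <- fix$bins$bins
  for (cc in unique(b$chrom)) {
    sub <- b[b$chrom == cc, ]
    expect_true(all(diff(sub$start_bp) > 0))
    expect_true(all(sub$end_bp > sub$start_bp))
    expect_equal(sub$start_bp[-1], sub$end_bp[-nrow(sub)])  # no gaps/overlap
    p <- fix$snps$sites$pos[fix$snps$sites$chrom == cc]
    expect_equal(min(sub$start_bp), min(p))
    expect_equal(max(sub$end_bp), max(p))
  }
})

test_that("genotype calling is per-RIL independent (permutation equivariant)", {
  cfg <- small_cfg(seed = 72, n_ril = 12, n_snp = 500)
  fix <- sim_bin_map(cfg)
  perm <- c(4L, 1L, 3L, 2L, 8L, 5L, 6L, 7L, 12L, 9L, 10L, 11L)
  snps_p <- fix$snps
  snps_p$calls <- snps_p$calls[, perm]
  snps_p$depth <- snps_p$depth[, perm]
  span <- do.call(rbind, lapply(unique(snps_p$sites$chrom), function(cc) {
    p <- snps_p$sites$pos[snps_p$sites$chrom == cc]
    data.frame(chrom = cc, start_bp = min(p), end_bp = max(p))
  }))
  blocks_p <- lapply(seq_len(12), function(i)
    call_blocks(call_windows(snps_p, i), span = span))
  bins_p <- build_bin_map(blocks_p, ril_ids = fix$snps$ril_ids[perm])
  expect_equal(bins_p$bins, fix$bins$bins)
  expect_equal(unname(bins_p$geno), unname(fix$bins$geno[, perm]))
})

test_that("heterozygosity is length-weighted with defined edge cases", {
  g <- cbind(c(GENO_LM, GENO_TQ, GENO_LM), c(GENO_HET, GENO_HET, GENO_HET),
             c(NA_integer_, NA_integer_, NA_integer_),
             c(GENO_HET, GENO_LM, NA_integer_))
  bm <- manual_bin_matrix(g)
  bm$bins$end_bp <- c(1e5, 3e5, 6e5)  # lengths 1, 2, 3 (x 1e5)
  bm$bins$start_bp <- c(0, 1e5, 3e5)
  expect_warning(h <- heterozygosity(bm), "no called bins")
  expect_equal(unname(h$per_ril),
               c(0, 1, NA, 1 / 3))  # RIL4: HET 1e5 of 3e5 called
  expect_equal(h$population, mean(c(0, 1, 1 / 3)))

  # high-depth error-free F20 panel: bin-scale heterozygosity near zero
  cfg <- small_cfg(seed = 73, n_ril = 40, n_snp = 800, mean_depth = 30,
                   genotyping_error = 0)
  fix <- sim_bin_map(cfg)
  h20 <- heterozygosity(fix$bins)
  expect_lt(h20$population, 0.005)
})

test_that("bin genotypes recover the truth at high depth", {
  cfg <- small_cfg(seed = 74, n_ril = 50, n_snp = 1500, mean_depth = 30,
                   genotyping_error = 0)
  fix <- sim_bin_map(cfg)
  mids <- (fix$bins$bins$start_bp + fix$bins$bins$end_bp) / 2
  acc <- mean(vapply(seq_len(cfg$n_ril), function(i)
    mean(fix$bins$geno[, i] ==
           truth_genotype_at(fix$truth, i, 1, mids), na.rm = TRUE),
    numeric(1)))
  expect_gt(acc, 0.995)
})
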