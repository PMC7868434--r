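test_that("phenotype statistics: correlations, significance mask, shape", {
  set.seed(11)
  n <- 120
  tab <- data.frame(ril_id = sprintf("RIL%03d", 1:n),
                    Ca = rnorm(n), Cd = rnorm(n))
  tab$Sr <- tab$Ca  # duplicated element
  rep_ <- phenotype_stats(tab)
  expect_equal(rep_$r["Ca", "Sr"], 1.0)
  expect_true(rep_$r_significant["Ca", "Sr"])
  expect_false(rep_$r_significant["Ca", "Cd"])
  expect_true(isSymmetric(rep_$r))
  expect_equal(unname(diag(rep_$r)), rep(1, 3))
  expect_true(all(abs(rep_$r) <= 1))
  # symmetric distribution: skewness ~ 0
  expect_lt(abs(rep_$per_element$skewness[rep_$per_element$element == "Ca"]),
            3 * sqrt(6 / n))
  # replicate rows enable the across-RIL ANOVA
  tab2 <- rbind(cbind(env = "e1", tab), cbind(env = "e2", tab))
  tab2$Ca <- tab2$Ca + rnorm(2 * n, sd = 0.1)
  rep2 <- phenotype_stats(tab2)
  expect_gt(rep2$per_element$anova_F[rep2$per_element$element == "Ca"], 10)
  expect_lt(rep2$per_element$anova_p[rep2$per_element$element == "Ca"], 1e-6)
  # without replicates the ANOVA is flagged NA
  expect_true(is.na(rep_$per_element$anova_F[1]))
})

test_that("simulated shared QTL plus correlated noise yields a strong Ca-Sr r", {
  S <- diag(4)
  S[1, 2] <- S[2, 1] <- 0.6
  cfg <- sim_config(n_ril = 250, n_chrom = 1, chrom_len_bp = 5e6,
                    chrom_len_cM = 100, n_snp_per_chrom = 10,
                    elements = c("Ca", "Sr", "Cd", "Zn"),
                    qtl_spec = list(planted_qtl(1, 50, c("Ca", "Sr"), 0.6)),
                    element_corr_noise = S, seed = 12)
  ph <- simulate_phenotypes(simulate_ril_genomes(cfg), cfg)
  rep_ <- phenotype_stats(ph$tables$env1)
  expect_gt(rep_$r["Ca", "Sr"], 0.6)
  expect_true(rep_$r_significant["Ca", "Sr"])
})

test_that("within-environment PCA conserves variance and reconstructs the data", {
  set.seed(13)
  n <- 100
  tab <- data.frame(ril_id = sprintf("R%03d", 1:n),
                    matrix(rnorm(n * 16), n, dimnames = list(NULL,
                                                             ION_ELEMENTS)))
  m <- pca_within(tab, scope = "toy")
  expect_equal(ncol(m$loadings), 16L)
  expect_equal(sum(m$var_fraction), 1.0, tolerance = 1e-9)
  # orthonormal loadings, uncorrelated scores
  expect_equal(crossprod(m$loadings), diag(16), tolerance = 1e-8,
               ignore_attr = TRUE)
  cv <- crossprod(m$scores) / (n - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])) / max(diag(cv)), 1e-8)
  # reconstruction of the scaled data
  Z <- scale(as.matrix(tab[ION_ELEMENTS]), m$center, m$scale)
  expect_equal(max(abs(Z - m$scores %*% t(m$loadings))), 0, tolerance = 1e-8)
  # independent elements: each PC holds roughly 1/16 of the variance
  expect_lt(max(abs(m$var_fraction - 1 / 16)), 0.06)
  # deterministic sign convention across repeated runs
  m2 <- pca_within(tab[sample(n), ], scope = "toy")
  expect_equal(abs(m$loadings), abs(m2$loadings), tolerance = 1e-8)
  for (k in 1:16) expect_gt(m$loadings[which.max(abs(m$loadings[, k])), k], 0)
})

test_that("a correlated element block dominates one PC with equal loadings", {
  set.seed(14)
  n <- 400
  base <- rnorm(n)
  tab <- data.frame(ril_id = seq_len(n),
                    Ca = base + rnorm(n, sd = 0.2),
                    Sr = base + rnorm(n, sd = 0.2),
                    Cd = rnorm(n), Zn = rnorm(n), Mo = rnorm(n))
  m <- pca_within(tab)
  top2 <- top_loading_elements(m, 1, k = 2)$element
  expect_setequal(top2, c("Ca", "Sr"))
  l <- m$loadings[, 1]
  expect_equal(unname(abs(l["Ca"])), unname(abs(l["Sr"])), tolerance = 0.05)
})

test_that("across-environment PCA stacks rows and regroups scores by environment", {
  set.seed(15)
  n <- 60
  mk <- function() data.frame(ril_id = sprintf("R%02d", 1:n),
                              Ca = rnorm(n), Sr = rnorm(n), Cd = rnorm(n))
  tabs <- list(e1 = mk(), e2 = mk(), e3 = mk())
  m <- pca_across(tabs, c("e1", "e2", "e3"), scope = "F")
  expect_equal(nrow(m$scores), 3L * n)
  # duplication invariance: identical replicated tables give the loadings of one
  dup <- list(a = tabs$e1, b = tabs$e1)
  md <- pca_across(dup, c("a", "b"), scope = "dup")
  m1 <- pca_within(tabs$e1)
  expect_equal(abs(md$loadings), abs(m1$loadings), tolerance = 1e-8)
  # per-environment regrouping bookkeeping
  traits <- apc_score_traits(m)
  expect_length(traits, 3L * 3L)
  expect_true(all(vapply(traits, length, integer(1)) == n))
  expect_named(traits["F_e2_aPC1"])
  # strong environment shifts push PC1 variance above any within-env PC1
  shifted <- list(e1 = tabs$e1,
                  e2 = transform(tabs$e2, Ca = Ca + 6, Sr = Sr + 6,
                                 Cd = Cd - 6))
  ms <- pca_across(shifted, c("e1", "e2"), scope = "S")
  expect_gt(ms$var_fraction[1],
            max(pca_within(tabs$e1)$var_fraction[1],
                pca_within(shifted$e2)$var_fraction[1]))
  # singleton set delegates with a warning
  expect_warning(pca_across(tabs, "e1", scope = "one"), "size 1")
})

test_that("top-loading extraction sorts by |loading| with fixed-order ties", {
  m <- list(loadings = matrix(c(0.9, -0.8, 0.1, 0.05), 4,
                              dimnames = list(c("Ca", "Sr", "Cd", "Zn"),
                                              NULL)))
  m$loadings <- cbind(m$loadings, m$loadings[, 1])
  class(m) <- "pca_model"
  top <- top_loading_elements(m, 1, k = 2)
  expect_equal(top$element, c("Ca", "Sr"))
  expect_equal(top$loading, c(0.9, -0.8))
  # k beyond the element count is clipped to a permutation of all elements
  expect_setequal(top_loading_elements(m, 1, k = 99)$element,
                  c("Ca", "Sr", "Cd", "Zn"))
  # brute-force sort oracle on random vectors
  set.seed(16)
  for (i in 1:10) {
    lo <- round(rnorm(4), 2)
    m$loadings[, 2] <- lo
    got <- top_loading_elements(m, 2, k = 4)$element
    oracle <- rownames(m$loadings)[order(-abs(lo), seq_along(lo))]
    expect_identical(got, oracle)
  }
})

test_that("a pleiotropic QTL surfaces its elements in an early PC's top loadings", {
  S <- diag(6)
  S[1:3, 1:3] <- 0.5; diag(S) <- 1
  cfg <- sim_config(n_ril = 250, n_chrom = 1, chrom_len_bp = 5e6,
                    chrom_len_cM = 100, n_snp_per_chrom = 10,
                    elements = c("Ca", "Sr", "Cd", "Zn", "Mo", "Ni"),
                    qtl_spec = list(planted_qtl(1, 50, c("Ca", "Sr", "Cd"),
                                                0.5)),
                    element_corr_noise = S, seed = 17)
  ph <- simulate_phenotypes(simulate_ril_genomes(cfg), cfg)
  hits <- vapply(1:3, function(pc) {
    top <- top_loading_elements(pca_within(ph$tables$env1), pc, k = 3)
    setequal(top$element, c("Ca", "Sr", "Cd"))
  }, logical(1))
  expect_true(any(hits))
})
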