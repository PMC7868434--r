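#' Conditional genotype probabilities on a cM grid
#'
#' For each linkage group, positions every `step_cM` plus all marker
#' positions form the evaluation points.  Along them a two-state (LM/TQ)
#' Markov chain is run per RIL, with transition probability between adjacent
#' points equal to the RIL-level recombinant fraction implied by the map
#' distance (R = 2r/(1+2r), r from the inverse map function).  HET and
#' missing marker calls are uninformative; P(TQ) conditions on all markers
#' of the group by forward-backward smoothing.
#'
#' @param bin_matrix a `bin_matrix`.
#' @param linkage_map the matching [build_linkage_map()] result.
#' @param step_cM grid step (default 1).
#' @return a `geno_probs` object: per linkage group, evaluation points,
#'   per-RIL P(TQ), and step transition probabilities.
#' @export
genotype_probs <- function(bin_matrix, linkage_map, step_cM = 1.0) {
  if (!nrow(linkage_map)) stop("empty linkage map")
  map_function <- attr(linkage_map, "map_function")
  n_ril <- length(bin_matrix$ril_ids)
  lgs <- list()
  for (g in sort(unique(linkage_map$lg))) {
    sub <- linkage_map[linkage_map$lg == g, , drop = FALSE]
    mpos <- sub$pos_cM
    pts <- sort(unique(c(seq(0, max(mpos), by = step_cM), mpos)))
    m <- length(pts)
    # emission indicators (1 = state allowed) per point per RIL
    eL <- matrix(1, m, n_ril)
    eT <- matrix(1, m, n_ril)
    pt_of_marker <- match(mpos, pts)
    for (k in seq_len(nrow(sub))) {
      gcalls <- bin_matrix$geno[sub$bin[k], ]
      p <- pt_of_marker[k]
      isL <- !is.na(gcalls) & gcalls == GENO_LM
      isT <- !is.na(gcalls) & gcalls == GENO_TQ
      eT[p, isL] <- 0
      eL[p, isT] <- 0
    }
    # conflicting evidence at one point (can arise from bridged map gaps)
    # leaves the RIL uninformative there rather than zero-probability
    conflict <- eL == 0 & eT == 0
    eL[conflict] <- eT[conflict] <- 1
    d <- diff(pts)
    # tiny floor keeps the chain irreducible across zero-cM intervals
    Rstep <- pmax(ril_expand(inverse_map_distance(d, map_function)), 1e-9)
    # forward
    fL <- fT <- matrix(0, m, n_ril)
    aL <- 0.5 * eL[1L, ]
    aT <- 0.5 * eT[1L, ]
    s <- aL + aT
    fL[1L, ] <- aL / s; fT[1L, ] <- aT / s
    for (t in seq_len(m - 1L)) {
      R <- Rstep[t]
      aL <- (fL[t, ] * (1 - R) + fT[t, ] * R) * eL[t + 1L, ]
      aT <- (fL[t, ] * R + fT[t, ] * (1 - R)) * eT[t + 1L, ]
      s <- aL + aT
      fL[t + 1L, ] <- aL / s; fT[t + 1L, ] <- aT / s
    }
    # backward
    bL <- bT <- matrix(0, m, n_ril)
    bL[m, ] <- bT[m, ] <- 1
    for (t in seq(m - 1L, by = -1L, length.out = m - 1L)) {
      R <- Rstep[t]
      nbL <- bL[t + 1L, ] * eL[t + 1L, ]
      nbT <- bT[t + 1L, ] * eT[t + 1L, ]
      bL[t, ] <- (1 - R) * nbL + R * nbT
      bT[t, ] <- R * nbL + (1 - R) * nbT
      s <- bL[t, ] + bT[t, ]
      bL[t, ] <- bL[t, ] / s; bT[t, ] <- bT[t, ] / s
    }
    num <- fT * bT
    P <- num / (fL * bL + num)
    lgs[[as.character(g)]] <- list(lg = g, points = pts, P = t(P),
                                   eL = eL, eT = eT, Rstep = Rstep)
  }
  structure(list(lgs = lgs, ril_ids = bin_matrix$ril_ids,
                 map_function = map_function, step_cM = step_cM),
            class = "geno_probs")
}

.scan_stats <- function(X, y) {
  # single-point regressions of y on each column of X; returns lod and slope
  n <- length(y)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  Xc <- sweep(X, 2L, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, yc))
  ok <- sxx > 1e-12
  slope <- ifelse(ok, sxy / sxx, 0)
  rss1 <- rss0 - ifelse(ok, sxy^2 / sxx, 0)
  rss1 <- pmax(rss1, 1e-300)
  lod <- pmax((n / 2) * log10(rss0 / rss1), 0)
  list(lod = lod, slope = slope, rss0 = rss0, n = n)
}

#' Haley-Knott genome scan
#'
#' At each evaluation point the trait is regressed on the expected genotype
#' score E[x] = 2 P(TQ) - 1; LOD = (n/2) log10(RSS0/RSS1) against the
#' intercept-only model.  RILs with a missing trait value are dropped.
#'
#' @param probs a `geno_probs` object.
#' @param trait numeric trait vector aligned to `probs$ril_ids` (names are
#'   matched if present).
#' @param trait_id label stored on the curve.
#' @return a `lod_curve` data frame (`lg`, `pos_cM`, `lod`, `slope`) with
#'   attributes `trait`, `n_used`.
#' @export
hk_scan <- function(probs, trait, trait_id = "trait") {
  trait <- .align_trait(probs, trait)
  use <- which(!is.na(trait))
  y <- trait[use]
  if (length(use) < 10L) warning("fewer than 10 RILs with trait data")
  if (stats::sd(y) == 0) stop("trait is constant")
  out <- lapply(probs$lgs, function(lgp) {
    X <- 2 * lgp$P[use, , drop = FALSE] - 1
    st <- .scan_stats(X, y)
    data.frame(lg = lgp$lg, pos_cM = lgp$points, lod = st$lod,
               slope = st$slope)
  })
  curve <- do.call(rbind, out)
  rownames(curve) <- NULL
  structure(curve, class = c("lod_curve", "data.frame"),
            trait = trait_id, n_used = length(use))
}

.align_trait <- function(probs, trait) {
  if (!is.null(names(trait))) {
    trait <- trait[match(probs$ril_ids, names(trait))]
  } else if (length(trait) != length(probs$ril_ids)) {
    stop("trait length does not match RIL panel")
  }
  as.numeric(trait)
}

# forward-filter backward-sample genotype realizations for one linkage group
.sample_paths <- function(lgp, n_draw) {
  m <- length(lgp$points)
  n_ril <- ncol(lgp$eL)
  draws <- array(0L, c(n_ril, m, n_draw))
  fL <- fT <- matrix(0, m, n_ril)
  aL <- 0.5 * lgp$eL[1L, ]; aT <- 0.5 * lgp$eT[1L, ]
  s <- aL + aT
  fL[1L, ] <- aL / s; fT[1L, ] <- aT / s
  for (t in seq_len(m - 1L)) {
    R <- lgp$Rstep[t]
    aL <- (fL[t, ] * (1 - R) + fT[t, ] * R) * lgp$eL[t + 1L, ]
    aT <- (fL[t, ] * R + fT[t, ] * (1 - R)) * lgp$eT[t + 1L, ]
    s <- aL + aT
    fL[t + 1L, ] <- aL / s; fT[t + 1L, ] <- aT / s
  }
  for (k in seq_len(n_draw)) {
    st <- matrix(0L, n_ril, m)  # 1 = TQ
    st[, m] <- as.integer(stats::runif(n_ril) < fT[m, ])
    for (t in seq(m - 1L, by = -1L, length.out = m - 1L)) {
      R <- lgp$Rstep[t]
      # P(TQ_t | state_{t+1}) proportional to f_t(TQ) * T(TQ, s_{t+1})
      tr_to_next <- ifelse(st[, t + 1L] == 1L, 1 - R, R)      # from TQ
      tr_from_lm <- ifelse(st[, t + 1L] == 1L, R, 1 - R)      # from LM
      pT <- fT[t, ] * tr_to_next /
        (fT[t, ] * tr_to_next + fL[t, ] * tr_from_lm)
      st[, t] <- as.integer(stats::runif(n_ril) < pT)
    }
    draws[, , k] <- st
  }
  draws
}

#' Multiple-imputation genome scan
#'
#' Draws genotype realizations from the conditional Markov chain, computes
#' a per-imputation single-point regression LOD, and combines imputations by
#' the log-mean-likelihood rule LOD = log10 mean_i 10^LOD_i.  With fully
#' observed markers every draw is identical and the result equals
#' [hk_scan()] at marker positions.
#'
#' @inheritParams hk_scan
#' @param n_imputations number of genotype draws (default 64).
#' @param seed integer seed for the draws.
#' @return a `lod_curve` data frame.
#' @export
imputation_scan <- function(probs, trait, n_imputations = 64L, seed = 1L,
                            trait_id = "trait") {
  trait <- .align_trait(probs, trait)
  use <- which(!is.na(trait))
  y <- trait[use]
  if (stats::sd(y) == 0) stop("trait is constant")
  set.seed(substream_seed(seed, 11L))
  out <- lapply(probs$lgs, function(lgp) {
    draws <- .sample_paths(lgp, n_imputations)
    lods <- matrix(0, length(lgp$points), n_imputations)
    slopes <- matrix(0, length(lgp$points), n_imputations)
    for (k in seq_len(n_imputations)) {
      X <- 2 * draws[use, , k] - 1
      st <- .scan_stats(X, y)
      lods[, k] <- st$lod
      slopes[, k] <- st$slope
    }
    mx <- apply(lods, 1L, max)
    lod <- mx + log10(rowMeans(10^(lods - mx)))
    data.frame(lg = lgp$lg, pos_cM = lgp$points, lod = pmax(lod, 0),
               slope = rowMeans(slopes))
  })
  curve <- do.call(rbind, out)
  rownames(curve) <- NULL
  structure(curve, class = c("lod_curve", "data.frame"),
            trait = trait_id, n_used = length(use))
}

#' Permutation-based genome-wide LOD threshold
#'
#' Permutes the trait across RILs with genotypes fixed, records the
#' genome-wide maximum LOD of each permutation, and returns the empirical
#' (1 - alpha) quantile (type-7 interpolation).
#'
#' @inheritParams hk_scan
#' @param n_perm number of permutations (default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed.
#' @return a `permutation_result`: `threshold`, `max_lods`, `n_perm`,
#'   `alpha`, `seed`.
#' @export
permute_threshold <- function(probs, trait, n_perm = 1000L, alpha = 0.05,
                              seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100: unstable quantile estimate")
  trait <- .align_trait(probs, trait)
  use <- which(!is.na(trait))
  y <- trait[use]
  n <- length(y)
  set.seed(substream_seed(seed, 12L))
  Y <- vapply(seq_len(n_perm), function(k) y[sample.int(n)],
              numeric(n))
  Yc <- sweep(Y, 2L, colMeans(Y))
  rss0 <- colSums(Yc^2)
  maxlod <- rep(0, n_perm)
  for (lgp in probs$lgs) {
    X <- 2 * lgp$P[use, , drop = FALSE] - 1
    Xc <- sweep(X, 2L, colMeans(X))
    sxx <- colSums(Xc^2)
    num <- crossprod(Xc, Yc)              # points x perms
    ok <- sxx > 1e-12
    num[!ok, ] <- 0
    rss1 <- sweep(-(num^2 / ifelse(ok, sxx, 1)), 2L, -rss0)
    rss1 <- pmax(rss1, 1e-300)
    lod <- (n / 2) * log10(sweep(1 / rss1, 2L, rss0, `*`))
    maxlod <- pmax(maxlod, apply(lod, 2L, max))
  }
  structure(list(threshold = as.numeric(
    stats::quantile(maxlod, 1 - alpha, type = 7)),
    max_lods = maxlod, n_perm = n_perm, alpha = alpha, seed = seed),
    class = "permutation_result")
}

#' Percent variance explained from a LOD score
#' @param lod LOD score(s).
#' @param n sample size.
#' @return PVE in percent: \eqn{100 (1 - 10^{-2\,\mathrm{LOD}/n})}.
#' @export
pve_from_lod <- function(lod, n) 100 * (1 - 10^(-2 * lod / n))

#' LOD score corresponding to a given PVE
#' @param pve percent variance explained.
#' @param n sample size.
#' @export
lod_from_pve <- function(pve, n) -(n / 2) * log10(1 - pve / 100)

#' Find significant QTL peaks on a LOD curve
#'
#' Local maxima with LOD >= threshold are reported; maxima closer than
#' `min_sep_cM` on the same linkage group are merged keeping the higher.
#' The support interval is the contiguous region around the peak where LOD
#' stays within `lod_drop` of the peak.  PVE uses the PVE-LOD identity;
#' the additive effect is the fitted slope at the peak (positive = TQ
#' allele increases the trait).
#'
#' @param curve a `lod_curve`.
#' @param threshold LOD significance threshold (scalar or
#'   `permutation_result`).
#' @param min_sep_cM minimum separation between reported peaks (default 10).
#' @param lod_drop support-interval drop (default 1.5).
#' @param map optional `linkage_map` for physical-interval anchoring.
#' @return data frame of peaks: `trait`, `lg`, `peak_cM`, `lod`,
#'   `threshold`, `ci_lo_cM`, `ci_hi_cM`, `pve_pct`, `add_effect` and, with
#'   `map`, `phys_lo_bp`, `phys_hi_bp`.  Zero rows when nothing exceeds the
#'   threshold.
#' @export
find_peaks <- function(curve, threshold, min_sep_cM = 10.0, lod_drop = 1.5,
                       map = NULL) {
  if (inherits(threshold, "permutation_result")) threshold <- threshold$threshold
  n <- attr(curve, "n_used")
  trait <- attr(curve, "trait")
  rows <- list()
  for (g in unique(curve$lg)) {
    sub <- curve[curve$lg == g, , drop = FALSE]
    sub <- sub[order(sub$pos_cM), , drop = FALSE]
    lod <- sub$lod
    m <- length(lod)
    if (!m) next
    left <- c(-Inf, lod[-m])
    right <- c(lod[-1L], -Inf)
    cand <- which(lod >= threshold & lod >= left & lod >= right)
    if (!length(cand)) next
    cand <- cand[order(-lod[cand])]
    acc <- integer(0)
    for (k in cand) {
      if (!length(acc) ||
          all(abs(sub$pos_cM[k] - sub$pos_cM[acc]) >= min_sep_cM))
        acc <- c(acc, k)
    }
    for (k in sort(acc)) {
      within <- lod >= lod[k] - lod_drop
      lo_i <- k
      while (lo_i > 1L && within[lo_i - 1L]) lo_i <- lo_i - 1L
      hi_i <- k
      while (hi_i < m && within[hi_i + 1L]) hi_i <- hi_i + 1L
      row <- data.frame(trait = trait, lg = g, peak_cM = sub$pos_cM[k],
                        lod = lod[k], threshold = threshold,
                        ci_lo_cM = sub$pos_cM[lo_i],
                        ci_hi_cM = sub$pos_cM[hi_i],
                        pve_pct = pve_from_lod(lod[k], n),
                        add_effect = sub$slope[k])
      if (!is.null(map)) {
        msub <- map[map$lg == g, , drop = FALSE]
        inside <- msub$pos_cM >= row$ci_lo_cM & msub$pos_cM <= row$ci_hi_cM
        if (!any(inside))
          inside <- which.min(abs(msub$pos_cM - row$peak_cM))
        row$phys_lo_bp <- min(msub$start_bp[inside])
        row$phys_hi_bp <- max(msub$end_bp[inside])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    out <- data.frame(trait = character(0), lg = integer(0),
                      peak_cM = numeric(0), lod = numeric(0),
                      threshold = numeric(0), ci_lo_cM = numeric(0),
                      ci_hi_cM = numeric(0), pve_pct = numeric(0),
                      add_effect = numeric(0))
    if (!is.null(map)) {
      out$phys_lo_bp <- numeric(0)
      out$phys_hi_bp <- numeric(0)
    }
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Least-squares adjusted trait means across environments
#'
#' Fits the additive two-way fixed-effects model trait = RIL + environment
#' by least squares (environments sum-coded) and returns the RIL adjusted
#' means; with balanced data these equal the simple per-RIL means.
#'
#' @param tables named list of phenotype data frames (`ril_id` + element
#'   columns), one per environment.
#' @param env_set environments to combine (names into `tables`); default all.
#' @return data frame `ril_id` + one LS-mean column per element.
#' @export
ls_means <- function(tables, env_set = NULL) {
  if (is.null(env_set)) env_set <- names(tables)
  if (length(env_set) < 1L) stop("need at least one environment")
  stacked <- do.call(rbind, lapply(env_set, function(e)
    cbind(env = e, tables[[e]])))
  elements <- setdiff(names(stacked), c("env", "ril_id"))
  rils <- sort(unique(stacked$ril_id))
  ril_f <- factor(stacked$ril_id, levels = rils)
  out <- data.frame(ril_id = rils)
  if (length(env_set) == 1L) {
    for (el in elements)
      out[[el]] <- stacked[[el]][match(rils, stacked$ril_id)]
    return(out)
  }
  env_f <- factor(stacked$env, levels = env_set)
  Xr <- stats::model.matrix(~ 0 + ril_f)
  Xe <- stats::model.matrix(~ env_f,
                            contrasts.arg = list(env_f = "contr.sum"))[, -1L,
                                                                      drop = FALSE]
  X <- cbind(Xr, Xe)
  for (el in elements) {
    y <- stacked[[el]]
    ok <- !is.na(y)
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    out[[el]] <- fit$coefficients[seq_along(rils)]
  }
  out
}
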