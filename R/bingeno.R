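#' Sliding-window calling parameters
#'
#' Windows of `window_snps` observed SNP calls slide one call at a time; a
#' window is called for a parent when that parent's call count exceeds
#' `majority_threshold` (strictly), called HET when both parental counts are
#' at least `het_min_each`, and missing otherwise.
#'
#' @param window_snps window size in observed SNPs (default 15).
#' @param step_snps step in observed SNPs (default 1).
#' @param majority_threshold strict majority count T; parent call requires
#'   count > T (default 11).
#' @param het_min_each minimum count of each parent for a HET call (default 4).
#' @return a `window_call_params` list.
#' @export
window_call_params <- function(window_snps = 15L, step_snps = 1L,
                               majority_threshold = 11L, het_min_each = 4L) {
  stopifnot(majority_threshold > 0, majority_threshold < window_snps,
            step_snps >= 1)
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps),
                 majority_threshold = as.integer(majority_threshold),
                 het_min_each = as.integer(het_min_each)),
            class = "window_call_params")
}

#' Label one window composition
#'
#' Pure decision rule mapping parental call counts to a window genotype.
#' @param c_tq,c_lm counts of TQ and LM calls in the window.
#' @param params [window_call_params()].
#' @return integer genotype code (1 LM, 2 TQ, 3 HET) or NA (missing).
#' @export
classify_window <- function(c_tq, c_lm, params = window_call_params()) {
  t <- params$majority_threshold
  h <- params$het_min_each
  out <- rep(NA_integer_, length(c_tq))
  out[c_tq > t] <- GENO_TQ
  out[c_lm > t] <- GENO_LM
  het <- c_tq <= t & c_lm <= t & c_tq >= h & c_lm >= h
  out[het] <- GENO_HET
  out
}

#' Filter SNP sites before bin-map construction
#'
#' Applies, in order: (i) parents must carry different homozygous alleles;
#' (ii) both parental depths >= `parent_min_depth`; (iii) sites within
#' `adjacency_bp` of another SNP, or of an indel, are dropped (both members
#' of a close pair); (iv) total RIL depth across the population must reach
#' `ril_min_depth` (low-coverage data cannot support a per-RIL depth rule).
#'
#' @param raw a `snp_table`, sorted by (chrom, pos).
#' @param parent_min_depth minimum depth in each parent (default 10).
#' @param ril_min_depth minimum summed RIL depth per site (default 4).
#' @param adjacency_bp exclusion distance in bp (default 5).
#' @param indels optional data frame (`chrom`, `pos`) of indel positions.
#' @return filtered `snp_table` with attribute `removed` (counts per rule).
#' @export
filter_snps <- function(raw, parent_min_depth = 10L, ril_min_depth = 4L,
                        adjacency_bp = 5L, indels = NULL) {
  sites <- raw$sites
  if (is.unsorted(order(sites$chrom, sites$pos)) ||
      any(diff(sites$pos)[diff(sites$chrom) == 0L] <= 0L))
    stop("snp_table must be sorted by (chrom, pos) with unique positions")
  keep <- rep(TRUE, nrow(sites))
  removed <- c(parent_not_polymorphic = 0L, parent_depth = 0L,
               adjacency = 0L, ril_depth = 0L)

  bad <- sites$parent1_allele == sites$parent2_allele
  removed["parent_not_polymorphic"] <- sum(bad & keep)
  keep <- keep & !bad

  if (!all(is.na(sites$parent1_depth))) {
    bad <- sites$parent1_depth < parent_min_depth |
      sites$parent2_depth < parent_min_depth
    removed["parent_depth"] <- sum(bad & keep, na.rm = TRUE)
    keep <- keep & !bad
  }

  near <- rep(FALSE, nrow(sites))
  for (cc in unique(sites$chrom)) {
    idx <- which(sites$chrom == cc)
    p <- sites$pos[idx]
    if (length(p) > 1L) {
      d <- diff(p)
      close_pair <- d <= adjacency_bp
      near[idx[c(close_pair, FALSE)]] <- TRUE
      near[idx[c(FALSE, close_pair)]] <- TRUE
    }
    if (!is.null(indels)) {
      ip <- indels$pos[indels$chrom == cc]
      if (length(ip)) {
        for (i in seq_along(idx)) {
          if (any(abs(ip - p[i]) <= adjacency_bp)) near[idx[i]] <- TRUE
        }
      }
    }
  }
  removed["adjacency"] <- sum(near & keep)
  keep <- keep & !near

  tot_depth <- rowSums(raw$depth)
  if (!all(is.na(tot_depth))) {
    bad <- tot_depth < ril_min_depth
    removed["ril_depth"] <- sum(bad & keep, na.rm = TRUE)
    keep <- keep & !bad
  }

  out <- new_snp_table(sites[keep, , drop = FALSE],
                       raw$calls[keep, , drop = FALSE],
                       raw$depth[keep, , drop = FALSE], raw$ril_ids)
  rownames(out$sites) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Sliding-window genotype calls for one RIL
#'
#' Windows slide over this RIL's observed (non-missing, homozygous) calls on
#' each chromosome; a chromosome with fewer observed calls than the window
#' size yields no windows.  Each window is anchored at its median observed
#' SNP position.
#'
#' @param snps filtered `snp_table`.
#' @param ril RIL index or id.
#' @param params [window_call_params()].
#' @return data frame `chrom`, `anchor_bp`, `c_tq`, `c_lm`, `label`.
#' @export
call_windows <- function(snps, ril, params = window_call_params()) {
  if (is.character(ril)) ril <- match(ril, snps$ril_ids)
  W <- params$window_snps
  res <- vector("list", 0L)
  for (cc in unique(snps$sites$chrom)) {
    sel <- snps$sites$chrom == cc
    calls <- snps$calls[sel, ril]
    pos <- snps$sites$pos[sel]
    obs <- which(!is.na(calls) & calls != GENO_HET)
    if (length(obs) < W) {
      warning("chromosome ", cc, ": fewer than ", W,
              " observed calls; no windows")
      next
    }
    ct <- calls[obs] == GENO_TQ
    cs <- c(0L, cumsum(ct))
    starts <- seq.int(1L, length(obs) - W + 1L, by = params$step_snps)
    c_tq <- cs[starts + W] - cs[starts]
    c_lm <- W - c_tq
    anchor <- pos[obs[starts + (W - 1L) %/% 2L]]
    res[[length(res) + 1L]] <- data.frame(
      chrom = cc, anchor_bp = anchor, c_tq = c_tq, c_lm = c_lm,
      label = classify_window(c_tq, c_lm, params))
  }
  if (!length(res))
    return(data.frame(chrom = integer(0), anchor_bp = numeric(0),
                      c_tq = integer(0), c_lm = integer(0),
                      label = integer(0)))
  do.call(rbind, res)
}

#' Collapse window calls into genotype blocks with breakpoints
#'
#' Maximal runs of identical non-missing window labels become blocks; a
#' breakpoint between adjacent discordant blocks is placed at the midpoint
#' between the last anchor of the left run and the first anchor of the right
#' run.  Missing runs are absorbed into the flanks only when both flanks
#' agree, otherwise they remain missing blocks.  A short HET run (at most
#' `het_run_max` windows) sandwiched between opposite parental genotypes is
#' the expected signature of the sliding window crossing a single crossover
#' (intermediate counts), not of residual heterozygosity: it is split at its
#' midpoint between the two flanks.  Longer HET runs are genuine HET blocks.
#'
#' @param windows data frame from [call_windows()] (one RIL).
#' @param span optional data frame `chrom`, `start_bp`, `end_bp` giving the
#'   SNP-covered span each chromosome's blocks must tile; default the anchor
#'   range.
#' @param het_run_max maximum window count of a HET run treated as a
#'   crossover transition (default 15, one window's worth of evidence).
#' @return data frame `chrom`, `start_bp`, `end_bp`, `geno` (half-open bp).
#' @export
call_blocks <- function(windows, span = NULL, het_run_max = 15L) {
  out <- vector("list", 0L)
  for (cc in unique(windows$chrom)) {
    w <- windows[windows$chrom == cc, , drop = FALSE]
    lab <- w$label
    r <- rle(ifelse(is.na(lab), 0L, lab))
    # absorb missing runs flanked by agreeing labels
    v <- r$values
    if (length(v) > 2L) {
      for (k in 2:(length(v) - 1L)) {
        if (v[k] == 0L && v[k - 1L] == v[k + 1L] && v[k - 1L] != 0L)
          v[k] <- v[k - 1L]
      }
    }
    lab2 <- inverse.rle(list(lengths = r$lengths, values = v))
    # split short HET transition runs between discordant parental flanks
    r1 <- rle(lab2)
    v1 <- r1$values
    ends1 <- cumsum(r1$lengths)
    starts1 <- c(1L, ends1[-length(ends1)] + 1L)
    if (length(v1) > 2L) {
      for (k in 2:(length(v1) - 1L)) {
        if (v1[k] == GENO_HET && r1$lengths[k] <= het_run_max &&
            v1[k - 1L] %in% c(GENO_LM, GENO_TQ) &&
            v1[k + 1L] %in% c(GENO_LM, GENO_TQ) &&
            v1[k - 1L] != v1[k + 1L]) {
          half <- starts1[k] + (r1$lengths[k] - 1L) %/% 2L
          lab2[starts1[k]:half] <- v1[k - 1L]
          if (half < ends1[k]) lab2[(half + 1L):ends1[k]] <- v1[k + 1L]
        }
      }
    }
    r2 <- rle(lab2)
    ends <- cumsum(r2$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    n_run <- length(ends)
    if (is.null(span)) {
      lo <- min(w$anchor_bp); hi <- max(w$anchor_bp)
    } else {
      srow <- span[span$chrom == cc, , drop = FALSE]
      lo <- srow$start_bp[1L]; hi <- srow$end_bp[1L]
    }
    brk <- if (n_run > 1L)
      (w$anchor_bp[ends[-n_run]] + w$anchor_bp[starts[-1L]]) / 2
    else numeric(0)
    out[[length(out) + 1L]] <- data.frame(
      chrom = cc,
      start_bp = c(lo, brk),
      end_bp = c(brk, hi),
      geno = ifelse(r2$values == 0L, NA_integer_, r2$values))
  }
  do.call(rbind, out)
}

new_bin_matrix <- function(bins, geno, ril_ids) {
  structure(list(bins = bins, geno = geno, ril_ids = ril_ids),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat("bin_matrix:", nrow(x$bins), "bins x", length(x$ril_ids), "RILs on",
      length(unique(x$bins$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Build the population-level recombination bin map
#'
#' Population bin boundaries are the union of all per-RIL breakpoints on
#' each chromosome; each bin's genotype for a RIL is the label of the block
#' containing it.  Bins shorter than `min_bin_bp` are merged into the
#' adjacent bin introducing fewer population-level genotype conflicts (ties
#' merge left); chromosomes in `exempt_chroms` skip the length filter.
#'
#' @param blocks list of per-RIL block data frames from [call_blocks()].
#' @param min_bin_bp minimum bin length in bp (default 20000).
#' @param exempt_chroms chromosomes exempt from the length filter
#'   (default 4, which lacks enough markers on its long arm).
#' @param ril_ids optional RIL names.
#' @return a `bin_matrix`; `summary()` reports bin count, length
#'   distribution and per-RIL heterozygosity.
#' @export
build_bin_map <- function(blocks, min_bin_bp = 20000L, exempt_chroms = 4L,
                          ril_ids = NULL) {
  if (!length(blocks)) stop("empty block set")
  n_ril <- length(blocks)
  if (is.null(ril_ids)) ril_ids <- sprintf("RIL%03d", seq_len(n_ril))
  chroms <- sort(unique(unlist(lapply(blocks, function(b) b$chrom))))
  bins_list <- geno_list <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    cc <- chroms[ci]
    per_ril <- lapply(blocks, function(b) b[b$chrom == cc, , drop = FALSE])
    cuts <- sort(unique(unlist(lapply(per_ril, function(b)
      c(b$start_bp, b$end_bp)))))
    lo <- min(cuts); hi <- max(cuts)
    inner <- cuts[cuts > lo & cuts < hi]
    start <- c(lo, inner)
    end <- c(inner, hi)
    mids <- (start + end) / 2
    G <- matrix(NA_integer_, length(start), n_ril)
    for (i in seq_len(n_ril)) {
      b <- per_ril[[i]]
      if (!nrow(b)) next
      idx <- findInterval(mids, b$start_bp)
      ok <- idx >= 1L & mids <= b$end_bp[pmax(idx, 1L)]
      G[ok, i] <- b$geno[idx[ok]]
    }
    # merge sub-threshold bins
    if (!(cc %in% exempt_chroms)) {
      repeat {
        len <- end - start
        short <- which(len < min_bin_bp)
        if (!length(short) || length(len) == 1L) break
        k <- short[which.min(len[short])]
        conflicts <- function(a, b) sum(G[a, ] != G[b, ], na.rm = TRUE)
        left_ok <- k > 1L
        right_ok <- k < length(start)
        cl <- if (left_ok) conflicts(k, k - 1L) else Inf
        cr <- if (right_ok) conflicts(k, k + 1L) else Inf
        into <- if (cl <= cr) k - 1L else k + 1L
        if (into < k) {  # extend left neighbor
          end[into] <- end[k]
        } else {
          start[into] <- start[k]
        }
        start <- start[-k]; end <- end[-k]; G <- G[-k, , drop = FALSE]
      }
    }
    bins_list[[ci]] <- data.frame(chrom = cc, start_bp = start, end_bp = end)
    geno_list[[ci]] <- G
  }
  bins <- do.call(rbind, bins_list)
  geno <- do.call(rbind, geno_list)
  colnames(geno) <- ril_ids
  new_bin_matrix(bins, geno, ril_ids)
}

#' Heterozygous genome fraction from a bin matrix
#'
#' Length-weighted fraction of non-missing called genome that is HET, per
#' RIL and averaged over the population.
#'
#' @param bin_matrix a `bin_matrix`.
#' @return list `per_ril` (named numeric; NA with a flag for all-missing
#'   RILs) and `population` (mean over defined RILs).
#' @export
heterozygosity <- function(bin_matrix) {
  len <- bin_matrix$bins$end_bp - bin_matrix$bins$start_bp
  per_ril <- apply(bin_matrix$geno, 2L, function(g) {
    tot <- sum(len[!is.na(g)])
    if (tot == 0) return(NA_real_)
    sum(len[!is.na(g) & g == GENO_HET]) / tot
  })
  if (anyNA(per_ril))
    warning(sum(is.na(per_ril)), " RIL(s) with no called bins")
  list(per_ril = per_ril, population = mean(per_ril, na.rm = TRUE))
}

#' Bin-map summary statistics
#' @param object a `bin_matrix`.
#' @param ... unused.
#' @return list with bin count, length quantiles and heterozygosity.
#' @export
summary.bin_matrix <- function(object, ...) {
  len <- object$bins$end_bp - object$bins$start_bp
  het <- suppressWarnings(heterozygosity(object))
  list(n_bins = nrow(object$bins),
       length_bp = stats::quantile(len, c(0, 0.25, 0.5, 0.75, 1)),
       mean_length_bp = mean(len),
       het_population = het$population)
}
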