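#' Observed recombinant fraction between two bins
#'
#' Counts discordant parental calls across RILs; HET or missing at either
#' bin makes a RIL uninformative.  The estimate is clamped to
#' `[0, 0.5 - 1e-9]` (a selfing-RIL panel cannot inform beyond R = 0.5).
#'
#' @param bin_matrix a `bin_matrix`.
#' @param i,j bin row indices.
#' @return list `R_obs`, `n_informative`, `n_discordant`; `R_obs` is NA
#'   (flagged missing) when no RIL is informative.
#' @export
estimate_rf <- function(bin_matrix, i, j) {
  a <- bin_matrix$geno[i, ]
  b <- bin_matrix$geno[j, ]
  inf <- !is.na(a) & !is.na(b) & a != GENO_HET & b != GENO_HET
  n <- sum(inf)
  if (n == 0L)
    return(list(R_obs = NA_real_, n_informative = 0L, n_discordant = 0L))
  d <- sum(a[inf] != b[inf])
  list(R_obs = min(d / n, 0.5 - 1e-9), n_informative = n, n_discordant = d)
}

#' Selfing-RIL correction of a recombinant fraction
#'
#' Inverts the RIL-panel expectation \eqn{R = 2r/(1+2r)}: \eqn{r = R/(2(1-R))}.
#' @param R_obs observed recombinant fraction(s).
#' @return per-meiosis recombination fraction, clamped to `[0, 0.5)`.
#' @export
ril_correct <- function(R_obs) {
  if (any(R_obs >= 0.5, na.rm = TRUE)) {
    warning("R_obs >= 0.5 clamped")
    R_obs <- pmin(R_obs, 0.5 - 1e-9)
  }
  pmin(pmax(R_obs / (2 * (1 - R_obs)), 0), 0.5 - .Machine$double.eps)
}

#' RIL-panel recombinant fraction from a per-meiosis fraction
#' @param r per-meiosis recombination fraction.
#' @return expected observed fraction \eqn{R = 2r/(1+2r)} in a selfing RIL.
#' @export
ril_expand <- function(r) 2 * r / (1 + 2 * r)

#' Map distance from a recombination fraction
#'
#' Haldane: \eqn{d = -50\,\ln(1-2r)}; Kosambi: \eqn{d = 25\,\ln((1+2r)/(1-2r))}.
#' @param r per-meiosis recombination fraction(s), in `[0, 0.5)`.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return distance in cM.
#' @export
map_distance <- function(r, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(r >= 0.5, na.rm = TRUE)) stop("r >= 0.5 gives infinite distance")
  if (any(r < 0, na.rm = TRUE)) stop("r must be non-negative")
  switch(map_function,
         haldane = -50 * log(1 - 2 * r),
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' Recombination fraction from a map distance (inverse map function)
#' @param d distance(s) in cM.
#' @param map_function `"kosambi"` or `"haldane"`.
#' @return per-meiosis recombination fraction.
#' @export
inverse_map_distance <- function(d, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  switch(map_function,
         haldane = (1 - exp(-d / 50)) / 2,
         kosambi = tanh(d / 50) / 2)
}

#' Assemble the linkage map from a bin matrix
#'
#' Bins are kept in physical order (one linkage group per chromosome);
#' adjacent-bin recombinant fractions are RIL-corrected and converted to cM,
#' and cumulative positions accumulated.  A missing adjacent estimate is
#' bridged by estimating against the previous informative bin.
#'
#' @param bin_matrix a `bin_matrix`.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return a `linkage_map` data frame: `lg`, `bin`, `chrom`, `start_bp`,
#'   `end_bp`, `pos_cM`, `R_obs`, `r`, `d_cM`, `n_informative`; attributes
#'   `map_function`, `total_cM`, `mean_interval_cM`.
#' @export
build_linkage_map <- function(bin_matrix,
                              map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  bins <- bin_matrix$bins
  out <- vector("list", 0L)
  for (cc in sort(unique(bins$chrom))) {
    idx <- which(bins$chrom == cc)
    n <- length(idx)
    if (n < 2L)
      warning("chromosome ", cc, ": single-bin linkage group")
    pos <- numeric(n)
    R <- r <- d <- rep(NA_real_, n)
    ninf <- rep(0L, n)
    anchor <- idx[1L]  # last informative bin
    for (k in seq_len(n)[-1L]) {
      est <- estimate_rf(bin_matrix, anchor, idx[k])
      if (is.na(est$R_obs)) {
        pos[k] <- pos[k - 1L]  # uninformative: carried, bridged later
        next
      }
      R[k] <- est$R_obs
      r[k] <- ril_correct(est$R_obs)
      d[k] <- map_distance(r[k], map_function)
      ninf[k] <- est$n_informative
      pos[k] <- pos[match(anchor, idx)] + d[k]
      anchor <- idx[k]
    }
    out[[length(out) + 1L]] <- data.frame(
      lg = cc, bin = idx, chrom = cc,
      start_bp = bins$start_bp[idx], end_bp = bins$end_bp[idx],
      pos_cM = pos, R_obs = R, r = r, d_cM = d, n_informative = ninf)
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  lens <- tapply(map$pos_cM, map$lg, max)
  structure(map, class = c("linkage_map", "data.frame"),
            map_function = map_function,
            total_cM = sum(lens),
            mean_interval_cM = sum(lens) / max(nrow(map) -
                                                 length(unique(map$lg)), 1L))
}
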