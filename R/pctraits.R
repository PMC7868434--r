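#' Descriptive statistics and element correlations
#'
#' Per element: skewness, kurtosis, Shapiro-Wilk normality test, fold-range,
#' and (when replicate rows per RIL are present, e.g. a stacked
#' multi-environment table) a one-way ANOVA across RILs.  Pairwise Pearson
#' correlations are computed on per-RIL means with pairwise-complete
#' observations and two-sided p-values from the t transform; a significance
#' mask at p < 0.01 accompanies the r matrix.
#'
#' @param table data frame with `ril_id` and element columns; an optional
#'   `env` column marks stacked environments.
#' @param p_mask significance level for the correlation mask (default 0.01).
#' @return a `stats_report`: `per_element` data frame, `r` matrix,
#'   `r_pvalue` matrix, `r_significant` logical mask.
#' @export
phenotype_stats <- function(table, p_mask = 0.01) {
  elements <- setdiff(names(table), c("ril_id", "env"))
  has_reps <- anyDuplicated(table$ril_id) > 0L
  per_el <- lapply(elements, function(el) {
    y <- table[[el]]
    ok <- !is.na(y)
    sw <- if (sum(ok) >= 3 && sum(ok) <= 5000 && stats::sd(y[ok]) > 0)
      stats::shapiro.test(y[ok]) else list(statistic = NA, p.value = NA)
    if (has_reps && stats::sd(y[ok]) > 0) {
      fit <- stats::aov(y ~ factor(ril_id), data = table[ok, , drop = FALSE])
      an <- summary(fit)[[1]]
      aov_f <- an[["F value"]][1]; aov_p <- an[["Pr(>F)"]][1]
    } else {
      aov_f <- NA_real_; aov_p <- NA_real_
    }
    data.frame(element = el,
               skewness = e1071::skewness(y[ok]),
               kurtosis = e1071::kurtosis(y[ok]),
               shapiro_W = unname(sw$statistic),
               shapiro_p = sw$p.value,
               fold_range = if (min(y[ok]) > 0) max(y[ok]) / min(y[ok])
                            else NA_real_,
               anova_F = aov_f, anova_p = aov_p)
  })
  means <- stats::aggregate(table[elements], list(ril_id = table$ril_id),
                            mean, na.rm = TRUE)
  M <- as.matrix(means[elements])
  r <- stats::cor(M, use = "pairwise.complete.obs")
  n_pair <- crossprod(!is.na(M))
  tval <- r * sqrt(pmax(n_pair - 2, 0) / pmax(1 - r^2, 1e-15))
  pmat <- 2 * stats::pt(abs(tval), pmax(n_pair - 2, 1), lower.tail = FALSE)
  diag(pmat) <- 0
  const <- apply(M, 2L, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(const)) {
    r[const, ] <- r[, const] <- NA
    warning("constant element column(s): ",
            paste(elements[const], collapse = ", "))
  }
  structure(list(per_element = do.call(rbind, per_el), r = r,
                 r_pvalue = pmat, r_significant = pmat < p_mask & !is.na(r)),
            class = "stats_report")
}

.fix_signs <- function(loadings, scores) {
  # deterministic orientation: the element with the largest |loading| of
  # each PC loads positively; ties break on the first such element
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(loadings = loadings, scores = scores)
}

new_pca_model <- function(scope, loadings, scores, var_fraction,
                          center, scale, rows) {
  colnames(loadings) <- colnames(scores) <-
    paste0("PC", seq_len(ncol(loadings)))
  structure(list(scope = scope, loadings = loadings, scores = scores,
                 var_fraction = var_fraction, center = center, scale = scale,
                 rows = rows),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model [", x$scope, "]: ", nrow(x$scores), " rows x ",
      ncol(x$loadings), " PCs; PC1 ",
      sprintf("%.1f%%", 100 * x$var_fraction[1]), " of variance\n", sep = "")
  invisible(x)
}

#' PCA of the ionome within one environment/tissue
#'
#' Z-scores each element (centre and scale) and eigendecomposes the
#' correlation matrix via [stats::prcomp()]; all PCs (one per element) are
#' returned with a deterministic sign convention.  Rows with any missing
#' element are dropped listwise with a reported count.
#'
#' @param table phenotype data frame (`ril_id` + element columns) for one
#'   environment.
#' @param scope label stored on the model.
#' @return a `pca_model`: `loadings` (element x PC), `scores` (row x PC),
#'   `var_fraction`, z-score parameters, and `rows` (`ril_id`, `env`).
#' @export
pca_within <- function(table, scope = "within") {
  elements <- setdiff(names(table), c("ril_id", "env"))
  M <- as.matrix(table[elements])
  complete <- stats::complete.cases(M)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L)
    message(n_dropped, " row(s) with missing elements dropped")
  M <- M[complete, , drop = FALSE]
  if (nrow(M) < 2L) stop("need at least 2 complete rows for PCA")
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE, retx = TRUE)
  L <- pc$rotation
  S <- pc$x
  # pad in the degenerate n <= p case so all 16 PCs exist
  p <- ncol(M)
  if (ncol(L) < p) {
    L <- cbind(L, matrix(0, p, p - ncol(L)))
    S <- cbind(S, matrix(0, nrow(S), p - ncol(S)))
  }
  fs <- .fix_signs(L, S)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  varfrac <- c(varfrac, rep(0, p - length(varfrac)))
  rows <- data.frame(ril_id = table$ril_id[complete],
                     env = if ("env" %in% names(table))
                       table$env[complete] else scope)
  new_pca_model(scope, fs$loadings, fs$scores, varfrac,
                pc$center, pc$scale, rows)
}

#' PCA of the ionome across environments/tissues
#'
#' Stacks the per-environment tables in long format (one row per RIL x
#' environment, 16 element columns), z-scores over the stacked rows, and
#' proceeds as [pca_within()].  Scores are returned grouped by environment,
#' so each environment contributes one score vector per across-environment
#' PC (aPC) for scanning, labelled `<set>_<env>_aPC<k>`.
#'
#' @param tables named list of phenotype data frames.
#' @param env_set environments to stack (names into `tables`); a singleton
#'   delegates to [pca_within()] with a warning.
#' @param scope label for the set (e.g. "F", "U", "FUGG", "GRS").
#' @return a `pca_model`; see [apc_score_traits()] for per-environment
#'   score extraction.
#' @export
pca_across <- function(tables, env_set = names(tables), scope = "across") {
  if (length(env_set) == 1L) {
    warning("environment set of size 1: delegating to pca_within")
    tab <- tables[[env_set]]
    tab$env <- env_set
    return(pca_within(tab, scope = scope))
  }
  stacked <- do.call(rbind, lapply(env_set, function(e) {
    tab <- tables[[e]]
    cbind(env = e, tab[c("ril_id", setdiff(names(tab), c("ril_id", "env")))])
  }))
  el_sets <- lapply(env_set, function(e)
    sort(setdiff(names(tables[[e]]), c("ril_id", "env"))))
  if (length(unique(vapply(el_sets, paste, character(1), collapse = ","))) != 1L)
    stop("environments do not share the same element set")
  pca_within(stacked, scope = scope)
}

#' Per-environment aPC score trait vectors
#'
#' Regroups the scores of an across-environment PCA by environment: each
#' (aPC, environment) pair yields one named trait vector over that
#' environment's RILs, labelled `<scope>_<env>_aPC<k>`.
#'
#' @param model a `pca_model` from [pca_across()].
#' @return named list of named numeric vectors.
#' @export
apc_score_traits <- function(model) {
  out <- list()
  for (e in unique(model$rows$env)) {
    sel <- model$rows$env == e
    for (k in seq_len(ncol(model$scores))) {
      v <- model$scores[sel, k]
      names(v) <- model$rows$ril_id[sel]
      out[[sprintf("%s_%s_aPC%d", model$scope, e, k)]] <- v
    }
  }
  out
}

#' Elements with the largest loadings on a PC
#'
#' @param model a `pca_model`.
#' @param pc PC index.
#' @param k number of elements to return (default 5; clipped to the element
#'   count).
#' @return data frame `element`, `loading`, ordered by |loading| descending,
#'   ties broken by the fixed element order.
#' @export
top_loading_elements <- function(model, pc, k = 5L) {
  p <- nrow(model$loadings)
  stopifnot(pc >= 1L, pc <= ncol(model$loadings))
  k <- min(k, p)
  lo <- model$loadings[, pc]
  ord <- order(-abs(lo), seq_len(p))[seq_len(k)]
  data.frame(element = rownames(model$loadings)[ord], loading = lo[ord])
}
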