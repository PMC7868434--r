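#' Build unified QTL records from a peak table
#'
#' @param peaks data frame from [find_peaks()].
#' @param qtl_class one of `"elemental"`, `"PC"`, `"aPC"`.
#' @param env environment/tissue label.
#' @param element element name (elemental class only).
#' @param top5 character vector of the PC's top-loading elements (PC/aPC
#'   classes), stored as a semicolon-joined string.
#' @return data frame of `QtlRecord` rows.
#' @export
qtl_records <- function(peaks, qtl_class = c("elemental", "PC", "aPC"),
                        env = NA_character_, element = NA_character_,
                        top5 = NULL) {
  qtl_class <- match.arg(qtl_class)
  if (!nrow(peaks)) return(empty_qtl_records())
  data.frame(id = NA_character_, qtl_class = qtl_class,
             trait = peaks$trait, element = element, env = env,
             lg = peaks$lg, lo_cM = peaks$ci_lo_cM, hi_cM = peaks$ci_hi_cM,
             peak_cM = peaks$peak_cM, lod = peaks$lod, pve = peaks$pve_pct,
             top5 = if (is.null(top5)) NA_character_
                    else paste(top5, collapse = ";"),
             stringsAsFactors = FALSE)
}

empty_qtl_records <- function() {
  data.frame(id = character(0), qtl_class = character(0),
             trait = character(0), element = character(0),
             env = character(0), lg = integer(0), lo_cM = numeric(0),
             hi_cM = numeric(0), peak_cM = numeric(0), lod = numeric(0),
             pve = numeric(0), top5 = character(0), stringsAsFactors = FALSE)
}

.assign_ids <- function(records) {
  if (nrow(records))
    records$id <- sprintf("Q%03d", seq_len(nrow(records)))
  records
}

# connected components of the closed-interval overlap graph on one line:
# sort by lo, a new component starts when lo exceeds the running max hi
.interval_components <- function(lo, hi) {
  ord <- order(lo, hi)
  comp <- integer(length(lo))
  cur <- 0L
  run_hi <- -Inf
  for (k in ord) {
    if (lo[k] > run_hi) {
      cur <- cur + 1L
      run_hi <- hi[k]
    } else {
      run_hi <- max(run_hi, hi[k])
    }
    comp[k] <- cur
  }
  comp
}

#' Merge repeated elemental QTLs into unique QTLs
#'
#' Records for the same element whose support intervals overlap (closed
#' intervals, transitively) on the same linkage group are merged into one
#' unique QTL: interval = union, representative LOD/PVE/peak = the
#' highest-LOD member, provenance keeps all member environments.
#'
#' @param records elemental QTL records.
#' @return data frame of unique QTLs with `n_detections` and `environments`.
#' @export
merge_unique <- function(records) {
  records <- records[records$qtl_class == "elemental", , drop = FALSE]
  if (!nrow(records)) {
    out <- empty_qtl_records()
    out$n_detections <- integer(0)
    out$environments <- character(0)
    return(out)
  }
  key <- paste(records$element, records$lg, sep = "|")
  merged <- list()
  for (kk in unique(key)) {
    sub <- records[key == kk, , drop = FALSE]
    comp <- .interval_components(sub$lo_cM, sub$hi_cM)
    for (cmp in unique(comp)) {
      mem <- sub[comp == cmp, , drop = FALSE]
      best <- mem[which.max(mem$lod), , drop = FALSE]
      best$lo_cM <- min(mem$lo_cM)
      best$hi_cM <- max(mem$hi_cM)
      # aggregate provenance; re-merging an already-merged set preserves it
      best$n_detections <- if ("n_detections" %in% names(mem))
        sum(mem$n_detections) else nrow(mem)
      envs <- if ("environments" %in% names(mem))
        unlist(strsplit(mem$environments, ";", fixed = TRUE)) else mem$env
      best$environments <- paste(sort(unique(envs)), collapse = ";")
      merged[[length(merged) + 1L]] <- best
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$lg, out$lo_cM, out$element), , drop = FALSE]
  rownames(out) <- NULL
  .assign_ids(out)
}

#' Co-localization report across QTL classes
#'
#' Two records co-localize iff their support intervals intersect (closed
#' intervals in cM) on the same linkage group.  Reports per-record
#' co-localization lists and Venn-style counts per class combination.
#'
#' @param records combined QTL records (>= 2 classes).
#' @return an `overlap_report`: `records` (with ids), `pairs` (data frame of
#'   co-localized pairs), `per_record` (list of co-localized ids), `venn`
#'   (per class, counts of records co-localizing with each other-class
#'   combination).
#' @export
overlap_classes <- function(records) {
  records <- .assign_ids(records)
  n <- nrow(records)
  pairs <- list()
  per_record <- stats::setNames(vector("list", n), records$id)
  for (g in unique(records$lg)) {
    idx <- which(records$lg == g)
    if (length(idx) < 2L) next
    ord <- idx[order(records$lo_cM[idx])]
    for (a_i in seq_along(ord)[-length(ord)]) {
      i <- ord[a_i]
      for (b_i in (a_i + 1L):length(ord)) {
        j <- ord[b_i]
        if (records$lo_cM[j] > records$hi_cM[i]) break
        pairs[[length(pairs) + 1L]] <- data.frame(
          id1 = records$id[i], id2 = records$id[j],
          class1 = records$qtl_class[i], class2 = records$qtl_class[j])
        per_record[[records$id[i]]] <- c(per_record[[records$id[i]]],
                                         records$id[j])
        per_record[[records$id[j]]] <- c(per_record[[records$id[j]]],
                                         records$id[i])
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id1 = character(0), id2 = character(0),
               class1 = character(0), class2 = character(0))
  classes <- c("elemental", "PC", "aPC")
  venn <- list()
  for (cl in classes) {
    sel <- records$qtl_class == cl
    others <- setdiff(classes, cl)
    partner_class <- function(id) unique(
      records$qtl_class[match(per_record[[id]], records$id)])
    with1 <- vapply(records$id[sel], function(id)
      others[1] %in% partner_class(id), logical(1))
    with2 <- vapply(records$id[sel], function(id)
      others[2] %in% partner_class(id), logical(1))
    venn[[cl]] <- c(total = sum(sel),
                    stats::setNames(sum(with1), paste0("with_", others[1])),
                    stats::setNames(sum(with2), paste0("with_", others[2])),
                    with_both = sum(with1 & with2),
                    with_none = sum(!with1 & !with2))
  }
  structure(list(records = records, pairs = pairs,
                 per_record = per_record, venn = venn),
            class = "overlap_report")
}

#' Detect three-class QTL clusters
#'
#' Connected components of the co-localization graph (closed-interval
#' overlap within a linkage group) restricted to components containing at
#' least one record of each class (elemental, PC, aPC).  The cluster
#' interval is the union of member intervals.
#'
#' @param records combined QTL records.
#' @return list of `qtl_cluster` objects: `cluster_id`, `lg`, `lo_cM`,
#'   `hi_cM`, `members` (record data frame), `concordant` (any member
#'   PC/aPC top-5 contains a co-localized elemental record's element).
#' @export
find_clusters <- function(records) {
  records <- .assign_ids(records)
  clusters <- list()
  for (g in sort(unique(records$lg))) {
    sub <- records[records$lg == g, , drop = FALSE]
    comp <- .interval_components(sub$lo_cM, sub$hi_cM)
    for (cmp in sort(unique(comp))) {
      mem <- sub[comp == cmp, , drop = FALSE]
      if (!all(c("elemental", "PC", "aPC") %in% mem$qtl_class)) next
      conc <- concordance_top5(mem)
      clusters[[length(clusters) + 1L]] <- structure(
        list(cluster_id = length(clusters) + 1L, lg = g,
             lo_cM = min(mem$lo_cM), hi_cM = max(mem$hi_cM),
             members = mem,
             concordant = isTRUE(any(conc$pairs$concordant))),
        class = "qtl_cluster")
    }
  }
  clusters
}

#' Top-5 loading concordance between PC/aPC and elemental QTLs
#'
#' For every (PC-or-aPC record, co-localized elemental record) pair, flags
#' whether the elemental record's element appears in the composite record's
#' top-5 loading list; aggregates fractions per class.
#'
#' @param records combined QTL records (pairs are formed by closed-interval
#'   overlap within the set).
#' @return list `pairs` (per-pair flags) and `aggregate` (per class:
#'   n_pairs, n_concordant, fraction).
#' @export
concordance_top5 <- function(records) {
  records <- .assign_ids(records)
  comp_sel <- records$qtl_class %in% c("PC", "aPC")
  el_sel <- records$qtl_class == "elemental"
  rows <- list()
  for (i in which(comp_sel)) {
    if (is.na(records$top5[i])) {
      warning("record ", records$id[i], " lacks a top-5 list; skipped")
      next
    }
    top5 <- strsplit(records$top5[i], ";", fixed = TRUE)[[1]]
    for (j in which(el_sel)) {
      if (records$lg[j] != records$lg[i]) next
      if (records$lo_cM[j] > records$hi_cM[i] ||
          records$hi_cM[j] < records$lo_cM[i]) next
      rows[[length(rows) + 1L]] <- data.frame(
        composite_id = records$id[i], composite_class = records$qtl_class[i],
        elemental_id = records$id[j], element = records$element[j],
        concordant = records$element[j] %in% top5)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(composite_id = character(0), composite_class = character(0),
               elemental_id = character(0), element = character(0),
               concordant = logical(0))
  agg <- lapply(c(PC = "PC", aPC = "aPC"), function(cl) {
    sel <- pairs$composite_class == cl
    c(n_pairs = sum(sel), n_concordant = sum(pairs$concordant[sel]),
      fraction = if (any(sel)) mean(pairs$concordant[sel]) else NA_real_)
  })
  list(pairs = pairs, aggregate = agg)
}
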