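#' Write a SNP table as VCF 4.2
#'
#' Parents are emitted as the first two samples (`LM`, `TQ`) as opposite
#' homozygotes; RIL calls are `0/0` (LM allele), `1/1` (TQ allele) or `./.`,
#' each with a `DP` field.  Plain text, deterministic byte-for-byte.
#'
#' @param snps a `snp_table`.
#' @param path output file.
#' @param chrom_len_bp optional contig lengths for the header.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(snps, path, chrom_len_bp = NULL) {
  sites <- snps$sites
  hdr <- c("##fileformat=VCFv4.2", "##source=ionqtl")
  chroms <- sort(unique(sites$chrom))
  if (!is.null(chrom_len_bp)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%d,length=%d>", chroms,
                          as.integer(chrom_len_bp[chroms])))
  } else {
    hdr <- c(hdr, sprintf("##contig=<ID=%d>", chroms))
  }
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "LM", "TQ", snps$ril_ids), collapse = "\t"))
  gt <- matrix("./.", nrow(sites), length(snps$ril_ids))
  gt[which(snps$calls == GENO_LM)] <- "0/0"
  gt[which(snps$calls == GENO_TQ)] <- "1/1"
  gt[which(snps$calls == GENO_HET)] <- "0/1"
  cells <- matrix(paste0(gt, ":", snps$depth), nrow(sites))
  body <- paste(sites$chrom, sites$pos, ".", sites$parent1_allele,
                sites$parent2_allele, ".", "PASS", ".", "GT:DP",
                paste0("0/0:", sites$parent1_depth),
                paste0("1/1:", sites$parent2_depth),
                apply(cells, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a SNP table
#'
#' Parses a VCF 4.x with `GT` (and optionally `DP`) via vcfR.  The parent
#' samples (default the first two, or named via `parents`) define which
#' allele is LM-type and which TQ-type; per-RIL calls are mapped to
#' LM/TQ/missing.  Multi-allelic records, indels and records where a parent
#' call is missing or heterozygous are skipped, with counts reported.
#'
#' @param path VCF file.
#' @param parents length-2 character, sample names of the LM- and TQ-type
#'   parents, in that order; default the first two samples.
#' @return a `snp_table` with attribute `skipped` (named counts).
#' @export
read_vcf <- function(path, parents = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- tryCatch(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
    error = function(e) NULL)
  samples <- colnames(gt_raw)
  if (is.null(parents)) parents <- samples[1:2]
  if (!all(parents %in% samples)) stop("parent samples not found in VCF")
  ril_ids <- setdiff(samples, parents)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- nchar(ref) != 1L | (nchar(alt) != 1L & !multi)
  norm_gt <- function(g) {
    g <- sub(":.*", "", g)
    gsub("|", "/", g, fixed = TRUE)
  }
  p1 <- norm_gt(gt_raw[, parents[1]])
  p2 <- norm_gt(gt_raw[, parents[2]])
  p_bad <- !(p1 %in% c("0/0", "1/1")) | !(p2 %in% c("0/0", "1/1"))
  p_same <- !p_bad & p1 == p2
  keep <- !multi & !indel & !p_bad & !p_same
  skipped <- c(multiallelic = sum(multi),
               indel = sum(indel & !multi),
               parent_not_homozygous = sum(p_bad & !multi & !indel),
               parent_monomorphic = sum(p_same & !multi & !indel))

  fix <- fix[keep, , drop = FALSE]
  p1 <- p1[keep]
  gtm <- gt_raw[keep, ril_ids, drop = FALSE]
  gtm <- matrix(norm_gt(gtm), nrow = nrow(gtm), dimnames = dimnames(gtm))
  calls <- matrix(NA_integer_, nrow(fix), length(ril_ids))
  # allele 0 belongs to whichever parent carries it
  ref_is_lm <- p1 == "0/0"
  code_ref <- ifelse(ref_is_lm, GENO_LM, GENO_TQ)
  code_alt <- ifelse(ref_is_lm, GENO_TQ, GENO_LM)
  for (j in seq_along(ril_ids)) {
    g <- gtm[, j]
    iref <- which(g == "0/0")
    ialt <- which(g == "1/1")
    calls[iref, j] <- code_ref[iref]
    calls[ialt, j] <- code_alt[ialt]
    calls[which(g %in% c("0/1", "1/0")), j] <- GENO_HET
  }
  depth <- if (is.null(dp_raw)) matrix(NA_integer_, nrow(fix), length(ril_ids))
           else {
             m <- dp_raw[keep, ril_ids, drop = FALSE]
             m[is.na(m)] <- 0
             matrix(as.integer(m), nrow(fix))
           }
  p_depth <- if (is.null(dp_raw)) {
    matrix(NA_integer_, nrow(fix), 2L)
  } else {
    m <- dp_raw[keep, parents, drop = FALSE]
    m[is.na(m)] <- 0
    matrix(as.integer(m), nrow(fix))
  }
  a_ref <- fix[, "REF"]
  a_alt <- fix[, "ALT"]
  sites <- data.frame(
    chrom = as.integer(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    parent1_allele = ifelse(ref_is_lm, a_ref, a_alt),
    parent2_allele = ifelse(ref_is_lm, a_alt, a_ref),
    parent1_depth = p_depth[, 1L], parent2_depth = p_depth[, 2L],
    stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  out <- new_snp_table(sites[ord, , drop = FALSE],
                       calls[ord, , drop = FALSE],
                       depth[ord, , drop = FALSE], ril_ids)
  rownames(out$sites) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a bin matrix as CSV
#'
#' Rows are bins (`chrom,start_bp,end_bp` 1-based inclusive on disk),
#' columns RILs, genotype codes A = LM, B = TQ, H = HET, `-` = missing.
#' @param bins a `bin_matrix`.
#' @param path output file.
#' @export
write_bin_csv <- function(bins, path) {
  disk <- matrix(geno_disk_code(bins$geno), nrow(bins$geno),
                 dimnames = dimnames(bins$geno))
  df <- cbind(data.frame(chrom = bins$bins$chrom,
                         start_bp = bins$bins$start_bp + 1L,
                         end_bp = bins$bins$end_bp),
              as.data.frame(disk))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a bin matrix CSV written by [write_bin_csv()]
#' @param path CSV file.
#' @return a `bin_matrix`.
#' @export
read_bin_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  geno <- as.matrix(df[, -(1:3), drop = FALSE])
  m <- matrix(geno_from_disk(geno), nrow(geno), dimnames = dimnames(geno))
  new_bin_matrix(data.frame(chrom = df$chrom, start_bp = df$start_bp - 1L,
                            end_bp = df$end_bp),
                 m, colnames(m))
}
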