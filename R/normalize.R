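# Preprocessing: sample/gene filters, log2(cpm), rank-based normalization,
# splicing phenotype preparation, and cis-window SNP selection.

#' Filter low-depth samples and low-expression genes, convert to log2(cpm)
#'
#' Samples with fewer than `min_reads` total assigned reads (default 1e7)
#' are dropped first; counts-per-million are then computed per remaining
#' sample and genes whose median log2(cpm) is below 0 are dropped. The
#' threshold applies to the column totals of the supplied count matrix;
#' alignments are never recomputed.
#'
#' Returned values are log2(cpm) with cpm = count / library size * 1e6.
#' Zero counts, which have no finite log, are given a count of 0.5 before
#' the log so the output has no non-finite entries; the gene filter itself
#' is computed without that adjustment.
#'
#' @param counts an [expr_matrix()] in `raw_counts` state.
#' @param design the matching [sample_design()].
#' @param min_reads sample inclusion threshold on total assigned reads.
#' @return list: `expr` ([expr_matrix()] in `log2cpm` state), `design`
#'   (subset to kept samples), `removed_samples`, `removed_genes`.
#' @export
filter_and_normalize <- function(counts, design, min_reads = 1e7) {
  stopifnot(inherits(counts, "expr_matrix"), counts$state == "raw_counts")
  x <- counts$values
  if (any(x < 0) || any(x != round(x)))
    stop_respqtl("raw counts must be nonnegative integers",
                 "respqtl_invalid_expression")
  lib <- colSums(x)
  keep_s <- lib >= min_reads
  if (!any(keep_s))
    stop_respqtl("all samples below the read-depth threshold",
                 "respqtl_all_filtered")
  removed_samples <- colnames(x)[!keep_s]
  x <- x[, keep_s, drop = FALSE]
  lib <- lib[keep_s]
  cpm <- sweep(x, 2, lib / 1e6, "/")
  med <- apply(log2(cpm), 1, stats::median)
  keep_g <- med >= 0
  removed_genes <- rownames(x)[!keep_g]
  xk <- x[keep_g, , drop = FALSE]
  xk[xk == 0] <- 0.5
  l2 <- log2(sweep(xk, 2, lib / 1e6, "/"))
  des <- design[design$sample_id %in% colnames(l2), , drop = FALSE]
  class(des) <- c("sample_design", "data.frame")
  list(expr = expr_matrix(l2, "log2cpm", design = des), design = des,
       removed_samples = removed_samples, removed_genes = removed_genes)
}

# Rankit transform of one numeric vector; average ranks on ties.
rankit <- function(x) stats::qnorm((rank(x, ties.method = "average") - 0.5) /
                                     length(x))

#' Quantile-normalize each feature to a standard normal
#'
#' Per feature (row), values are replaced by the standard-normal quantiles
#' of their ranks across samples, using the rankit convention
#' `(r - 0.5) / n` with average ranks on ties. This is the transform used
#' before all mixed-model testing so that the Gaussian likelihood is
#' reasonable. Constant rows are set to all zeros and flagged.
#'
#' @param x an [expr_matrix()] (any state) or plain numeric matrix.
#' @return [expr_matrix()] in `quantile_normal` state, with attribute
#'   `degenerate` naming constant rows.
#' @export
quantile_normalize_features <- function(x) {
  m <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (anyNA(m))
    stop_respqtl("missing values not allowed", "respqtl_invalid_expression")
  const <- apply(m, 1, function(r) max(r) - min(r) == 0)
  out <- t(apply(m, 1, rankit))
  out[const, ] <- 0
  dimnames(out) <- dimnames(m)
  res <- expr_matrix(out, "quantile_normal")
  attr(res, "degenerate") <- rownames(m)[const]
  res
}

#' Prepare splicing phenotypes from ASC junction counts
#'
#' For each alternative-splicing cluster (ASC), intron excision ratios are
#' computed with a 0.5 pseudocount:
#' `psi = (count + 0.5) / (ASC total + 0.5 * n_introns)`.
#' Samples with zero ASC total have psi imputed to the intron's mean over
#' the other samples. Rows are then (1) z-scored across samples and (2)
#' quantile-normalized to a standard normal. ASCs with a single intron are
#' excluded (psi is identically constant).
#'
#' @param ascs list of [splicing_phenotype()] objects sharing sample
#'   columns.
#' @param qn_axis `"per_intron"` (default): rank-normalize each intron
#'   across samples; `"per_sample"`: rank-normalize each sample across
#'   introns.
#' @return [expr_matrix()] in `quantile_normal` state (introns x samples),
#'   with attribute `excluded_ascs`.
#' @export
prepare_splicing_phenotypes <- function(ascs,
                                        qn_axis = c("per_intron",
                                                    "per_sample")) {
  qn_axis <- match.arg(qn_axis)
  excluded <- character(0)
  rows <- list()
  for (asc in ascs) {
    stopifnot(inherits(asc, "splicing_phenotype"))
    cnt <- asc$counts
    if (nrow(cnt) < 2) {
      excluded <- c(excluded, asc$cluster_id)
      next
    }
    tot <- colSums(cnt)
    psi <- sweep(cnt + 0.5, 2, tot + 0.5 * nrow(cnt), "/")
    zero <- tot == 0
    if (any(zero)) {
      if (all(zero))
        stop_respqtl(sprintf("ASC %s has no reads in any sample",
                             asc$cluster_id), "respqtl_invalid_splicing")
      m <- rowMeans(psi[, !zero, drop = FALSE])
      psi[, zero] <- m
    }
    rows[[asc$cluster_id]] <- psi
  }
  if (!length(rows))
    stop_respqtl("no usable ASCs", "respqtl_invalid_splicing")
  psi <- do.call(rbind, rows)
  z <- t(apply(psi, 1, function(r) {
    s <- stats::sd(r)
    if (s < .Machine$double.eps) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(psi)
  qn <- if (qn_axis == "per_intron") t(apply(z, 1, rankit))
        else apply(z, 2, rankit)
  dimnames(qn) <- dimnames(z)
  res <- expr_matrix(qn, "quantile_normal")
  attr(res, "excluded_ascs") <- excluded
  res
}

#' Select cis-window SNPs for a feature
#'
#' Gene mode: SNPs within 1 Mb of the TSS (inclusive). Junction mode: SNPs
#' within 100 kb of either junction end (inclusive). SNPs on other
#' chromosomes are excluded, as are SNPs with fewer than `min_alt_alleles`
#' alternative alleles among the phenotyped individuals (the
#' total-expression eligibility rule; allelic eligibility is handled by
#' [ase_eligibility()]). Coordinates are 1-based; strand is ignored.
#'
#' @param feature one row of a [feature_annotation()].
#' @param genotypes a [genotype_data()].
#' @param mode `"gene"` or `"junction"`.
#' @param individuals individuals to count alternative alleles over
#'   (default: all genotyped).
#' @param window window half-width; defaults to 1e6 (gene) / 1e5
#'   (junction).
#' @param min_alt_alleles minimum alternative-allele count (default 5).
#' @return character vector of SNP ids (possibly empty).
#' @export
select_cis_snps <- function(feature, genotypes, mode = c("gene", "junction"),
                            individuals = NULL, window = NULL,
                            min_alt_alleles = 5) {
  mode <- match.arg(mode)
  if (is.null(window)) window <- if (mode == "gene") 1e6 else 1e5
  pos <- genotypes$positions
  on_chrom <- pos$chrom == feature$chrom
  if (mode == "gene") {
    hit <- on_chrom & abs(pos$pos - feature$tss) <= window
  } else {
    hit <- on_chrom & (abs(pos$pos - feature$junction_start) <= window |
                         abs(pos$pos - feature$junction_end) <= window)
  }
  snps <- pos$snp_id[hit]
  if (!length(snps)) return(character(0))
  dos <- genotypes$dosages[snps, , drop = FALSE]
  if (!is.null(individuals)) dos <- dos[, individuals, drop = FALSE]
  nalt <- rowSums(dos, na.rm = TRUE)
  snps[nalt >= min_alt_alleles]
}

#' Mean-impute missing dosages per SNP
#'
#' SNPs with more than `max_missing` fraction missing are dropped.
#'
#' @param genotypes a [genotype_data()].
#' @param max_missing maximum tolerated missing fraction (default 0.1).
#' @return a [genotype_data()] with complete dosages; attribute
#'   `dropped_snps` lists removals.
#' @export
impute_dosages <- function(genotypes, max_missing = 0.1) {
  dos <- genotypes$dosages
  fr <- rowMeans(is.na(dos))
  keep <- fr <= max_missing
  dos <- dos[keep, , drop = FALSE]
  for (i in seq_len(nrow(dos))) {
    j <- is.na(dos[i, ])
    if (any(j)) dos[i, j] <- mean(dos[i, !j])
  }
  g <- genotypes
  g$dosages <- dos
  g$positions <- g$positions[keep, , drop = FALSE]
  attr(g, "dropped_snps") <- rownames(genotypes$dosages)[!keep]
  g
}
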