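#' @keywords internal
"_PACKAGE"

# Classed error helper: every validation failure carries a distinct condition
# class so callers (and tests) can discriminate failure modes.
stop_respqtl <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "respqtl_error"), call = call))
}

#' Sample design: sample -> (individual, condition)
#'
#' Describes the experimental layout of a multi-condition study with repeat
#' measures: each RNA-seq sample belongs to exactly one individual and one
#' ordered condition (e.g. drug concentration). The design implies the two
#' indicator matrices used throughout the mixed models: `V` (sample x
#' condition membership) and `U` (sample x sample, same-individual).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param individual_id character vector, same length, individual of origin.
#' @param condition integer condition index in `1..C` (ordered, e.g. by
#'   increasing concentration).
#' @param condition_value optional numeric value of the condition (e.g. uM).
#' @return A `sample_design` data frame.
#' @export
sample_design <- function(sample_id, individual_id, condition,
                          condition_value = NULL) {
  sample_id <- as.character(sample_id)
  individual_id <- as.character(individual_id)
  condition <- as.integer(condition)
  if (anyDuplicated(sample_id))
    stop_respqtl("duplicate sample ids", "respqtl_duplicate_id")
  if (length(individual_id) != length(sample_id) ||
      length(condition) != length(sample_id))
    stop_respqtl("sample_id, individual_id, condition lengths differ",
                 "respqtl_dimension_mismatch")
  C <- max(condition)
  if (C < 2L)
    stop_respqtl("need at least 2 conditions", "respqtl_invalid_design")
  if (any(condition < 1L))
    stop_respqtl("condition indices must be >= 1", "respqtl_invalid_design")
  d <- data.frame(sample_id = sample_id, individual_id = individual_id,
                  condition = condition, stringsAsFactors = FALSE)
  d$condition_value <- if (is.null(condition_value)) NA_real_
                       else as.numeric(condition_value)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Number of conditions in a design
#' @param design a [sample_design()].
#' @return integer C.
#' @export
n_conditions <- function(design) max(design$condition)

#' Condition indicator matrix V (samples x conditions)
#'
#' `V[s, c] = 1` iff sample `s` was assayed in condition `c`.
#' @param design a [sample_design()].
#' @return 0/1 matrix, samples x C.
#' @export
condition_matrix <- function(design) {
  C <- n_conditions(design)
  V <- matrix(0, nrow(design), C,
              dimnames = list(design$sample_id, paste0("c", seq_len(C))))
  V[cbind(seq_len(nrow(design)), design$condition)] <- 1
  V
}

#' Same-individual indicator matrix U (samples x samples)
#'
#' `U[s, s'] = 1` iff samples `s` and `s'` come from the same individual;
#' symmetric with unit diagonal.
#' @param design a [sample_design()].
#' @return 0/1 symmetric matrix.
#' @export
individual_matrix <- function(design) {
  ind <- design$individual_id
  U <- outer(ind, ind, "==") * 1
  dimnames(U) <- list(design$sample_id, design$sample_id)
  U
}

#' Expression matrix container
#'
#' A features x samples numeric matrix together with its normalization
#' state. States form a pipeline: `raw_counts` -> `log2cpm`
#' (via [filter_and_normalize()]) -> `quantile_normal`
#' (via [quantile_normalize_features()]).
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param state one of `"raw_counts"`, `"log2cpm"`, `"quantile_normal"`.
#' @param design optional [sample_design()]; if given, columns are checked
#'   against it.
#' @return An `expr_matrix` object (list with `values`, `state`).
#' @export
expr_matrix <- function(values, state = c("raw_counts", "log2cpm",
                                          "quantile_normal"),
                        design = NULL) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop_respqtl("expression matrix needs sample column names",
                 "respqtl_invalid_expression")
  if (!is.null(design)) {
    if (!identical(colnames(values), design$sample_id))
      stop_respqtl("expression columns do not match design sample ids",
                   "respqtl_dimension_mismatch")
  }
  if (state != "raw_counts" && anyNA(values))
    stop_respqtl("missing values not allowed after preprocessing",
                 "respqtl_invalid_expression")
  structure(list(values = values, state = state), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Genotype data: SNP dosages plus kinship
#'
#' @param dosages numeric matrix SNPs x individuals with entries in
#'   \{0, 1, 2\} or `NA`; rownames are SNP ids, colnames individual ids.
#' @param positions data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based).
#' @param kinship symmetric positive semi-definite individuals x
#'   individuals matrix (expected genetic covariance, i.e. twice the
#'   kinship coefficient); if `NULL`, computed from the dosages as the
#'   standardized-genotype cross-product divided by the SNP count.
#' @return A `genotype_data` object.
#' @export
genotype_data <- function(dosages, positions, kinship = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop_respqtl("dosage matrix needs SNP rownames and individual colnames",
                 "respqtl_invalid_genotypes")
  bad <- which(!is.na(dosages) & !(dosages %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_respqtl(sprintf(
      "dosage outside {0,1,2}: SNP %s, individual %s (value %g)",
      rownames(dosages)[bad[1, 1]], colnames(dosages)[bad[1, 2]],
      dosages[bad[1, , drop = FALSE]]), "respqtl_invalid_dosage")
  }
  positions <- as.data.frame(positions)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(positions)))
    stop_respqtl("positions must have snp_id, chrom, pos",
                 "respqtl_invalid_genotypes")
  if (!setequal(positions$snp_id, rownames(dosages)) ||
      anyDuplicated(positions$snp_id))
    stop_respqtl("positions and dosage SNP ids disagree",
                 "respqtl_dimension_mismatch")
  positions <- positions[match(rownames(dosages), positions$snp_id), ]
  if (any(positions$pos <= 0))
    stop_respqtl("positions must be positive (1-based)",
                 "respqtl_invalid_genotypes")
  if (is.null(kinship)) {
    kinship <- kinship_from_dosages(dosages)
  } else {
    kinship <- as.matrix(kinship)
    if (nrow(kinship) != ncol(dosages) || ncol(kinship) != ncol(dosages))
      stop_respqtl("kinship dimension does not match individuals",
                   "respqtl_dimension_mismatch")
    if (max(abs(kinship - t(kinship))) > 1e-8)
      stop_respqtl("kinship matrix is not symmetric",
                   "respqtl_asymmetric_kinship")
    kinship <- (kinship + t(kinship)) / 2
    ev <- eigen(kinship, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop_respqtl("kinship matrix is not positive semi-definite",
                   "respqtl_invalid_kinship")
    dimnames(kinship) <- list(colnames(dosages), colnames(dosages))
  }
  structure(list(dosages = dosages, positions = positions,
                 kinship = kinship), class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data> %d SNPs x %d individuals\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Empirical kinship from standardized dosages
#'
#' Fallback when no pedigree kinship is available: per-SNP standardized
#' genotypes (mean-imputed, centered, scaled by sqrt(2 p (1-p))) averaged
#' into a cross-product matrix. Small negative eigenvalues (> -1e-8) are
#' clipped to zero.
#'
#' @param dosages SNPs x individuals matrix in \{0,1,2\}/NA.
#' @return individuals x individuals PSD matrix.
#' @export
kinship_from_dosages <- function(dosages) {
  Z <- t(apply(dosages, 1, function(d) {
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    p <- mean(d) / 2
    s <- sqrt(2 * p * (1 - p))
    if (s < .Machine$double.eps) rep(0, length(d)) else (d - 2 * p) / s
  }))
  K <- crossprod(Z) / nrow(dosages)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  K <- e$vectors %*% (lam * t(e$vectors))
  dimnames(K) <- list(colnames(dosages), colnames(dosages))
  K
}

#' Feature annotation table
#'
#' Gene TSS coordinates (for the 1 Mb cis window) or splice-junction end
#' coordinates (for the 100 kb window).
#'
#' @param feature_id,chrom character vectors.
#' @param tss 1-based TSS position (gene features), or `NA`.
#' @param junction_start,junction_end 1-based junction ends (introns), or
#'   `NA`.
#' @param strand `"+"`, `"-"` or `"*"`; ignored for window computation.
#' @return A `feature_annotation` data frame.
#' @export
feature_annotation <- function(feature_id, chrom, tss = NA,
                               junction_start = NA, junction_end = NA,
                               strand = "*") {
  d <- data.frame(feature_id = as.character(feature_id),
                  chrom = as.character(chrom),
                  tss = as.numeric(tss),
                  junction_start = as.numeric(junction_start),
                  junction_end = as.numeric(junction_end),
                  strand = strand, stringsAsFactors = FALSE)
  coords <- c(d$tss, d$junction_start, d$junction_end)
  if (any(coords[!is.na(coords)] <= 0))
    stop_respqtl("annotation coordinates must be positive",
                 "respqtl_invalid_annotation")
  if (anyDuplicated(d$feature_id))
    stop_respqtl("duplicate feature ids", "respqtl_duplicate_id")
  class(d) <- c("feature_annotation", "data.frame")
  d
}

#' Splicing phenotype: one alternative-splicing cluster (ASC)
#'
#' Junction read counts for the introns of one ASC across samples. The raw
#' excision ratio psi of an intron in a sample is its count divided by the
#' ASC total in that sample, so raw psi sums to 1 over introns.
#'
#' @param cluster_id ASC identifier.
#' @param counts intron x sample nonnegative count matrix; rownames are
#'   intron ids.
#' @return A `splicing_phenotype` object.
#' @export
splicing_phenotype <- function(cluster_id, counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts))
    stop_respqtl("junction counts must be nonnegative and complete",
                 "respqtl_invalid_splicing")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0(cluster_id, "_i", seq_len(nrow(counts)))
  structure(list(cluster_id = cluster_id, counts = counts),
            class = "splicing_phenotype")
}

#' Phased allelic count table
#'
#' Alternative-allele and total read counts at exonic SNPs, with the phased
#' heterozygosity `phase` of the test regulatory SNP: 0 if the regulatory
#' SNP is homozygous in that individual, +1/-1 if heterozygous and in
#' phase/anti-phase with the exonic SNP's alternative allele.
#'
#' @param gene,exonic_snp,individual character vectors.
#' @param condition integer condition index.
#' @param alt,total nonnegative integer counts with `alt <= total`.
#' @param phase integer in \{-1, 0, 1\}, constant per
#'   (individual, exonic SNP).
#' @return An `allelic_count_table` data frame.
#' @export
allelic_count_table <- function(gene, exonic_snp, individual, condition,
                                alt, total, phase) {
  d <- data.frame(gene = as.character(gene),
                  exonic_snp = as.character(exonic_snp),
                  individual = as.character(individual),
                  condition = as.integer(condition),
                  alt = as.integer(alt), total = as.integer(total),
                  phase = as.integer(phase), stringsAsFactors = FALSE)
  if (any(d$alt < 0) || any(d$total < 0) || any(d$alt > d$total))
    stop_respqtl("need 0 <= alt <= total", "respqtl_invalid_counts")
  if (!all(d$phase %in% c(-1L, 0L, 1L)))
    stop_respqtl("phase must be in {-1, 0, 1}", "respqtl_invalid_phase")
  ph <- tapply(d$phase, paste(d$individual, d$exonic_snp), function(x)
    length(unique(x)))
  if (any(ph > 1))
    stop_respqtl("phase must be constant per (individual, exonic SNP)",
                 "respqtl_invalid_phase")
  class(d) <- c("allelic_count_table", "data.frame")
  d
}
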