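# File readers/writers. All tabular output is TSV with a header line; a
# leading '#' comment block carries provenance. Matrices round-trip at full
# double precision (15 significant digits).

#' Write a numeric matrix as TSV
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param comment optional character vector written as leading `#` lines.
#' @export
write_tsv_matrix <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  header <- paste(c("id", colnames(x)), collapse = "\t")
  writeLines(header, con)
  body <- apply(format(x, digits = 15, scientific = TRUE, trim = TRUE), 1,
                paste, collapse = "\t")
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a numeric matrix written by [write_tsv_matrix()]
#' @param path TSV path (first column = row ids, `#` lines skipped).
#' @return numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read genotype dosages from a VCF
#'
#' Unphased or phased diploid GT fields are converted to alternative-allele
#' dosages: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`; missing genotypes become
#' `NA`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param kinship optional kinship matrix (individuals x individuals); if
#'   absent, computed from the dosages.
#' @return A [genotype_data()] object.
#' @export
read_vcf_genotypes <- function(path, kinship = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(as.numeric(al) > 0)
  })
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(dos) <- ids
  genotype_data(dos,
                positions = data.frame(snp_id = ids,
                                       chrom = fix[, "CHROM"],
                                       pos = as.numeric(fix[, "POS"]),
                                       stringsAsFactors = FALSE),
                kinship = kinship)
}

#' Load and cross-reference all study inputs
#'
#' Reads the count matrix, sample design, genotypes (VCF or dosage TSV),
#' optional kinship TSV and feature annotation TSV, checks mutual
#' consistency (shared individual ordering, matching sample ids) and
#' returns consistently ordered objects. Any unknown sample or individual
#' ids are reported in the error.
#'
#' @param counts path to features x samples count TSV.
#' @param design path to design TSV with columns sample_id, individual_id,
#'   condition, and optionally condition_value.
#' @param vcf,dosages genotype source: a VCF path or a SNPs x individuals
#'   dosage TSV (exactly one required). A dosage TSV must be accompanied by
#'   a `positions` TSV (snp_id, chrom, pos) unless the dosage file carries
#'   `chrom`/`pos` columns.
#' @param kinship optional square kinship TSV; if absent, kinship is
#'   computed from the dosages.
#' @param annotation optional feature annotation TSV (feature_id, chrom,
#'   then tss or junction_start/junction_end, optional strand).
#' @param positions optional SNP position TSV for the dosage-TSV route.
#' @return list with elements `counts` ([expr_matrix()], raw),
#'   `design`, `genotypes`, `annotation` (or `NULL`).
#' @export
load_inputs <- function(counts, design, vcf = NULL, dosages = NULL,
                        kinship = NULL, annotation = NULL,
                        positions = NULL) {
  des <- utils::read.delim(design, comment.char = "#",
                           stringsAsFactors = FALSE)
  des <- sample_design(des$sample_id, des$individual_id, des$condition,
                       des$condition_value)
  cnt <- read_tsv_matrix(counts)
  missing_samp <- setdiff(des$sample_id, colnames(cnt))
  extra_samp <- setdiff(colnames(cnt), des$sample_id)
  if (length(missing_samp) || length(extra_samp))
    stop_respqtl(paste0("count/design sample mismatch; missing: ",
                        paste(missing_samp, collapse = ","),
                        "; unknown: ", paste(extra_samp, collapse = ",")),
                 "respqtl_unknown_sample")
  cnt <- cnt[, des$sample_id, drop = FALSE]

  kin <- if (!is.null(kinship)) read_tsv_matrix(kinship) else NULL
  if (!is.null(vcf)) {
    geno <- read_vcf_genotypes(vcf, kinship = kin)
  } else if (!is.null(dosages)) {
    d <- utils::read.delim(dosages, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
    poscols <- intersect(c("chrom", "pos"), names(d))
    if (length(poscols) == 2) {
      pos <- data.frame(snp_id = as.character(d[[1]]), chrom = d$chrom,
                        pos = d$pos, stringsAsFactors = FALSE)
      dm <- as.matrix(d[, setdiff(names(d), c(names(d)[1], "chrom", "pos")),
                        drop = FALSE])
    } else {
      if (is.null(positions))
        stop_respqtl("dosage TSV needs chrom/pos columns or a positions file",
                     "respqtl_invalid_genotypes")
      pos <- utils::read.delim(positions, comment.char = "#",
                               stringsAsFactors = FALSE)
      dm <- as.matrix(d[, -1, drop = FALSE])
    }
    rownames(dm) <- as.character(d[[1]])
    geno <- genotype_data(dm, pos, kinship = kin)
  } else {
    stop_respqtl("provide either vcf or dosages", "respqtl_invalid_genotypes")
  }

  unknown_ind <- setdiff(des$individual_id, colnames(geno$dosages))
  if (length(unknown_ind))
    stop_respqtl(paste0("design individuals absent from genotypes: ",
                        paste(unknown_ind, collapse = ",")),
                 "respqtl_unknown_individual")

  ann <- NULL
  if (!is.null(annotation)) {
    a <- utils::read.delim(annotation, comment.char = "#",
                           stringsAsFactors = FALSE)
    ann <- feature_annotation(
      a$feature_id, a$chrom,
      tss = if ("tss" %in% names(a)) a$tss else NA,
      junction_start = if ("junction_start" %in% names(a))
        a$junction_start else NA,
      junction_end = if ("junction_end" %in% names(a))
        a$junction_end else NA,
      strand = if ("strand" %in% names(a)) a$strand else "*")
  }
  list(counts = expr_matrix(cnt, "raw_counts", design = des),
       design = des, genotypes = geno, annotation = ann)
}
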