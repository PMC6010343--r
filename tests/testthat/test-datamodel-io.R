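# Domain types, validation, file round-trips, preprocessing.

test_that("validators raise distinct, named errors", {
  dos <- matrix(c(0, 1, 3, 2), 2, 2,
                dimnames = list(c("snpA", "snpB"), c("i1", "i2")))
  pos <- data.frame(snp_id = c("snpA", "snpB"), chrom = "chr1",
                    pos = c(100, 200))
  err <- expect_error(genotype_data(dos, pos),
                      class = "respqtl_invalid_dosage")
  expect_match(conditionMessage(err), "snpA")  # offending SNP named
  expect_match(conditionMessage(err), "i2")    # offending individual named

  dos[dos == 3] <- 1
  K <- diag(2); K[1, 2] <- 0.2  # asymmetric beyond 1e-8
  expect_error(genotype_data(dos, pos, kinship = K),
               class = "respqtl_asymmetric_kinship")
  Kbad <- matrix(c(1, 2, 2, 1), 2, 2)  # symmetric but indefinite
  expect_error(genotype_data(dos, pos, kinship = Kbad),
               class = "respqtl_invalid_kinship")

  expect_error(sample_design(c("s1", "s1"), c("i1", "i1"), c(1, 2)),
               class = "respqtl_duplicate_id")
  expect_error(sample_design("s1", "i1", 1),
               class = "respqtl_invalid_design")  # C < 2
  expect_error(allelic_count_table("g", "e", "i", 1, alt = 5, total = 3,
                                   phase = 1),
               class = "respqtl_invalid_counts")
})

test_that("design indicator matrices satisfy their invariants", {
  des <- tiny_design(4, 3)
  V <- condition_matrix(des)
  U <- individual_matrix(des)
  expect_true(all(V %in% c(0, 1)))
  expect_equal(rowSums(V), rep(1, nrow(des)), ignore_attr = TRUE)
  expect_identical(U, t(U))
  expect_equal(unname(diag(U)), rep(1, nrow(des)))
})

test_that("VCF GT fields become dosages 0/1/2 and missing stays NA", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ind1", "ind2", "ind3", sep = "\t"),
    paste("chr1", "1000", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "2000", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0|1", "./.", "0/0", sep = "\t")), vcf)
  g <- read_vcf_genotypes(vcf)
  expect_equal(unname(g$dosages["rs1", ]), c(0, 1, 2))
  expect_equal(unname(g$dosages["rs2", ]), c(1, NA, 0))
  expect_equal(g$positions$pos, c(1000, 2000))
})

test_that("matrix TSV writing round-trips at full precision", {
  set.seed(7)
  m <- matrix(rnorm(12) * 10 ^ sample(-6:6, 12, TRUE), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  f <- tempfile(fileext = ".tsv")
  write_tsv_matrix(m, f, comment = "test output")
  m2 <- read_tsv_matrix(f)
  expect_equal(m2, m, tolerance = 1e-12)
})

test_that("load_inputs cross-references and reports unknown ids", {
  dir <- tempfile(); dir.create(dir)
  des <- tiny_design(3, 2)
  cnt <- matrix(rpois(4 * nrow(des), 50), 4, nrow(des),
                dimnames = list(paste0("g", 1:4), des$sample_id))
  write_tsv_matrix(cnt, file.path(dir, "counts.tsv"))
  write.table(as.data.frame(des), file.path(dir, "design.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  dos <- matrix(rbinom(2 * 3, 2, 0.5), 2, 3,
                dimnames = list(c("snp1", "snp2"), unique(des$individual_id)))
  d <- data.frame(snp_id = rownames(dos), chrom = "chr1", pos = c(10, 20),
                  dos, check.names = FALSE)
  write.table(d, file.path(dir, "dosages.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  inp <- load_inputs(counts = file.path(dir, "counts.tsv"),
                     design = file.path(dir, "design.tsv"),
                     dosages = file.path(dir, "dosages.tsv"))
  expect_s3_class(inp$counts, "expr_matrix")
  expect_identical(colnames(inp$counts$values), inp$design$sample_id)
  # a sample missing from the counts is reported by name
  write_tsv_matrix(cnt[, -1], file.path(dir, "counts2.tsv"))
  err <- expect_error(
    load_inputs(counts = file.path(dir, "counts2.tsv"),
                design = file.path(dir, "design.tsv"),
                dosages = file.path(dir, "dosages.tsv")),
    class = "respqtl_unknown_sample")
  expect_match(conditionMessage(err), des$sample_id[1])
})

test_that("read-depth and median-log2cpm filters apply in the stated order", {
  des <- tiny_design(3, 2)  # 6 samples
  n <- nrow(des)
  cnt <- matrix(2e6, 4, n, dimnames = list(paste0("g", 1:4), des$sample_id))
  cnt[1, ] <- 5e6          # high gene
  cnt[2, ] <- 2            # low gene: log2cpm << 0
  cnt[3, ] <- 3e6
  # sample 1 one read short of the threshold
  tot <- colSums(cnt)
  cnt[4, ] <- 1e7 - tot[1] + cnt[4, 1] - 1
  cnt[4, 1] <- cnt[4, 1]  # column 1 total = 9,999,999
  cnt[4, -1] <- cnt[4, -1] + 10  # others just above
  em <- expr_matrix(cnt, "raw_counts", design = des)
  res <- filter_and_normalize(em, des)
  expect_identical(res$removed_samples, des$sample_id[1])
  expect_true("g2" %in% res$removed_genes)
  expect_false("g1" %in% res$removed_genes)
  expect_identical(res$expr$state, "log2cpm")
  # cpm definition: count 2 at library 1e6 -> log2(cpm) = 1
  cnt2 <- matrix(c(2, 1e6 - 2), 2, 1,
                 dimnames = list(c("gA", "gB"), "s1"))
  cpm <- 2 / (1e6 / 1e6)
  expect_equal(log2(cpm), 1)
  # all samples filtered -> classed error
  expect_error(filter_and_normalize(
    expr_matrix(matrix(1, 1, n,
                       dimnames = list("g", des$sample_id)),
                "raw_counts"), des),
    class = "respqtl_all_filtered")
})

test_that("rankit quantile normalization matches its closed form", {
  em <- expr_matrix(matrix(c(5, 1, 9), 1, 3,
                           dimnames = list("g1", c("a", "b", "c"))),
                    "log2cpm")
  qn <- quantile_normalize_features(em)
  expect_equal(unname(qn$values[1, ]),
               c(0, -qnorm(5 / 6), qnorm(5 / 6)))
  # rank order preserved; mean exactly 0 by rankit symmetry
  set.seed(3)
  x <- matrix(rnorm(217), 1, 217,
              dimnames = list("g", paste0("s", 1:217)))
  qn2 <- quantile_normalize_features(x)
  expect_identical(order(qn2$values[1, ]), order(x[1, ]))
  expect_lt(abs(mean(qn2$values[1, ])), 1e-6)
  expect_lt(abs(sd(qn2$values[1, ]) - 1), 0.05)
  # idempotent up to tie handling
  qn3 <- quantile_normalize_features(qn2$values)
  expect_lt(max(abs(qn3$values - qn2$values)), 1e-12)
  # constant row flagged degenerate, set to zero
  qn4 <- quantile_normalize_features(matrix(2, 1, 5,
                                            dimnames = list("g", 1:5)))
  expect_equal(unname(qn4$values[1, ]), rep(0, 5))
  expect_identical(attr(qn4, "degenerate"), "g")
})

test_that("splicing phenotypes follow the pseudocount and imputation rules", {
  cnt <- rbind(i1 = c(3, 0, 6), i2 = c(1, 0, 2))
  colnames(cnt) <- paste0("s", 1:3)
  asc <- splicing_phenotype("clu1", cnt)
  # pseudocount arithmetic: counts (3,1) -> psi (0.7, 0.3)
  psi <- (cnt[, 1] + 0.5) / (sum(cnt[, 1]) + 0.5 * 2)
  expect_equal(unname(psi), c(0.7, 0.3))
  # raw psi sums to 1 before adjustment
  expect_equal(sum(cnt[, 1] / sum(cnt[, 1])), 1)
  single <- splicing_phenotype("clu2", matrix(5, 1, 3,
                                              dimnames = list("j", 1:3)))
  prep <- prepare_splicing_phenotypes(list(asc, single))
  expect_identical(attr(prep, "excluded_ascs"), "clu2")
  expect_equal(nrow(prep$values), 2)
  expect_identical(prep$state, "quantile_normal")
  # sample 2 (zero ASC total) was imputed to the intron mean over the other
  # samples: its rank must fall strictly between the two observed samples
  psi_full <- sweep(cnt + 0.5, 2, colSums(cnt) + 1, "/")
  expect_true(psi_full[1, 3] > psi_full[1, 1])
  expect_equal(order(prep$values[1, ]), c(1, 2, 3))
})

test_that("z-scored splicing rows have mean 0 and SD 1 before rank-normalization", {
  set.seed(5)
  cnt <- matrix(rpois(3 * 8, 20), 3, 8,
                dimnames = list(paste0("i", 1:3), paste0("s", 1:8)))
  asc <- splicing_phenotype("clu", cnt)
  psi <- sweep(cnt + 0.5, 2, colSums(cnt) + 0.5 * 3, "/")
  z <- t(scale(t(psi)))
  expect_equal(unname(rowMeans(z)), rep(0, 3))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 3))
})

test_that("cis windows are inclusive and respect the alt-allele rule", {
  tss <- 5e6
  pos <- c(tss + 999999, tss + 1e6, tss + 1000001, tss - 1e6, 100)
  dos <- matrix(1, 5, 6,
                dimnames = list(paste0("snp", 1:5), paste0("ind", 1:6)))
  dos[5, ] <- 1
  g <- genotype_data(dos,
                     data.frame(snp_id = rownames(dos),
                                chrom = c(rep("chr1", 4), "chr2"),
                                pos = pos),
                     kinship = diag(6))
  feat <- feature_annotation("geneA", "chr1", tss = tss)
  hits <- select_cis_snps(feat[1, ], g, mode = "gene")
  expect_true(all(c("snp1", "snp2", "snp4") %in% hits))  # boundary inclusive
  expect_false("snp3" %in% hits)                          # 1 bp outside
  expect_false("snp5" %in% hits)                          # other chromosome
  # fewer than 5 alternative alleles -> excluded
  dos2 <- dos; dos2["snp1", ] <- c(1, 1, 1, 1, 0, 0)     # 4 alt alleles
  g2 <- genotype_data(dos2, g$positions, kinship = diag(6))
  expect_false("snp1" %in% select_cis_snps(feat[1, ], g2, mode = "gene"))
  dos3 <- dos; dos3["snp1", ] <- c(1, 1, 1, 1, 1, 0)     # exactly 5: kept
  g3 <- genotype_data(dos3, g$positions, kinship = diag(6))
  expect_true("snp1" %in% select_cis_snps(feat[1, ], g3, mode = "gene"))
  # junction mode: within 100 kb of either end
  featj <- feature_annotation("intron1", "chr1", junction_start = 2e6,
                              junction_end = 2.4e6)
  gj <- genotype_data(
    matrix(1, 3, 6, dimnames = list(paste0("j", 1:3), paste0("ind", 1:6))),
    data.frame(snp_id = paste0("j", 1:3), chrom = "chr1",
               pos = c(2e6 - 1e5, 2.2e6, 2.4e6 + 1e5 + 1)),
    kinship = diag(6))
  hj <- select_cis_snps(featj[1, ], gj, mode = "junction")
  expect_true("j1" %in% hj)    # exactly at the window edge
  expect_false("j2" %in% hj)   # between ends but > 100 kb from both
  expect_false("j3" %in% hj)   # 1 bp outside
})

test_that("missing dosages are mean-imputed and high-missingness SNPs dropped", {
  dos <- matrix(c(0, 1, 2, NA,
                  NA, NA, 0, 1), 2, 4, byrow = TRUE,
                dimnames = list(c("ok", "bad"), paste0("i", 1:4)))
  g <- genotype_data(dos,
                     data.frame(snp_id = c("ok", "bad"), chrom = "chr1",
                                pos = c(1, 2)),
                     kinship = diag(4))
  gi <- impute_dosages(g, max_missing = 0.3)
  expect_identical(attr(gi, "dropped_snps"), "bad")
  expect_equal(unname(gi$dosages["ok", "i4"]), 1)  # mean of 0,1,2
})
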