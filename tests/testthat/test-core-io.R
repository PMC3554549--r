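# I/O layer: VCF reading, coordinate mapping, GMT parsing, round trips.

write_test_vcf <- function(path, samples, records) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               records), path)
  path
}

test_gene_models <- function(path) {
  writeLines(c("gene\tchrom\tstart\tend\tstrand\tframe",
               "geneA\tchr1\t0\t1500\t+\t0",
               "geneB\tchr2\t100\t400\t-\t0"), path)
  path
}

test_that("VCF genotypes load with GT arithmetic and sample restriction", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c("S1", "S2", "S3"),
                        "chr1\t10\trs1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1")
  gm <- read_gene_models(test_gene_models(tempfile(fileext = ".tsv")))
  pheno <- data.frame(sample = c("S1", "S2", "S3"),
                      status = c("case", "case", "control"),
                      stratum = NA)
  g <- read_vcf_genotypes(vcf, pheno, gm)
  expect_equal(unname(g$G[, 1]), c(0L, 1L, 2L))
  expect_equal(g$variants$gene, "geneA")
  expect_equal(g$variants$codon_index, 3L)  # pos 10 -> offset 9 -> codon 3
})

test_that("missing genotypes impute to zero and are counted", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c("S1", "S2", "S3"),
                        "chr1\t10\trs1\tA\tG\t.\t.\t.\tGT\t./.\t0/1\t0/1")
  gm <- read_gene_models(test_gene_models(tempfile(fileext = ".tsv")))
  pheno <- data.frame(sample = c("S1", "S2", "S3"),
                      status = c("case", "case", "control"), stratum = NA)
  g <- suppressMessages(read_vcf_genotypes(vcf, pheno, gm))
  expect_equal(unname(g$G[, 1]), c(0L, 1L, 1L))
  expect_equal(attr(g, "missingness"), 1L)
})

test_that("multiallelic records split into biallelic variants", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c("S1", "S2"),
                        "chr1\t10\trs1\tA\tG,T\t.\t.\t.\tGT\t1/2\t0/1")
  gm <- read_gene_models(test_gene_models(tempfile(fileext = ".tsv")))
  pheno <- data.frame(sample = c("S1", "S2"),
                      status = c("case", "control"), stratum = NA)
  g <- read_vcf_genotypes(vcf, pheno, gm)
  expect_equal(ncol(g$G), 2L)
  expect_equal(unname(g$G[, 1]), c(1L, 1L))  # allele G
  expect_equal(unname(g$G[, 2]), c(1L, 0L))  # allele T
  expect_equal(g$variants$id, c("rs1_G", "rs1_T"))
})

test_that("sample absent from the VCF is a named hard error", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c("S1", "S2"),
                        "chr1\t10\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t0/1")
  gm <- read_gene_models(test_gene_models(tempfile(fileext = ".tsv")))
  pheno <- data.frame(sample = c("S1", "S9"),
                      status = c("case", "control"), stratum = NA)
  expect_error(read_vcf_genotypes(vcf, pheno, gm), "S9")
})

test_that("variants outside gene models drop; none retained is an error", {
  gm <- read_gene_models(test_gene_models(tempfile(fileext = ".tsv")))
  pheno <- data.frame(sample = c("S1", "S2"),
                      status = c("case", "control"), stratum = NA)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c("S1", "S2"),
                        c("chr1\t10\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t0/0",
                          "chr9\t10\trs2\tA\tG\t.\t.\t.\tGT\t0/1\t0/1"))
  g <- suppressMessages(read_vcf_genotypes(vcf, pheno, gm))
  expect_equal(ncol(g$G), 1L)
  vcf2 <- write_test_vcf(tempfile(fileext = ".vcf"), c("S1", "S2"),
                         "chr9\t10\trs2\tA\tG\t.\t.\t.\tGT\t0/1\t0/1")
  expect_error(suppressMessages(read_vcf_genotypes(vcf2, pheno, gm)),
               "no biallelic")
})

test_that("minus-strand CDS offsets reverse genomic order", {
  # geneB: chr2 [100, 400), minus strand; genomic position 399 (1-based
  # 400) is the first CDS base -> codon 0; position 100 (1-based 101) is
  # the last -> codon 99
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c("S1", "S2"),
                        c("chr2\t400\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t0/0",
                          "chr2\t101\trs2\tA\tG\t.\t.\t.\tGT\t0/0\t0/1"))
  gm <- read_gene_models(test_gene_models(tempfile(fileext = ".tsv")))
  pheno <- data.frame(sample = c("S1", "S2"),
                      status = c("case", "control"), stratum = NA)
  g <- read_vcf_genotypes(vcf, pheno, gm)
  expect_equal(g$variants$codon_index[g$variants$id == "rs1"], 0L)
  expect_equal(g$variants$codon_index[g$variants$id == "rs2"], 99L)
})

test_that("codon mapping follows floor(offset / 3) with bounds checks", {
  expect_equal(map_variant_to_codon(0, 1500), 0L)
  expect_equal(map_variant_to_codon(1499, 1500), 499L)
  expect_equal(map_variant_to_codon(c(2, 3, 5), 9), c(0L, 1L, 1L))
  expect_error(map_variant_to_codon(1500, 1500))
  expect_error(map_variant_to_codon(-1, 1500))
})

test_that("GMT parsing retains empty genes and rejects malformed files", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tgeneA\tgeneB\tgeneC",
               "setB\tdesc\tgeneA\tgeneZ"), gmt)
  sets <- read_gene_sets(gmt)
  expect_named(sets, c("setA", "setB"))
  expect_length(sets$setA, 3L)
  dup <- tempfile(fileext = ".gmt")
  writeLines(c("setA\td\tg1", "setA\td\tg2"), dup)
  expect_error(read_gene_sets(dup), "duplicate")
  short <- tempfile(fileext = ".gmt")
  writeLines("setA\tdesc", short)
  expect_error(read_gene_sets(short), "fewer than one gene")
})

test_that("functional groups keep set genes that carry no variants", {
  G <- matrix(c(0L, 1L), 2, 1)
  g <- tiny_genotypes(G, codons = 0L, gene = "geneA")
  lens <- c(geneA = 500L, geneB = 500L)
  gr <- functional_groups(g, lens, sets = list(s1 = c("geneA", "geneB")))
  expect_length(gr$s1$genes, 2L)
  expect_length(gr$s1$genes[[2]]$variant_idx, 0L)
})

test_that("genotype TSV round trip is exact", {
  set.seed(1)
  G <- matrix(sample(0:2, 30, replace = TRUE, prob = c(.7, .2, .1)), 6, 5)
  g <- tiny_genotypes(G, codons = c(0L, 5L, 10L, 40L, 499L))
  path <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, path)
  g2 <- read_genotypes_tsv(path)
  expect_identical(unname(g2$G), unname(g$G))
  expect_equal(g2$variants$codon_index, g$variants$codon_index)
  expect_equal(g2$samples, g$samples)
})

test_that("column allele sums match case plus control allele counts", {
  set.seed(2)
  G <- matrix(sample(0:2, 40, replace = TRUE), 8, 5)
  g <- tiny_genotypes(G, codons = 0:4)
  st <- tiny_sample_table(4, 4)
  case <- st$status == "case"
  a_case <- colSums(g$G[case, , drop = FALSE])
  a_ctrl <- colSums(g$G[!case, , drop = FALSE])
  expect_equal(a_case + a_ctrl, colSums(g$G))
})

test_that("genotype container rejects invalid values", {
  v <- data.frame(id = "v1", gene = "g", codon_index = 0L)
  expect_error(bomp_genotypes(matrix(3L, 1, 1), v, "S1"), "0, 1, 2")
  expect_error(bomp_genotypes(matrix(0.5, 1, 1), v, "S1"), "0, 1, 2")
})
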