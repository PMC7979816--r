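vcf_text <- function(records, samples = c("S1", "S2", "S3")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("read_vcf parses diploid GT fields into 0/1/2/missing codes", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_text(c(
    paste(c("1A", 100, ".", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("1A", 200, ".", "C", "T", ".", "PASS", ".", "GT",
            "0/0", "./.", "0/1"), collapse = "\t"))), f)
  gm <- suppressMessages(read_vcf(f))
  expect_identical(unname(gm$geno),
                   matrix(c(0L, 1L, 2L, 0L, NA, 1L), nrow = 3))
  expect_identical(gm$sites$pos, c(100L, 200L))
  expect_identical(gm$samples$sample_id, c("S1", "S2", "S3"))
})

test_that("read_vcf drops multi-allelic and non-SNP records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  rec <- function(pos, ref, alt)
    paste(c("2B", pos, ".", ref, alt, ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t")
  writeLines(vcf_text(c(rec(1, "A", "G"), rec(2, "C", "T"),
                        rec(3, "A", "G,T"), rec(4, "G", "A"),
                        rec(5, "T", "C"))), f)
  gm <- suppressMessages(read_vcf(f))
  expect_equal(ncol(gm$geno), 4L)
  expect_identical(gm$sites$pos, c(1L, 2L, 4L, 5L))
})

test_that("header-only VCF yields an explicit empty result", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_text(character(0)), f)
  expect_warning(gm <- suppressMessages(read_vcf(f)), "no variant records")
  expect_equal(ncol(gm$geno), 0L)
})

test_that("VCF round-trip is lossless for codes, positions and alleles", {
  set.seed(11)
  geno <- matrix(sample(c(0:2, NA), 5 * 12, TRUE), nrow = 5)
  geno[, 1] <- c(0L, 1L, 2L, 0L, 1L) # guarantee one complete site
  gm <- toy_gm(geno, chrom = rep(c("3D", "5A"), each = 6),
               pos = rep(seq_len(6) * 500L, 2))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  expect_true(any(grepl("\\./\\.", readLines(f)))) # missing emitted as ./.
  back <- suppressMessages(read_vcf(f))
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_identical(back$sites[c("chrom", "pos", "ref", "alt")],
                   gm$sites[c("chrom", "pos", "ref", "alt")])
})

test_that("zero-site matrix writes a header-only VCF", {
  gm <- toy_gm(matrix(integer(0), nrow = 3, ncol = 0))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  expect_equal(sum(!startsWith(readLines(f), "#")), 0L)
})

test_that("subgenome derivation is total over chromosome names", {
  chroms <- c("1A", "7D", "chr2B", "Un", "scaffold123", "1b", "", "3C")
  out <- subgenome_of(chroms)
  expect_true(all(out %in% c("A", "B", "D", "unanchored")))
  expect_identical(out[1:3], c("A", "D", "B"))
  expect_identical(out[4:8],
                   c("unanchored", "unanchored", "unanchored",
                     "unanchored", "unanchored"))
})

test_that("read_tables types and validates phenotype, samples and GFF", {
  ph <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tglume_color", "S1\tred", "S2\twhite"), ph)
  sm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubspecies\torigin",
               "S1\tspelta\tAsia", "S2\taestivum\tCentralEurope"), sm)
  gf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1B\tsrc\tgene\t1000\t3000\t.\t+\t.\tID=gene1",
               "1B\tsrc\tCDS\t1000\t1500\t.\t+\t0\tParent=gene1",
               "1B\tsrc\tCDS\t2000\t3000\t.\t+\t0\tParent=gene1"), gf)
  tabs <- read_tables(ph, sm, gf)
  expect_length(tabs$phenotype, 2)
  expect_identical(unname(tabs$phenotype), c("red", "white"))
  expect_equal(nrow(tabs$annotation), 2)
  expect_identical(tabs$annotation$start, c(1000L, 2000L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tglume_color", "S1\tred", "S2\tpink"), bad)
  expect_error(read_phenotype(bad), "pink")
})

test_that("phenotype label 'missing' becomes NA", {
  ph <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tglume_color", "S1\tmissing"), ph)
  expect_true(is.na(read_phenotype(ph)[["S1"]]))
})

test_that("overlapping CDS intervals are merged per gene", {
  gf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("1B\tsrc\tCDS\t100\t200\t.\t+\t0\tParent=g1",
               "1B\tsrc\tCDS\t150\t300\t.\t+\t0\tParent=g1"), gf)
  ann <- read_gff_cds(gf)
  expect_equal(nrow(ann), 1)
  expect_identical(c(ann$start, ann$end), c(100L, 300L))
})

test_that("genotype_matrix enforces its invariants", {
  expect_error(toy_gm(matrix(3L, 2, 1)), "codes")
  s <- toy_samples(2); s$sample_id <- c("A", "A")
  expect_error(genotype_matrix(matrix(0L, 2, 1), s,
                               data.frame(chrom = "1A", pos = 1,
                                          ref = "A", alt = "G")),
               "duplicated")
  expect_error(toy_gm(matrix(0L, 2, 1), pos = 0L), "1-based")
  st <- data.frame(chrom = "1A", pos = 5L, ref = "A", alt = "A")
  expect_error(genotype_matrix(matrix(0L, 2, 1), toy_samples(2), st),
               "differ")
})
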