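# five samples, hand-built missingness pattern
miss_gm <- function() {
  geno <- matrix(0L, 5, 3)
  geno[2, 1] <- 1L
  geno[1, 2] <- NA  # site 2: 1/5 missing (0.2, boundary)
  geno[1:2, 3] <- NA # site 3: 2/5 missing (0.4)
  geno[3, 3] <- 2L
  toy_gm(geno)
}

test_that("site missing filter removes strictly above the threshold", {
  gm <- miss_gm()
  out <- filter_site_missing(gm, 0.2)
  expect_identical(out$sites$pos, gm$sites$pos[1:2]) # boundary site kept
  rep <- filter_report(out)
  expect_identical(c(rep$sites_before, rep$sites_after), c(3L, 2L))

  complete <- toy_gm(matrix(0:1, 4, 3))
  expect_identical(filter_site_missing(complete)$geno, complete$geno)
})

test_that("sample missing filter works on the sample axis", {
  geno <- matrix(0L, 3, 10)
  geno[1, 1:3] <- NA # 0.3 missing -> out
  geno[2, 1:2] <- NA # 0.2 boundary -> kept
  gm <- toy_gm(geno)
  out <- filter_sample_missing(gm, 0.2)
  expect_identical(out$samples$sample_id, c("S2", "S3"))
})

test_that("MAF filter honors its comparator at the boundary", {
  # 10 samples, one het: alt count 1 of 20 alleles -> MAF 0.05
  geno <- matrix(0L, 10, 1)
  geno[1, 1] <- 1L
  gm <- toy_gm(geno)
  expect_equal(ncol(filter_maf(gm, 0.05, "gt")$geno), 0L)
  expect_equal(ncol(filter_maf(gm, 0.05, "ge")$geno), 1L)

  mono <- toy_gm(matrix(0L, 4, 1))
  expect_equal(ncol(filter_maf(mono, 0.01, "gt")$geno), 0L)
  balanced <- toy_gm(matrix(1L, 4, 1))
  expect_equal(ncol(filter_maf(balanced, 0.05, "gt")$geno), 1L)
})

test_that("singleton removal counts minor alleles, not carriers", {
  geno <- matrix(0L, 6, 3)
  geno[1, 1] <- 1L # singleton -> removed
  geno[1, 2] <- 2L # hom-alt carrier, count 2 -> kept
  geno[1:3, 3] <- 1L
  out <- remove_singletons(toy_gm(geno))
  expect_identical(out$sites$pos, c(2000L, 3000L))
  nosing <- toy_gm(matrix(c(1L, 1L, 0L, 0L), 4, 2))
  expect_identical(remove_singletons(nosing)$geno, nosing$geno)
})

test_that("site classification follows exon > intron > proximal > intergenic", {
  ann <- structure(data.frame(gene_id = c("g1", "g1"), chrom = "1B",
                              strand = "+", start = c(10000L, 14000L),
                              end = c(11000L, 15000L)),
                   class = c("gene_annotation", "data.frame"))
  pos <- c(10500L,  # inside CDS -> exonic
           12000L,  # between CDS intervals -> intronic
           8500L,   # 1500 upstream of CDS start -> proximal
           16500L,  # 1500 downstream -> proximal
           20000L,  # 5 kb away -> intergenic
           7999L)   # 2001 upstream -> intergenic
  gm <- toy_gm(matrix(0L, 2, 6), pos = pos)
  cls <- classify_sites(gm, ann, window = 2000)
  expect_identical(cls, c("exonic", "intronic", "proximal", "proximal",
                          "intergenic", "intergenic"))
  expect_equal(sum(table(cls)), length(pos)) # partition
})

test_that("drop_genic removes exonic and intronic sites only", {
  gm <- toy_gm(matrix(0L, 2, 10))
  classes <- c(rep("exonic", 3), rep("intronic", 2), rep("proximal", 2),
               rep("intergenic", 3))
  out <- drop_genic(gm, classes)
  expect_equal(ncol(out$geno), 5L)
  all_inter <- rep("intergenic", 10)
  expect_equal(ncol(drop_genic(gm, all_inter)$geno), 10L)
})

test_that("greedy distance thinning keeps the documented set", {
  gm <- toy_gm(matrix(0L, 2, 4), pos = c(1L, 15000L, 25000L, 50000L))
  out <- thin_by_distance(gm, 20000)
  expect_identical(out$sites$pos, c(1L, 25000L, 50000L))

  single <- toy_gm(matrix(0L, 2, 1))
  expect_equal(ncol(thin_by_distance(single)$geno), 1L)

  two <- toy_gm(matrix(0L, 2, 4), chrom = c("1A", "1A", "2B", "2B"),
                pos = c(100L, 5000L, 100L, 5000L))
  thinned <- thin_by_distance(two, 20000)
  expect_identical(thinned$sites$chrom, c("1A", "2B"))
  expect_identical(thinned$sites$pos, c(100L, 100L))

  unsorted <- toy_gm(matrix(0L, 2, 2), pos = c(5000L, 100L))
  expect_error(thin_by_distance(unsorted), "sorted")
})

test_that("thinned output satisfies the gap invariant on simulated data", {
  gm <- shared_cohort()
  out <- thin_by_distance(gm, 25000)
  for (chr in unique(out$sites$chrom)) {
    pos <- out$sites$pos[out$sites$chrom == chr]
    if (length(pos) > 1) expect_true(all(diff(pos) >= 25000))
  }
})

test_that("per-group SNP counts match hand enumeration", {
  geno <- rbind(c(0L, 0L, 1L, 2L),
                c(0L, 1L, 1L, 2L),
                c(0L, 2L, 1L, 2L))
  gm <- toy_gm(geno)
  tab <- summarize_counts(gm, list(all = gm$samples$sample_id))
  # site 1 monomorphic; sites 2-3 polymorphic; site 4 fixed alt
  expect_equal(tab$polymorphic, 2L)
  expect_equal(tab$maf_ge_5, 2L)

  one <- summarize_counts(gm, list(s2 = "S2"))
  expect_equal(one$polymorphic, 2L) # het sites only

  mono <- summarize_counts(toy_gm(matrix(2L, 3, 2)), list(all = paste0("S", 1:3)))
  expect_equal(mono$polymorphic, 0L)

  expect_error(summarize_counts(gm, list(bad = character(0))), "empty")
})

test_that("filter chains report counts that an independent recount confirms", {
  gm <- shared_cohort()
  out <- filter_site_missing(gm, 0.2)
  out <- filter_maf(out, 0.05, "gt")
  out <- remove_singletons(out)
  rep <- filter_report(out)
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$sites_after <= rep$sites_before))
  expect_identical(rep$sites_before[-1], rep$sites_after[-nrow(rep)])
  expect_equal(rep$sites_after[nrow(rep)], ncol(out$geno))
  # recount: emitted matrix really has no singleton and passes MAF
  ac <- pmin(colSums(out$geno, na.rm = TRUE),
             2 * colSums(!is.na(out$geno)) - colSums(out$geno, na.rm = TRUE))
  expect_true(all(ac != 1))
  expect_true(all(site_maf(out) > 0.05))
})
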