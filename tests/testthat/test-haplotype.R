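fx <- make_allele_fixtures(1)
ref <- fx$alleles[[fx$reference_id]]

test_that("CDS identity: exact duplicates, counted substitutions", {
  expect_equal(cds_identity("ACGTACGT", "ACGTACGT"), 100)
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  v <- s
  pos <- sample(100, 7)
  for (p in pos) {
    old <- substr(v, p, p)
    substr(v, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(cds_identity(s, v), 93.0)
  expect_error(cds_identity("", "ACGT"), "empty")
})

test_that("G5 fixture identity falls in the tuned 93-94% window", {
  idy <- cds_identity(fx$alleles[["rg-B1a_h10"]], ref)
  expect_gte(idy, 93.0)
  expect_lte(idy, 94.0)
})

test_that("identity matrix is symmetric with unit diagonal", {
  M <- identity_matrix(fx$alleles[1:4])
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 100))
  expect_true(all(M >= 0 & M <= 100))
})

test_that("intron features are recovered against the stripped reference", {
  baseline <- strip_insertions(ref)
  g1 <- detect_insertions(ref, baseline)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$intron, 2)
  expect_equal(g1$type, "insertion")
  expect_equal(g1$length, 8100)
  expect_identical(g1$class, "large")

  g3 <- detect_insertions(fx$alleles[["Rg-B1b_h1"]], baseline)
  expect_equal(nrow(g3), 1)
  expect_identical(unname(unlist(g3[1, c("intron", "type", "length")])),
                   c("1", "deletion", "47"))

  g5 <- detect_insertions(fx$alleles[["rg-B1a_h10"]], baseline)
  expect_identical(g5$class, "small")
  expect_equal(g5$length, 300)

  self <- detect_insertions(baseline, baseline)
  expect_equal(nrow(self), 0)

  one_exon <- allele_sequence("x", "y", "ATGTAA", rbind(c(1, 6)))
  expect_error(detect_insertions(one_exon, baseline), "intron count")
})

test_that("ORF translation counts residues and flags premature stops", {
  expect_equal(orf_translate("ATGTAA")$n_residues, 1)
  expect_identical(orf_translate("ATGTAA")$protein, "M")
  expect_true(orf_translate("ATGTAA")$terminated)

  g3 <- orf_translate(fx$alleles[["Rg-B1b_h1"]])
  expect_equal(nchar(fx$alleles[["Rg-B1b_h1"]]$cds), 975)
  expect_equal(g3$n_residues, 324)

  ref_len <- orf_translate(ref)$n_residues
  g2 <- orf_translate(fx$alleles[["rg-B1a_h7"]], ref_len)
  expect_equal(g2$n_residues, ref_len - 66)
  expect_true(g2$premature_stop)

  expect_error(orf_translate("TTGTAA"), "ATG")
  unterm <- orf_translate("ATGAAAAAA")
  expect_false(unterm$terminated)
})

revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

test_that("minus-strand CDS derivation reverse-complements", {
  plus <- allele_sequence("p", "x", "ATGAAATAAG", rbind(c(1, 9)), "+")
  minus <- allele_sequence("m", "x", revcomp_oracle("ATGAAATAA"),
                           rbind(c(1, 9)), "-")
  expect_identical(minus$cds, plus$cds)
})

test_that("classification recovers the constructed groups exactly", {
  cls <- classify_alleles(fx$alleles, ref)
  m <- merge(cls, fx$truth, by = "allele_id")
  expect_identical(m$group.x, m$group.y)
  # the reference (Chinese Spring) itself is a group 1 allele
  expect_identical(cls$group[cls$allele_id == fx$reference_id], "G1")
  # the 90% paralog fails membership, with a reason
  para <- cls[cls$allele_id == "paralog_x", ]
  expect_true(is.na(para$group))
  expect_match(para$reason, "membership")
  # partition: every member in exactly one group
  assigned <- cls[!is.na(cls$group), ]
  expect_equal(anyDuplicated(assigned$allele_id), 0)
})

test_that("neighbor joining reconstructs additive trees exactly", {
  for (n in 4:6) {
    ad <- random_additive_matrix(n, seed = n * 13)
    njt <- nj_tree(ad$D)
    expect_equal(ape::dist.topo(ape::unroot(njt$tree), ape::unroot(ad$tree)),
                 0, ignore_attr = TRUE)
    # branch lengths of an additive matrix are reproduced exactly
    expect_equal(cophenetic(njt$tree)[rownames(ad$D), colnames(ad$D)],
                 ad$D, tolerance = 1e-8)
  }
})

test_that("brute-force topology search agrees with neighbor joining", {
  ad <- random_additive_matrix(5, seed = 91)
  oracle <- bruteforce_nj_oracle(ad$D)
  njt <- nj_tree(ad$D)
  expect_equal(ape::dist.topo(ape::unroot(oracle), ape::unroot(njt$tree)),
               0, ignore_attr = TRUE)
})

test_that("a star phylogeny yields a near-zero internal edge", {
  D <- matrix(2, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  diag(D) <- 0
  njt <- nj_tree(D)
  internal <- njt$tree$edge[, 2] > length(njt$tree$tip.label)
  expect_lt(max(abs(njt$tree$edge.length[internal])), 1e-9)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("fixture tree isolates the diverged G5 allele and supports G1/G2", {
  members <- fx$truth$allele_id[!is.na(fx$truth$group)]
  njt <- nj_tree(fx$alleles[members], bootstrap_n = 200, seed = 5)
  tree <- njt$tree
  ext <- tree$edge[, 2] <= length(tree$tip.label)
  tip_len <- tree$edge.length[ext][order(tree$edge[ext, 2])]
  expect_identical(unname(tree$tip.label[which.max(tip_len)]), "rg-B1a_h10")
  expect_true(all(njt$support >= 0 & njt$support <= 100))
  expect_identical(nj_tree(fx$alleles[members], bootstrap_n = 50,
                           seed = 5)$tree$node.label,
                   nj_tree(fx$alleles[members], bootstrap_n = 50,
                           seed = 5)$tree$node.label)
})

test_that("in-silico PCR: amplicon lengths, orientation, absence", {
  amp3 <- insilico_pcr(fx$alleles[["Rg-B1b_h1"]], fx$primers)
  amp4 <- insilico_pcr(fx$alleles[["rg-B1a_h9"]], fx$primers)
  expect_equal(amp3$length, 334)
  expect_equal(amp4$length, 381)
  expect_equal(amp4$length - amp3$length, 47)
  expect_equal(amp4$end - amp4$start + 1, amp4$length)

  none <- insilico_pcr(fx$alleles[["rg-B1a_h9"]],
                       list(forward = strrep("ACGT", 5),
                            reverse = fx$primers$reverse))
  expect_equal(nrow(none), 0)
  short <- list(forward = "ACGTACGTAC", reverse = fx$primers$reverse)
  expect_error(insilico_pcr(fx$alleles[["rg-B1a_h9"]], short), "15")
  # a pairing farther than max_len is not reported
  far <- insilico_pcr(ref, fx$primers, max_len = 300)
  expect_equal(nrow(far), 0)
})
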