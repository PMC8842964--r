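test_that("haplotype collapse and diversity follow the unbiased formulas", {
  aln <- make_aln(rep("ACGTACGT", 4))
  hs <- collapse_haplotypes(aln)
  expect_equal(hs$h, 1)
  expect_equal(hs$Hd, 0)

  aln2 <- make_aln(c("AAAA", "AAAT", "AATT", "ATTT"))
  hs2 <- collapse_haplotypes(aln2)
  expect_equal(hs2$h, 4)
  expect_equal(hs2$Hd, 1)  # n/(n-1) * (1 - 1/n) = 1 for all-distinct

  ## frequencies (2,1,1) of 4: Hd = (4/3)(1 - 0.375) = 0.8333...
  aln3 <- make_aln(c("AAAA", "AAAA", "AATT", "ATTT"))
  hs3 <- collapse_haplotypes(aln3)
  expect_equal(hs3$h, 3)
  expect_equal(hs3$Hd, (4 / 3) * (1 - 0.375))
})

test_that("complete deletion drops N sequences then gapped sites consistently", {
  aln <- make_aln(c("ACGTA", "ACNTA", "AC-TA", "ACGTT"))
  hs <- collapse_haplotypes(aln)                 # drops seq 2, then site 3
  expect_equal(hs$n_sequences, 3)
  expect_equal(hs$n_sites, 4)
  ## site set is invariant to sequence order
  perm <- make_aln(c("ACGTT", "AC-TA", "ACNTA", "ACGTA"))
  expect_equal(collapse_haplotypes(perm)$n_sites, 4)
  expect_error(collapse_haplotypes(make_aln(c("NNNN", "ANNN"))), "excluded")
})

test_that("nucleotide diversity equals mean pairwise difference per site", {
  expect_equal(nucleotide_diversity(make_aln(rep("ACGT", 3))), 0)
  s <- strrep("A", 99)
  expect_equal(nucleotide_diversity(make_aln(c(paste0(s, "C"), paste0(s, "G")))),
               0.01)
  ## n = 4, one singleton among 432 sites: (3/6) / 432
  base <- strrep("A", 432)
  var1 <- paste0("T", strrep("A", 431))
  pi4 <- nucleotide_diversity(make_aln(c(base, base, base, var1)))
  expect_equal(pi4, 0.5 / 432, tolerance = 1e-12)
})

test_that("raggedness follows Harpending's boundary convention", {
  ## all pairs identical: single class x0 = 1, r = (0 - 1)^2 = 1
  mm <- mismatch_distribution(make_aln(rep("ACGT", 4)))
  expect_equal(mm$raggedness, 1)
  ## direct substitution on fixed class frequencies
  expect_equal(pangotrace:::raggedness_from_freq(c(0.25, 0.5, 0.25)), 0.1875)
  expect_equal(pangotrace:::raggedness_from_freq(c(0.5, 0.5)), 0.25)
})

test_that("neutrality statistics match exact and independently frozen oracles", {
  ## n = 4, one singleton: exact algebra gives D = -sqrt(3/8), R2 = sqrt(3/16)
  aln4 <- make_aln(c("AA", "AA", "AA", "TA"))
  expect_equal(tajimas_d(aln4), -sqrt(3 / 8), tolerance = 1e-9)
  expect_equal(r2_statistic(aln4), sqrt(0.1875), tolerance = 1e-9)

  ## n = 2 with exactly one difference: theta = 1, S' = 0.5, Fs = 0
  expect_equal(fus_fs(make_aln(c("AA", "TA"))), 0, tolerance = 1e-12)

  ## 5-sequence fixture, expected values frozen from an independent
  ## from-scratch implementation (exact rational pi, sympy Stirling numbers)
  aln5 <- make_aln(c("AAAAAAAA", "AAAAAAAT", "AATAAAAT", "AATAATAT",
                     "TATAATAT"))
  expect_equal(tajimas_d(aln5), 0.2734497664558790, tolerance = 1e-9)
  expect_equal(fus_fs(aln5), -3.068052935133617, tolerance = 1e-9)
  expect_equal(r2_statistic(aln5), 0.1936491673103709, tolerance = 1e-9)
  expect_equal(mismatch_distribution(aln5)$raggedness, 0.2, tolerance = 1e-12)

  ## whenever pi equals S/a1 the numerator (and D) is exactly zero
  a1 <- sum(1 / (1:9))
  expect_equal(pangotrace:::tajimas_d_from_counts(10, 11, 11 / a1), 0,
               tolerance = 1e-9)

  ## degenerate inputs are flagged
  expect_warning(d0 <- tajimas_d(make_aln(rep("ACGT", 4))), "undefined")
  expect_true(is.na(d0))
  expect_warning(f0 <- fus_fs(make_aln(rep("ACGT", 4))), "degenerate")
  expect_equal(f0, Inf)
})

test_that("K2P distance matches the closed form and ape's implementation", {
  expect_equal(k2p_distance(strsplit("ACGT", "")[[1]],
                            strsplit("ACGT", "")[[1]]), 0)
  ## 10 sites, 1 transition + 1 transversion:
  ## 0.5 ln(1/0.7) + 0.25 ln(1/0.8)
  s1 <- strsplit("AAAAACCCCC", "")[[1]]
  s2 <- strsplit("GAAAAACCCC", "")[[1]]
  expect_equal(k2p_distance(s1, s2),
               0.5 * log(1 / 0.7) + 0.25 * log(1 / 0.8), tolerance = 1e-12)
  expect_equal(k2p_distance(s1, s2), k2p_distance(s2, s1))

  ## cross-check against ape on random pairs
  set.seed(31)
  for (i in 1:5) {
    a <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    b <- a
    mut <- sample(60, 6)
    b[mut] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    d_ape <- as.numeric(ape::dist.dna(ape::as.DNAbin(rbind(a, b)),
                                      model = "K80"))
    expect_equal(k2p_distance(a, b), d_ape, tolerance = 1e-9)
  }
  ## gap/N sites are excluded pairwise
  expect_equal(k2p_distance(c("A", "N", "C"), c("A", "G", "C")), 0)
  expect_warning(ks <- k2p_distance(c("A", "C", "A", "C"),
                                    c("G", "T", "G", "T")), "saturated")
  expect_equal(ks, Inf)
})

test_that("lineage assignment picks the nearest reference lineage", {
  ref <- make_aln(c(paste(rep("A", 40), collapse = ""),
                    paste(c(rep("A", 20), rep("G", 20)), collapse = "")),
                  ids = c("dgl1", "wca1"))
  lineages <- c("DGL", "WCA")
  q_dgl <- make_aln(paste(rep("A", 40), collapse = ""), ids = "q1")
  res <- assign_lineage(q_dgl, ref, lineages)
  expect_equal(res$lineage, "DGL")

  ## equidistant query: unassigned
  q_mid <- make_aln(paste(c(rep("A", 30), rep("G", 10)), collapse = ""),
                    ids = "q2")
  res2 <- assign_lineage(q_mid, ref, lineages)
  expect_true(is.na(res2$lineage))

  ## two diverged clusters (d ~ 0.05 between, ~0.005 within): every
  ## simulated query lands in its true cluster
  set.seed(33)
  L <- 432
  base1 <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  base2 <- base1
  swap <- sample(L, 22)
  base2[swap] <- vapply(base2[swap], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  refs <- rbind(base1, base2)
  rownames(refs) <- c("c1", "c2")
  ok <- 0
  for (i in 1:100) {
    truth <- sample(1:2, 1)
    q <- refs[truth, ]
    mut <- sample(L, 2)
    q[mut] <- vapply(q[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    res3 <- assign_lineage(hap_alignment(matrix(q, 1, dimnames = list("q", NULL))),
                           hap_alignment(refs), c("C1", "C2"))
    if (!is.na(res3$lineage) && res3$lineage == c("C1", "C2")[truth])
      ok <- ok + 1
  }
  expect_equal(ok, 100)
})

test_that("coalescent p-values sit where the null distribution says", {
  ## observed at the null median: p around 0.5
  set.seed(35)
  null_d <- replicate(400, suppressWarnings(
    tajimas_d(simulate_coalescent_sample(15, 8))))
  med <- stats::median(null_d, na.rm = TRUE)
  p_med <- coalescent_pvalues(list(D = med), n = 15, S = 8, reps = 400,
                              seed = 36)
  expect_gt(p_med[["D"]], 0.35)
  expect_lt(p_med[["D"]], 0.65)

  ## observed far below every replicate: minimal attainable p
  p_lo <- coalescent_pvalues(list(D = -50), n = 15, S = 8, reps = 200,
                             seed = 37)
  expect_equal(p_lo[["D"]], 1 / 201)
})
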