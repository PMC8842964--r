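test_that("presence probability matches enumeration and its limits", {
  expect_equal(presence_probability(10, 0, 3), 0)
  expect_equal(presence_probability(10, 4, 10), 1)
  ## N = 4, one copy, g = 2: enumeration over all 6 pairs gives 0.5
  expect_equal(presence_probability(4, 1, 2), 0.5)
  expect_equal(presence_probability(4, 1, 2), enum_presence_prob(4, 1, 2))
})

test_that("two-population private richness matches the enumeration oracle", {
  ## pop1 copies {A:1, B:3}, pop2 {B:4}, subsample of 2 gene copies:
  ## only A can be private to pop1, Q_A,1(2) * 1 = 0.5
  q_a <- presence_probability(4, 1, 2)
  expect_equal(q_a * (1 - presence_probability(4, 0, 2)), 0.5)
  expect_equal(enum_private_richness_2pop(c(`1` = 1, `2` = 3), c(`2` = 4), 2),
               0.5)

  ## full curve machinery against the joint-enumeration oracle
  ds <- make_ds(list(A1 = "1/2", A2 = "2/2", A3 = "2/3", A4 = "3/3",
                     B1 = "2/2", B2 = "2/4", B3 = "4/4", B4 = "2/4"),
                population = rep(c("PA", "PB"), each = 4))
  ft <- allele_frequencies(ds, population_partition(ds))
  rar <- private_richness_curves(ft, g_max = 3)
  for (g in 2:3) {
    want <- enum_private_richness_2pop(
      c(`1` = 1, `2` = 4, `3` = 3), c(`2` = 4, `4` = 4), 2 * g)
    got <- rar$richness[rar$population == "PA" & rar$g == g]
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("richness curves grow monotonically for truly private alleles", {
  ## an allele fixed in one population and absent elsewhere: contribution
  ## tends to 1 as g grows
  ds <- make_ds(c(stats::setNames(replicate(8, "9/9", simplify = FALSE), paste0("A", 1:8)),
                  stats::setNames(replicate(8, "2/2", simplify = FALSE), paste0("B", 1:8))),
                population = rep(c("PA", "PB"), each = 8))
  ft <- allele_frequencies(ds, population_partition(ds))
  rar <- private_richness_curves(ft, g_max = 7)
  cur <- rar[rar$population == "PA", ]
  cur <- cur[order(cur$g), ]
  expect_true(all(diff(cur$richness) >= -1e-12))
  expect_equal(cur$richness[nrow(cur)], 1, tolerance = 1e-9)
})

test_that("observed private alleles are alleles seen in exactly one population", {
  ds <- make_ds(list(A1 = "1/2", A2 = "2/5", B1 = "2/3", B2 = "3/3",
                     C1 = "3/3", C2 = "3/3"),
                population = c("PA", "PA", "PB", "PB", "PC", "PC"))
  cat <- observed_private_alleles(allele_frequencies(ds, population_partition(ds)))
  ## allele 2 occurs in PA and PB: not private; 3 in PB and PC: not private
  expect_setequal(cat$allele, c(1L, 5L))
  expect_true(all(cat$population == "PA"))
  ## PC ends up with no private allele at all
  expect_false("PC" %in% cat$population)
  ## planted alleles surface in the catalog
  sim <- simulate_dataset(simulation_config(seed = 23, missing_rate = 0))
  part <- default_partitions(sim$dataset)
  cat2 <- observed_private_alleles(allele_frequencies(sim$dataset, part))
  planted <- sim$truth$private_alleles
  for (i in seq_len(nrow(planted))) {
    hit <- cat2[cat2$allele == planted$allele[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$population, planted$population[i])
  }
})

test_that("trend classification follows the plateau/exponential/decreasing rules", {
  expect_equal(classify_trend(c(0.58, 0.60, 0.60)), "plateau")
  expect_equal(classify_trend(c(0.10, 0.20, 0.46)), "exponential")
  expect_equal(classify_trend(c(0.30, 0.25, 0.20)), "decreasing")
  ## flat but below the plateau threshold: not selectable
  expect_equal(classify_trend(c(0.30, 0.31, 0.31)), "rejected")
  ## rising but decelerating below the exponential threshold
  expect_equal(classify_trend(c(0.10, 0.30, 0.40)), "rejected")
})

test_that("locus selection requires both curve signature and observed alleles", {
  rar <- data.frame(
    locus = rep(c("L1", "L2", "L3"), each = 3),
    population = "PA", K = 2, g = rep(2:4, 3),
    richness = 1,
    frequency = c(0.55, 0.60, 0.60,   # plateau
                  0.30, 0.25, 0.20,   # decreasing
                  0.55, 0.60, 0.60))  # plateau but no observed allele
  class(rar) <- c("rarefaction_result", "data.frame")
  catalog <- data.frame(locus = c("L1", "L2"), allele = c(901L, 902L),
                        population = "PA")
  sel <- select_tracing_loci(rar, catalog)
  expect_equal(sel$locus, "L1")   # L2 decreasing, L3 unobserved: dropped
  expect_equal(sel$allele, 901L)
  expect_equal(sel$trend, "plateau")
})

test_that("market individuals are traced, flagged ambiguous, or untraceable", {
  ds <- make_ds(list(F1 = c("1/1", "3/3"), F2 = c("2/2", "4/4"),
                     M1 = c("1/2", "3/3"),   # carries PA's allele 1... and PB's 2
                     M2 = c("1/1", "3/3"),   # only PA hits
                     M3 = c("9/9", "8/8")),  # no selected allele
                population = c("PA", "PB", "MK", "MK", "MK"),
                site_class = c("forest", "forest", "market", "market", "market"))
  selected <- data.frame(locus = c("L1", "L1"), allele = c(1L, 2L),
                         population = c("PA", "PB"))
  tr <- trace_individuals(ds, selected)
  expect_equal(tr$verdict[tr$sample_id == "M1"], "ambiguous")
  expect_equal(tr$source[tr$sample_id == "M1"], "PA|PB")
  expect_equal(tr$verdict[tr$sample_id == "M2"], "traced")
  expect_equal(tr$source[tr$sample_id == "M2"], "PA")
  expect_equal(tr$verdict[tr$sample_id == "M3"], "untraceable")
})

test_that("per-population private richness never exceeds total allelic richness", {
  sim <- simulate_dataset(simulation_config(seed = 29, missing_rate = 0))
  part <- default_partitions(sim$dataset)
  ft <- allele_frequencies(sim$dataset, part)
  rar <- private_richness_curves(ft, g_max = 7)
  Kmax <- max(rar$K)
  for (l in unique(rar$locus)[1:5]) {
    sl <- rar[rar$locus == l & rar$K == Kmax & rar$g == 7, ]
    total_ar <- sum(vapply(ft$groups, function(gp) {
      cts <- ft$counts[[gp]][[l]]
      if (ft$n_genes[gp, l] >= 14) allelic_richness(cts, 14) else 0
    }, 0.0))
    expect_lte(sum(sl$richness), total_ar + 1e-9)
  }
})
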