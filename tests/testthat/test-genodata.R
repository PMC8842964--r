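test_that("native CSV dialect parses calls, canonicalizes pairs, flags errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,population,site_class,lat,lon,L1,L2",
    "S1,P1,forest,7.1,2.3,210/214,100/100",
    "S2,P1,forest,7.2,2.4,214/210,./.",
    "S3,P2,market,,,210/210,102/100"
  ), path)
  ds <- read_genotype_table(path)
  expect_equal(locus_names(ds), c("L1", "L2"))
  expect_equal(unname(ds$a1[1, 1]), 210L)
  expect_equal(unname(ds$a2[1, 1]), 214L)
  ## "214/210" parses to the same canonical unordered pair as "210/214"
  expect_equal(ds$a1[2, 1], ds$a1[1, 1])
  expect_equal(ds$a2[2, 1], ds$a2[1, 1])
  expect_true(is.na(ds$a1[2, 2]) && is.na(ds$a2[2, 2]))
  ## canonical sorting applies to every dialect and cell
  expect_equal(unname(ds$a1[3, 2]), 100L)
  expect_equal(ds$meta$site_class, c("forest", "forest", "market"))

  writeLines(c("sample_id,population,site_class,lat,lon,L1",
               "S1,P1,forest,1,1,210/"), path)
  expect_error(read_genotype_table(path), "malformed.*row 1.*L1")

  writeLines(c("sample_id,population,site_class,lat,lon,L1",
               "S1,P1,forest,1,1,210/212", "S1,P1,forest,1,1,210/212"), path)
  expect_error(read_genotype_table(path), "duplicated sample_id")
})

test_that("genalex dialect reads paired columns with 0 = missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,population,site_class,lat,lon,L1,L1b,L2,L2b",
    "S1,P1,forest,1,1,214,210,0,0",
    "S2,P1,forest,1,1,210,210,102,104"
  ), path)
  ds <- read_genotype_table(path, dialect = "genalex")
  expect_equal(locus_names(ds), c("L1", "L2"))
  expect_equal(unname(ds$a1[1, 1]), 210L)  # canonicalized
  expect_true(is.na(ds$a1[1, 2]))          # (0, 0) -> MISSING
  writeLines(c("sample_id,population,site_class,lat,lon,L1,L1b",
               "S1,P1,forest,1,1,210,0"), path)
  expect_error(read_genotype_table(path, dialect = "genalex"), "half-typed")
})

test_that("write/read round trip reproduces calls, metadata and ordering", {
  sim <- simulate_dataset(simulation_config(seed = 11))
  ds <- sim$dataset
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(ds, path, seed = 11)
  back <- read_genotype_table(path)
  expect_identical(back$a1, ds$a1)
  expect_identical(back$a2, ds$a2)
  expect_identical(back$meta$sample_id, ds$meta$sample_id)
  expect_identical(back$meta$population, ds$meta$population)
  expect_equal(back$meta$lat, ds$meta$lat, tolerance = 1e-12)
})

test_that("replicate consensus requires an allele in two of three replicates", {
  rep_ds <- function(cell) make_ds(list(S1 = cell))
  reps <- list(rep_ds("1/2"), rep_ds("1/2"), rep_ds("1/1"))
  cons <- consensus_from_replicates(reps)
  expect_equal(unname(c(cons$a1[1, 1], cons$a2[1, 1])), c(1L, 2L))

  reps <- list(rep_ds("1/1"), rep_ds("2/2"), rep_ds("./."))
  cons <- consensus_from_replicates(reps)
  expect_true(is.na(cons$a1[1, 1]))

  reps <- list(rep_ds("1/1"), rep_ds("1/1"), rep_ds("1/2"))
  cons <- consensus_from_replicates(reps)
  expect_equal(unname(c(cons$a1[1, 1], cons$a2[1, 1])), c(1L, 1L))

  ## three alleles each supported twice: conflict, flagged missing
  reps <- list(rep_ds("1/2"), rep_ds("2/3"), rep_ds("3/1"))
  expect_warning(cons <- consensus_from_replicates(reps), ">2 alleles")
  expect_true(is.na(cons$a1[1, 1]))
})

test_that("completeness filter keeps >= 15/20-typed samples and is idempotent", {
  calls15 <- c(rep("1/2", 15), rep("./.", 5))
  calls14 <- c(rep("1/2", 14), rep("./.", 6))
  ds <- make_ds(list(A = calls15, B = calls14))
  suppressMessages(kept <- filter_by_completeness(ds, 0.75))
  expect_equal(kept$meta$sample_id, "A")
  suppressMessages(again <- filter_by_completeness(kept, 0.75))
  expect_identical(again$a1, kept$a1)
  expect_warning(suppressMessages(filter_by_completeness(
    make_ds(list(B = calls14)), 0.75)), "no samples")
})

test_that("allele frequencies count gene copies over non-missing calls", {
  ds <- make_ds(list(S1 = "1/1", S2 = "1/2"))
  tab <- allele_frequencies(ds)
  expect_equal(af_freq(tab, "all", "L1"), c(`1` = 0.75, `2` = 0.25))
  expect_equal(unname(tab$n_genes[1, 1]), 4L)

  ## a fully missing locus is flagged undefined
  ds2 <- make_ds(list(S1 = c("1/1", "./."), S2 = c("1/2", "./.")))
  tab2 <- allele_frequencies(ds2)
  expect_true(tab2$undefined[1, "L2"])
  expect_length(af_freq(tab2, "all", "L2"), 0)

  ## partition additivity: group counts sum to pooled counts
  ds3 <- make_ds(list(S1 = "1/1", S2 = "1/2", S3 = "2/3"),
                 population = c("A", "A", "B"))
  part <- population_partition(ds3)
  tabg <- allele_frequencies(ds3, part)
  pooled <- allele_frequencies(ds3)
  summed <- tapply(
    c(tabg$counts$A$L1, tabg$counts$B$L1),
    c(names(tabg$counts$A$L1), names(tabg$counts$B$L1)), sum)
  ref <- pooled$counts$all$L1
  expect_equal(as.numeric(summed[names(ref)]), as.numeric(ref))
})

test_that("frequencies sum to one wherever genes were sampled", {
  sim <- simulate_dataset(simulation_config(seed = 4, missing_rate = 0.15))
  tab <- allele_frequencies(sim$dataset, population_partition(sim$dataset))
  for (gp in tab$groups) {
    for (l in tab$loci) {
      if (tab$n_genes[gp, l] > 0)
        expect_equal(sum(af_freq(tab, gp, l)), 1, tolerance = 1e-12)
    }
  }
})

test_that("alignment reader validates lengths and alphabet", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT-N", ">b", "ACGTAA"), path)
  aln <- read_alignment(path)
  expect_equal(dim(aln), c(2L, 6L))
  expect_equal(rownames(aln), c("a", "b"))

  writeLines(c(">a", "ACGT", ">b", "ACG"), path)
  expect_error(read_alignment(path), "unequal lengths")
  writeLines(c(">a", "ACGU", ">b", "ACGU"), path)
  expect_error(read_alignment(path), "outside")
  writeLines(character(0), path)
  expect_error(read_alignment(path))
  ## round trip
  writeLines(c(">a", "ACGT-N", ">b", "ACGTAA"), path)
  aln <- read_alignment(path)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_identical(unclass(read_alignment(out)), unclass(aln))
})
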