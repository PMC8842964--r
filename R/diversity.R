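# Per-locus diversity, HWE chi-square tests, Weir-Cockerham F-statistics
# (variance components) and permutation significance.

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a uniform subsample of `g` gene
#' copies: `sum_i [1 - C(N - N_i, g) / C(N, g)]` with `N` total gene copies
#' and `N_i` copies of allele i.
#'
#' @param counts named vector of gene-copy counts per allele
#' @param g standardised gene-sample size, `1 <= g <= sum(counts)`
#' @return expected allele count, in `[1, length(counts)]` for `g >= 1`
#' @export
allelic_richness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) stop("rarefaction size g = ", g, " exceeds gene copies N = ", N)
  stopifnot(g >= 1)
  sum(1 - choose_ratio(N - counts, N, g))
}

#' Per-locus diversity summary
#'
#' Computes, per locus over the samples named in `partition` (pooled by
#' default): the number of typed individuals `n`, allele count `Na`,
#' observed heterozygosity `Ho`, unbiased expected heterozygosity
#' `He = (2n / (2n - 1)) (1 - sum p_i^2)`, allelic richness `Ar` rarefied to
#' a standardised gene-sample size `g`, the single-population
#' Weir-Cockerham inbreeding estimate `Fis`, and the Hardy-Weinberg
#' chi-square p-value. Column means across loci are attached as attribute
#' `"means"` (and `g` as attribute `"g"`).
#'
#' The default `g` is the smallest per-locus gene-copy count across the
#' analysis set (the FSTAT convention), and can be overridden.
#'
#' @param ds a [geno_dataset()]
#' @param partition sample partition; all groups are pooled for this summary
#' @param g standardised gene-sample size for `Ar` (default: min over loci)
#' @return data frame with one row per locus
#' @export
locus_summary <- function(ds, partition = pooled_partition(ds), g = NULL) {
  stopifnot(n_samples(ds) > 0)
  ids <- names(partition)
  sub <- subset_samples(ds, ids)
  tab <- allele_frequencies(sub, pooled_partition(sub))
  n_genes <- tab$n_genes[1, ]
  if (is.null(g)) g <- min(n_genes[n_genes > 0])
  loci <- locus_names(sub)
  out <- data.frame(locus = loci, n = NA_real_, Na = NA_real_, Ho = NA_real_,
                    He = NA_real_, Ar = NA_real_, Fis = NA_real_,
                    p_hwe = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    cts <- tab$counts[[1]][[j]]
    N <- n_genes[j]
    if (N == 0) next
    if (g > N) stop("rarefaction size g = ", g,
                    " exceeds gene copies at locus ", loci[j])
    n <- N / 2
    p <- cts / N
    typed <- !is.na(sub$a1[, j])
    het <- sub$a1[typed, j] != sub$a2[typed, j]
    out$n[j] <- n
    out$Na[j] <- length(cts)
    out$Ho[j] <- mean(het)
    out$He[j] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    out$Ar[j] <- allelic_richness(cts, g)
    out$Fis[j] <- fis_single_locus(sub$a1[typed, j], sub$a2[typed, j])
    hw <- hwe_test(sub, loci[j])
    out$p_hwe[j] <- hw$p_value
  }
  attr(out, "g") <- g
  attr(out, "means") <- colMeans(out[, c("n", "Na", "Ho", "He", "Ar", "Fis")],
                                 na.rm = TRUE)
  out
}

## single-population Weir-Cockerham f at one locus (typed calls only)
fis_single_locus <- function(g1, g2) {
  n <- length(g1)
  if (n < 2) return(NA_real_)
  alleles <- sort(unique(c(g1, g2)))
  if (length(alleles) < 2) return(NA_real_)
  b_sum <- 0; c_sum <- 0
  for (al in alleles) {
    p <- (sum(g1 == al) + sum(g2 == al)) / (2 * n)
    h <- mean((g1 == al) != (g2 == al))
    b_sum <- b_sum + (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    c_sum <- c_sum + h / 2
  }
  if (b_sum + c_sum == 0) return(NA_real_)
  1 - c_sum / (b_sum + c_sum)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness-of-fit of observed genotype counts against Hardy-Weinberg
#' expectations computed from the sample allele frequencies, with
#' `df = k (k - 1) / 2` for `k` alleles (all heterozygote and homozygote
#' categories included). Monomorphic loci are flagged and return an
#' undefined p-value.
#'
#' @param ds a [geno_dataset()]
#' @param locus locus name
#' @param partition samples to use (pooled; default all)
#' @return list with `statistic`, `df`, `p_value` and `flag`
#'   (`"ok"`/`"monomorphic"`/`"untyped"`)
#' @export
hwe_test <- function(ds, locus, partition = pooled_partition(ds)) {
  sub <- subset_samples(ds, names(partition))
  j <- match(locus, locus_names(sub))
  if (is.na(j)) stop("unknown locus: ", locus)
  typed <- !is.na(sub$a1[, j])
  g1 <- sub$a1[typed, j]; g2 <- sub$a2[typed, j]
  n <- length(g1)
  if (n == 0) return(list(statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, flag = "untyped"))
  alleles <- sort(unique(c(g1, g2)))
  k <- length(alleles)
  if (k < 2) return(list(statistic = NA_real_, df = NA_real_,
                         p_value = NA_real_, flag = "monomorphic"))
  p <- vapply(alleles, function(al) (sum(g1 == al) + sum(g2 == al)) / (2 * n),
              0.0)
  obs <- exp <- numeric(0)
  for (i in seq_len(k)) {
    for (h in i:k) {
      o <- sum(g1 == alleles[i] & g2 == alleles[h])
      e <- if (i == h) n * p[i]^2 else 2 * n * p[i] * p[h]
      obs <- c(obs, o); exp <- c(exp, e)
    }
  }
  keep <- exp > 0
  stat <- sum((obs[keep] - exp[keep])^2 / exp[keep])
  df <- k * (k - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), flag = "ok")
}

## per-locus indicator matrices used by the Weir-Cockerham estimator:
## X[i, a] = copies of allele a in individual i, H[i, a] = 1 if i is
## heterozygous and carries allele a
wc_locus_mats <- function(g1, g2) {
  alleles <- sort(unique(c(g1, g2)))
  X <- outer(g1, alleles, "==") + outer(g2, alleles, "==")
  H <- (outer(g1, alleles, "==") | outer(g2, alleles, "==")) & (g1 != g2)
  list(X = X, H = H * 1, alleles = alleles)
}

## a, b, c summed over alleles at one locus for a given grouping
wc_locus_components <- function(X, H, pop) {
  n_i <- as.vector(table(pop))
  r <- length(n_i)
  if (r < 2 || any(n_i == 0)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  ntot <- sum(n_i)
  nbar <- ntot / r
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
  cnt <- rowsum(X, pop)                      # r x k allele copies
  hets <- rowsum(H, pop)                     # r x k het counts
  p_i <- cnt / (2 * n_i)
  h_i <- hets / n_i
  pbar <- colSums(cnt) / (2 * ntot)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(hets) / ntot
  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) * (s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pq - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(cc))
}

#' Weir-Cockerham F-statistics
#'
#' Variance-components estimators of FST (theta) and FIS over a partition of
#' samples into populations. Multi-locus estimates combine components by
#' summation across alleles and loci (ratios of sums, not means of ratios).
#' Per-group FIS uses the single-population estimator. Groups with fewer
#' than two typed individuals at every locus are excluded with a warning.
#'
#' @param ds a [geno_dataset()]
#' @param partition named character vector `sample_id -> population`
#' @return list with `fst` (multi-locus theta), `fis` (multi-locus overall
#'   f), `fis_by_group`, and `per_locus` (data frame of a, b, c components
#'   and per-locus theta and f)
#' @export
wc_f_statistics <- function(ds, partition) {
  ids <- names(partition)
  sub <- subset_samples(ds, ids)
  groups <- unname(partition)
  ## drop groups with < 2 typed individuals at all loci
  ok <- vapply(unique(groups), function(gp) {
    rows <- which(groups == gp)
    any(colSums(!is.na(sub$a1[rows, , drop = FALSE])) >= 2)
  }, TRUE)
  if (!all(ok)) {
    bad <- unique(groups)[!ok]
    warning("excluding group(s) with <2 typed individuals at all loci: ",
            paste(bad, collapse = ", "))
    keep <- groups %in% unique(groups)[ok]
    sub <- subset_samples(sub, ids[keep]); groups <- groups[keep]
  }
  loci <- locus_names(sub)
  per <- data.frame(locus = loci, a = NA_real_, b = NA_real_, c = NA_real_,
                    fst = NA_real_, fis = NA_real_, stringsAsFactors = FALSE)
  multi_groups <- length(unique(groups)) >= 2
  for (j in seq_along(loci)) {
    typed <- !is.na(sub$a1[, j])
    if (sum(typed) < 2) next
    if (multi_groups) {
      mats <- wc_locus_mats(sub$a1[typed, j], sub$a2[typed, j])
      comp <- wc_locus_components(mats$X, mats$H, factor(groups[typed]))
      per$a[j] <- comp["a"]; per$b[j] <- comp["b"]; per$c[j] <- comp["c"]
      tot <- comp["a"] + comp["b"] + comp["c"]
      if (!is.na(tot) && tot != 0) per$fst[j] <- comp["a"] / tot
      if (!is.na(comp["b"]) && comp["b"] + comp["c"] != 0)
        per$fis[j] <- 1 - comp["c"] / (comp["b"] + comp["c"])
    }
  }
  fst <- if (multi_groups && any(!is.na(per$a))) {
    sum(per$a, na.rm = TRUE) /
      sum(per$a + per$b + per$c, na.rm = TRUE)
  } else NA_real_
  fis <- if (multi_groups && any(!is.na(per$b)))
    1 - sum(per$c, na.rm = TRUE) / sum(per$b + per$c, na.rm = TRUE)
  else NA_real_
  fis_by_group <- vapply(unique(groups), function(gp) {
    rows <- which(groups == gp)
    b_sum <- 0; c_sum <- 0; any_ok <- FALSE
    for (j in seq_along(loci)) {
      g1 <- sub$a1[rows, j]; g2 <- sub$a2[rows, j]
      t <- !is.na(g1)
      if (sum(t) < 2) next
      g1 <- g1[t]; g2 <- g2[t]
      alleles <- unique(c(g1, g2))
      if (length(alleles) < 2) next
      n <- length(g1)
      for (al in alleles) {
        p <- (sum(g1 == al) + sum(g2 == al)) / (2 * n)
        h <- mean((g1 == al) != (g2 == al))
        b_sum <- b_sum + (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
        c_sum <- c_sum + h / 2
      }
      any_ok <- TRUE
    }
    if (!any_ok || b_sum + c_sum == 0) NA_real_ else 1 - c_sum / (b_sum + c_sum)
  }, 0.0)
  list(fst = unname(fst), fis = unname(fis), fis_by_group = fis_by_group,
       per_locus = per)
}

## multilocus theta for one grouping, from precomputed indicator matrices;
## mats_list[[j]] holds X, H and the typed-row index for locus j
wc_theta_from_mats <- function(mats_list, groups) {
  a_sum <- 0; d_sum <- 0
  for (m in mats_list) {
    comp <- wc_locus_components(m$X, m$H, factor(groups[m$typed]))
    if (is.na(comp["a"])) next
    a_sum <- a_sum + comp["a"]
    d_sum <- d_sum + comp["a"] + comp["b"] + comp["c"]
  }
  if (d_sum == 0) return(NA_real_)
  a_sum / d_sum
}

precompute_wc_mats <- function(ds) {
  lapply(seq_len(n_loci(ds)), function(j) {
    typed <- which(!is.na(ds$a1[, j]))
    if (length(typed) < 2) return(NULL)
    m <- wc_locus_mats(ds$a1[typed, j], ds$a2[typed, j])
    list(X = m$X, H = m$H, typed = typed)
  })
}

#' Pairwise Weir-Cockerham FST with permutation p-values
#'
#' Multi-locus pairwise theta between every pair of groups. When
#' `n_perm > 0`, significance is assessed by permuting individuals between
#' the two groups (group sizes preserved) and recomputing theta;
#' `p = (#\{theta_perm >= theta_obs\} + 1) / (n_perm + 1)`.
#'
#' @param ds a [geno_dataset()]
#' @param partition named character vector `sample_id -> population`
#' @param n_perm number of permutations (0 to skip the test)
#' @param seed optional integer seed for the permutations
#' @return list with `fst` (symmetric matrix, zero diagonal), `p_value`
#'   (matrix or NULL), and `n_perm`
#' @export
pairwise_fst <- function(ds, partition, n_perm = 0, seed = NULL) {
  groups <- sort(unique(unname(partition)))
  if (length(groups) < 2) stop("need at least two groups for pairwise FST")
  if (!is.null(seed)) set.seed(seed)
  G <- length(groups)
  fst <- matrix(0, G, G, dimnames = list(groups, groups))
  pmat <- if (n_perm > 0) matrix(NA_real_, G, G, dimnames = list(groups, groups))
          else NULL
  for (i in seq_len(G - 1)) {
    for (h in (i + 1):G) {
      ids <- names(partition)[partition %in% groups[c(i, h)]]
      sub <- subset_samples(ds, ids)
      labels <- unname(partition[ids])
      mats <- Filter(Negate(is.null), precompute_wc_mats(sub))
      obs <- wc_theta_from_mats(mats, labels)
      fst[i, h] <- fst[h, i] <- obs
      if (n_perm > 0) {
        hits <- 0L
        for (b in seq_len(n_perm)) {
          perm <- sample(labels)
          if (!is.na(obs) && !is.na(tp <- wc_theta_from_mats(mats, perm)) &&
              tp >= obs) hits <- hits + 1L
        }
        pmat[i, h] <- pmat[h, i] <- (hits + 1) / (n_perm + 1)
      }
    }
  }
  list(fst = fst, p_value = pmat, n_perm = n_perm)
}

#' @rdname pairwise_fst
#' @export
fst_permutation_test <- function(ds, partition, n_perm = 10000, seed = NULL) {
  pairwise_fst(ds, partition, n_perm = n_perm, seed = seed)
}

#' Reference partition of forest populations
#'
#' Builds the population-level analysis partition: forest populations with
#' at least `min_n` samples become groups; smaller populations are dropped
#' from population-level analyses (their samples remain available for
#' individual-level ones); market samples never enter reference partitions.
#'
#' @param ds a [geno_dataset()]
#' @param min_n minimum samples per qualifying population
#' @return named character vector `sample_id -> population`
#' @export
default_partitions <- function(ds, min_n = 7) {
  forest <- ds$meta$site_class == "forest"
  tab <- table(ds$meta$population[forest])
  keep_pops <- names(tab)[tab >= min_n]
  if (length(keep_pops) < 2)
    warning("fewer than 2 populations reach min_n = ", min_n)
  sel <- forest & ds$meta$population %in% keep_pops
  stats::setNames(ds$meta$population[sel], ds$meta$sample_id[sel])
}
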