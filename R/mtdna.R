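# mtDNA haplotype statistics, mismatch distribution, neutrality tests with
# coalescent-simulated p-values, and K2P-based lineage assignment.

## complete-deletion site filter: drop sequences containing N (optional),
## then drop sites with gap/N in any retained sequence
analysis_matrix <- function(aln, exclude_missing = TRUE) {
  m <- unclass(aln)
  if (exclude_missing) {
    has_n <- apply(m == "N", 1, any)
    m <- m[!has_n, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("all sequences excluded (missing data)")
  keep <- colSums(matrix(!(m %in% c("A", "C", "G", "T")), nrow(m))) == 0
  m[, keep, drop = FALSE]
}

pairwise_diff_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (s in seq_len(ncol(m))) {
    d <- d + outer(m[, s], m[, s], "!=")
  }
  d
}

#' Collapse an alignment into haplotypes
#'
#' Applies complete deletion (sequences containing `N` are dropped first
#' when `exclude_missing`, then every site with a gap or `N` in any retained
#' sequence is excluded) and collapses identical sequences into haplotypes.
#' Haplotype diversity is the unbiased
#' `Hd = n / (n - 1) * (1 - sum f_i^2)` with `f_i` the relative haplotype
#' frequencies.
#'
#' @param aln a `hap_alignment`
#' @param exclude_missing drop sequences containing `N` before site
#'   filtering (default TRUE)
#' @return object of class `haplotype_set`: list with `haplotypes`
#'   (character vector of collapsed sequences), `frequency` (counts),
#'   `assignment` (sequence id -> haplotype index), `h`, `Hd`, `pi`,
#'   `n_sequences`, `n_sites`
#' @export
collapse_haplotypes <- function(aln, exclude_missing = TRUE) {
  m <- analysis_matrix(aln, exclude_missing)
  n <- nrow(m)
  key <- apply(m, 1, paste, collapse = "")
  uniq <- unique(key)
  idx <- match(key, uniq)
  freq <- as.vector(table(idx))
  h <- length(uniq)
  f <- freq / n
  Hd <- if (n > 1) n / (n - 1) * (1 - sum(f^2)) else 0
  pi <- if (n > 1 && ncol(m) > 0)
    sum(pairwise_diff_matrix(m)) / (n * (n - 1)) / ncol(m) else 0
  structure(list(haplotypes = uniq, frequency = freq,
                 assignment = stats::setNames(idx, rownames(m)),
                 h = h, Hd = Hd, pi = pi,
                 n_sequences = n, n_sites = ncol(m)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", x$n_sequences, "sequences,", x$n_sites, "sites\n")
  cat("  h =", x$h, " Hd =", format(x$Hd, digits = 4),
      " pi =", format(x$pi, digits = 4), "\n")
  invisible(x)
}

#' Nucleotide diversity
#'
#' Mean pairwise proportion of differing sites over the complete-deletion
#' site set.
#'
#' @param aln a `hap_alignment` with at least two sequences
#' @param exclude_missing drop sequences containing `N` first
#' @return per-site nucleotide diversity
#' @export
nucleotide_diversity <- function(aln, exclude_missing = TRUE) {
  m <- analysis_matrix(aln, exclude_missing)
  n <- nrow(m)
  stopifnot(n >= 2)
  if (ncol(m) == 0) return(0)
  sum(pairwise_diff_matrix(m)) / (n * (n - 1)) / ncol(m)
}

## segregating sites and mean pairwise difference count (totals, not
## per site) on the analysis matrix
seg_stats <- function(m) {
  n <- nrow(m)
  poly <- vapply(seq_len(ncol(m)), function(s) length(unique(m[, s])) > 1, TRUE)
  S <- sum(poly)
  pi_tot <- if (n > 1) sum(pairwise_diff_matrix(m)) / (n * (n - 1)) else 0
  list(S = S, pi_tot = pi_tot, n = n)
}

#' Mismatch distribution and Harpending's raggedness index
#'
#' Relative frequencies `x_i` of pairwise difference counts `i = 0..d`
#' (d = largest observed difference) and the raggedness index
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` with `x_{d+1} = 0`: the leading
#' step off `x_0` is included through the `i = 1` term and a trailing
#' step to zero closes the sum (Harpending's convention).
#'
#' @param aln a `hap_alignment` with at least two sequences
#' @param exclude_missing drop sequences containing `N` first
#' @return list with `classes` (0..d), `freq` (relative frequencies) and
#'   `raggedness`
#' @export
mismatch_distribution <- function(aln, exclude_missing = TRUE) {
  m <- analysis_matrix(aln, exclude_missing)
  n <- nrow(m)
  stopifnot(n >= 2)
  d <- pairwise_diff_matrix(m)
  diffs <- d[upper.tri(d)]
  dmax <- max(diffs)
  x <- tabulate(diffs + 1, nbins = dmax + 1) / length(diffs)
  r <- raggedness_from_freq(x)
  list(classes = 0:dmax, freq = x, raggedness = r)
}

raggedness_from_freq <- function(x) {
  xx <- c(x, 0)
  sum(diff(xx)^2)
}

#' Tajima's D
#'
#' `D = (pi_hat - S / a1) / sqrt(e1 S + e2 S (S - 1))` with `pi_hat` the
#' mean pairwise difference count, `S` the number of segregating sites and
#' the standard `a1, a2, b1, b2, c1, c2, e1, e2` constants. Undefined
#' (flagged `NA`) when `S = 0`.
#'
#' @param aln a `hap_alignment`
#' @param exclude_missing drop sequences containing `N` first
#' @return the statistic (NA with a warning when S = 0)
#' @export
tajimas_d <- function(aln, exclude_missing = TRUE) {
  m <- analysis_matrix(aln, exclude_missing)
  st <- seg_stats(m)
  tajimas_d_from_counts(st$n, st$S, st$pi_tot)
}

tajimas_d_from_counts <- function(n, S, pi_tot) {
  if (S == 0) { warning("Tajima's D undefined: no segregating sites"); return(NA_real_) }
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## log unsigned Stirling numbers of the first kind, rows 1..n (computed in
## log space; exact recursion |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)|)
log_stirling_first <- function(n) {
  ls <- rep(-Inf, n + 1)
  ls[2] <- 0                     # |s(1,1)| = 1 at k index offset by 1
  for (m in seq_len(n - 1)) {
    new <- rep(-Inf, n + 1)
    for (k in seq_len(m + 1)) {
      new[k + 1] <- logsumexp2(log(m) + ls[k + 1], ls[k])
    }
    ls <- new
  }
  ls[-1]                          # log|s(n, k)| for k = 1..n
}

#' Fu's Fs
#'
#' `S' = P(K >= k_obs | theta = pi_hat, n)` under the Ewens sampling
#' formula, with `k_obs` the observed haplotype count and `theta` estimated
#' by the mean pairwise difference count; `Fs = ln(S' / (1 - S'))`.
#' Flagged infinite when `S'` reaches 0 or 1 numerically (e.g. all
#' sequences identical).
#'
#' @param aln a `hap_alignment` with at least two sequences
#' @param exclude_missing drop sequences containing `N` first
#' @return the statistic (+/-Inf flagged with a warning in degenerate cases)
#' @export
fus_fs <- function(aln, exclude_missing = TRUE) {
  m <- analysis_matrix(aln, exclude_missing)
  st <- seg_stats(m)
  k_obs <- length(unique(apply(m, 1, paste, collapse = "")))
  fus_fs_from_counts(st$n, k_obs, st$pi_tot)
}

fus_fs_from_counts <- function(n, k_obs, theta, log_stirling = NULL) {
  stopifnot(n >= 2)
  if (theta <= 0 || k_obs <= 1) {
    warning("Fu's Fs degenerate (no variation): flagged +Inf")
    return(Inf)
  }
  ls <- log_stirling %||% log_stirling_first(n)
  denom <- sum(log(theta + 0:(n - 1)))              # log rising factorial
  logp <- ls + (1:n) * log(theta) - denom           # log P(K = k)
  s_prime <- sum(exp(logp[k_obs:n]))
  if (s_prime >= 1) { warning("Fu's Fs: S' = 1, flagged -Inf"); return(-Inf) }
  if (s_prime <= 0) { warning("Fu's Fs: S' = 0, flagged +Inf"); return(Inf) }
  log(s_prime / (1 - s_prime))
}

#' Ramos-Onsins and Rozas' R2
#'
#' `R2 = sqrt((1/n) sum_i (U_i - pi_hat / 2)^2) / S` with `U_i` the number
#' of singleton mutations carried by sequence i. Small values indicate a
#' star-like genealogy (population growth). Flagged when `S = 0`.
#'
#' @param aln a `hap_alignment`
#' @param exclude_missing drop sequences containing `N` first
#' @return the statistic (NA with a warning when S = 0)
#' @export
r2_statistic <- function(aln, exclude_missing = TRUE) {
  m <- analysis_matrix(aln, exclude_missing)
  st <- seg_stats(m)
  if (st$S == 0) { warning("R2 undefined: no segregating sites"); return(NA_real_) }
  U <- singleton_counts(m)
  sqrt(mean((U - st$pi_tot / 2)^2)) / st$S
}

singleton_counts <- function(m) {
  n <- nrow(m)
  U <- numeric(n)
  for (s in seq_len(ncol(m))) {
    tb <- table(m[, s])
    if (length(tb) < 2) next
    singles <- names(tb)[tb == 1]
    for (al in singles) U[m[, s] == al] <- U[m[, s] == al] + 1
  }
  U
}

#' Neutrality statistics with coalescent-simulated p-values
#'
#' Simulates `reps` neutral constant-size coalescent samples conditioned on
#' the observed sample size and number of segregating sites
#' ([simulate_coalescent_sample()]), recomputes each statistic, and returns
#' `p = (#\{stat_sim <= stat_obs\} + 1) / (reps + 1)` (lower tail for D, Fs
#' and R2, the DnaSP convention; upper tail for the raggedness index).
#'
#' @param observed named list/vector with any of `D`, `Fs`, `R2`,
#'   `raggedness` (as from [neutrality_stats()])
#' @param n sample size of the observed data
#' @param S observed number of segregating sites
#' @param reps number of coalescent replicates (>= 100)
#' @param seed optional integer seed
#' @return named numeric vector of p-values (only for supplied statistics)
#' @export
coalescent_pvalues <- function(observed, n, S, reps = 1000, seed = NULL) {
  stopifnot(reps >= 100, n >= 2, S >= 1)
  if (!is.null(seed)) set.seed(seed)
  want <- intersect(names(observed), c("D", "Fs", "R2", "raggedness"))
  if (!length(want)) stop("no recognised statistic in 'observed'")
  ls <- if ("Fs" %in% want) log_stirling_first(n) else NULL
  sims <- replicate(reps, {
    aln <- simulate_coalescent_sample(n, S)
    suppressWarnings(null_stats_from_aln(aln, want, ls))
  })
  sims <- matrix(sims, nrow = length(want), dimnames = list(want, NULL))
  out <- stats::setNames(numeric(length(want)), want)
  for (st in want) {
    obs <- as.numeric(observed[[st]])
    vals <- sims[st, ]
    hits <- if (st == "raggedness") sum(vals >= obs, na.rm = TRUE)
            else sum(vals <= obs, na.rm = TRUE)
    out[st] <- (hits + 1) / (reps + 1)
  }
  out
}

null_stats_from_aln <- function(aln, want, log_stirling = NULL) {
  m <- unclass(aln)
  st <- seg_stats(m)
  out <- numeric(length(want)); names(out) <- want
  for (w in want) {
    out[w] <- switch(w,
      D = if (st$S == 0) NA_real_ else
        tajimas_d_from_counts(st$n, st$S, st$pi_tot),
      Fs = {
        k_obs <- length(unique(apply(m, 1, paste, collapse = "")))
        if (st$pi_tot <= 0 || k_obs <= 1) Inf else
          fus_fs_from_counts(st$n, k_obs, st$pi_tot, log_stirling)
      },
      R2 = if (st$S == 0) NA_real_ else
        sqrt(mean((singleton_counts(m) - st$pi_tot / 2)^2)) / st$S,
      raggedness = {
        d <- pairwise_diff_matrix(m); diffs <- d[upper.tri(d)]
        raggedness_from_freq(tabulate(diffs + 1, nbins = max(diffs) + 1) /
                               length(diffs))
      })
  }
  out
}

#' All neutrality statistics of an alignment
#'
#' Convenience wrapper computing `S`, Tajima's `D`, Fu's `Fs`, `R2` and the
#' raggedness index on the complete-deletion site set, optionally with
#' coalescent p-values.
#'
#' @param aln a `hap_alignment`
#' @param reps coalescent replicates for p-values (0 to skip)
#' @param seed optional integer seed
#' @param exclude_missing drop sequences containing `N` first
#' @return list with `S`, `D`, `Fs`, `R2`, `raggedness` and (when
#'   `reps > 0`) `p_values`
#' @export
neutrality_stats <- function(aln, reps = 1000, seed = NULL,
                             exclude_missing = TRUE) {
  m <- analysis_matrix(aln, exclude_missing)
  st <- seg_stats(m)
  mm <- mismatch_distribution(hap_alignment(m), exclude_missing = FALSE)
  obs <- list(
    D = suppressWarnings(tajimas_d_from_counts(st$n, st$S, st$pi_tot)),
    Fs = suppressWarnings(fus_fs(hap_alignment(m), exclude_missing = FALSE)),
    R2 = suppressWarnings(r2_statistic(hap_alignment(m), exclude_missing = FALSE)),
    raggedness = mm$raggedness)
  out <- c(list(S = st$S, n = st$n), obs)
  if (reps > 0 && st$S >= 1)
    out$p_values <- coalescent_pvalues(obs, st$n, st$S, reps = reps, seed = seed)
  out
}

#' Kimura two-parameter distance
#'
#' `d = 1/2 ln(1 / (1 - 2P - Q)) + 1/4 ln(1 / (1 - 2Q))` with `P` and `Q`
#' the transition and transversion proportions over sites without gaps or
#' `N` in either sequence. Saturated pairs (a log argument <= 0) are
#' flagged `Inf` with a warning.
#'
#' @param seq1,seq2 character vectors of equal length (or 1-row slices of a
#'   `hap_alignment`)
#' @return the distance (0 for identical sequences)
#' @export
k2p_distance <- function(seq1, seq2) {
  seq1 <- toupper(as.vector(seq1)); seq2 <- toupper(as.vector(seq2))
  stopifnot(length(seq1) == length(seq2))
  acgt <- c("A", "C", "G", "T")
  ok <- seq1 %in% acgt & seq2 %in% acgt
  if (!any(ok)) stop("no comparable site between the two sequences")
  s1 <- seq1[ok]; s2 <- seq2[ok]
  L <- length(s1)
  diff <- s1 != s2
  purine1 <- s1 %in% c("A", "G"); purine2 <- s2 %in% c("A", "G")
  transitions <- sum(diff & (purine1 == purine2))
  transversions <- sum(diff & (purine1 != purine2))
  P <- transitions / L; Q <- transversions / L
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P distance saturated; flagged Inf")
    return(Inf)
  }
  0.5 * log(1 / w1) + 0.25 * log(1 / w2)
}

#' Pairwise K2P distance matrix
#'
#' @param aln a `hap_alignment`
#' @return symmetric matrix of pairwise K2P distances
#' @export
k2p_matrix <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- suppressWarnings(k2p_distance(aln[i, ], aln[j, ]))
    }
  }
  d
}

#' Nearest-reference lineage assignment
#'
#' Assigns each query sequence to the lineage with the smallest mean K2P
#' distance to its reference sequences; the margin is the distance to the
#' second-best lineage minus the best. Queries whose margin does not exceed
#' `margin_threshold` (ties included) are left unassigned.
#'
#' @param query a `hap_alignment` of query sequences
#' @param reference a `hap_alignment` of reference sequences (same length)
#' @param lineages character vector of lineage labels, one per reference
#'   sequence (at least two distinct lineages)
#' @param margin_threshold minimum winning margin (default 0: strict
#'   nearest)
#' @return data frame with `sample_id`, `lineage` (`NA` when unassigned)
#'   and `margin`
#' @export
assign_lineage <- function(query, reference, lineages, margin_threshold = 0) {
  stopifnot(nrow(reference) == length(lineages))
  if (length(unique(lineages)) < 2)
    stop("reference panel must cover at least two lineages")
  stopifnot(ncol(query) == ncol(reference))
  out <- data.frame(sample_id = rownames(query), lineage = NA_character_,
                    margin = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(query))) {
    d <- vapply(seq_len(nrow(reference)), function(j)
      suppressWarnings(k2p_distance(query[i, ], reference[j, ])), 0.0)
    means <- tapply(d, lineages, mean)
    ord <- order(means)
    margin <- means[ord[2]] - means[ord[1]]
    out$margin[i] <- unname(margin)
    if (margin > margin_threshold) out$lineage[i] <- names(means)[ord[1]]
  }
  out
}
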