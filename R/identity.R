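# Forensic identity: multilocus genotype matching, genotype probability,
# probability-of-identity statistics and minimum-loci curves.

#' Find samples sharing a multilocus genotype
#'
#' Two samples match when their calls are identical at every locus typed in
#' both, and at least `min_shared_loci` loci are typed in both (so missing
#' data cannot fabricate matches). Match groups are transitive closures of
#' pairwise matches; singletons are not listed. Each group is annotated with
#' `pgen` of its first member (over that sample's typed loci, pooled
#' frequencies) and the probability `psex` that the genotype recurs by
#' chance among the remaining samples.
#'
#' @param ds a [geno_dataset()] (already completeness-filtered)
#' @param min_shared_loci minimum mutually typed loci for a comparison
#' @return object of class `match_report`: list with `groups` (list of
#'   sample-id vectors), `psex`, `pgen`, `n_distinct` (distinct genotypes =
#'   singletons + groups) and `n_samples`
#' @export
match_genotypes <- function(ds, min_shared_loci = 15) {
  n <- n_samples(ds)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  typed <- !is.na(ds$a1)
  for (i in seq_len(max(n - 1, 0))) {
    for (h in seq_len(n)[-seq_len(i)]) {
      both <- typed[i, ] & typed[h, ]
      if (sum(both) < min_shared_loci) next
      if (all(ds$a1[i, both] == ds$a1[h, both]) &&
          all(ds$a2[i, both] == ds$a2[h, both])) {
        ri <- find(i); rh <- find(h)
        if (ri != rh) parent[rh] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- split(ds$meta$sample_id, roots)
  groups <- unname(comp[lengths(comp) > 1])
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  ft <- allele_frequencies(ds)
  pg <- vapply(groups, function(g) pgen(ds, g[1], ft), 0.0)
  ps <- vapply(pg, psex, 0.0, n_samples = n)
  structure(list(groups = groups, pgen = pg, psex = ps,
                 n_distinct = length(groups) + sum(lengths(comp) == 1),
                 n_samples = n),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report:", x$n_samples, "samples,", x$n_distinct,
      "distinct genotypes,", length(x$groups), "match group(s)\n")
  for (i in seq_along(x$groups))
    cat("  {", paste(x$groups[[i]], collapse = ", "), "}  psex =",
        format(x$psex[i], digits = 3), "\n")
  invisible(x)
}

#' Multilocus genotype probability under Hardy-Weinberg
#'
#' Product over the sample's typed loci of the Hardy-Weinberg genotype
#' probability (`2 p_a p_b` for heterozygotes, `p_a^2` for homozygotes)
#' using pooled sample allele frequencies. No inbreeding correction is
#' applied (the simplest published definition).
#'
#' @param ds a [geno_dataset()]
#' @param sample_id sample whose genotype probability is computed
#' @param freq_table pooled `allele_freq_table` (default: computed from `ds`)
#' @return probability in `[0, 1]`
#' @export
pgen <- function(ds, sample_id, freq_table = allele_frequencies(ds)) {
  i <- match(sample_id, ds$meta$sample_id)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  gp <- freq_table$groups[1]
  out <- 1
  typed_any <- FALSE
  for (j in seq_len(n_loci(ds))) {
    a <- ds$a1[i, j]; b <- ds$a2[i, j]
    if (is.na(a)) next
    typed_any <- TRUE
    p <- af_freq(freq_table, gp, locus_names(ds)[j])
    pa <- p[as.character(a)]; pb <- p[as.character(b)]
    if (is.na(pa) || is.na(pb))
      stop("allele absent from frequency table at locus ", locus_names(ds)[j])
    out <- out * if (a == b) pa^2 else 2 * pa * pb
  }
  if (!typed_any) stop("sample ", sample_id, " is typed at no locus")
  unname(out)
}

#' Probability a genotype is encountered more than once by chance
#'
#' Single-encounter form `psex = 1 - (1 - pgen)^(n - 1)`: the probability
#' that at least one of the other `n - 1` samples shares the genotype by
#' chance under Hardy-Weinberg draws.
#'
#' @param pgen_value genotype probability in `[0, 1]`
#' @param n_samples total number of samples (>= 2)
#' @return probability in `[0, 1]`
#' @export
psex <- function(pgen_value, n_samples) {
  stopifnot(pgen_value >= 0, pgen_value <= 1, n_samples >= 2)
  1 - (1 - pgen_value)^(n_samples - 1)
}

pi_moments <- function(p) {
  c(a2 = sum(p^2), a3 = sum(p^3), a4 = sum(p^4))
}

## sample-size-corrected (unbiased) single-locus probability of identity,
## n = typed individuals
upi_locus <- function(p, n) {
  if (n < 4) return(NA_real_)
  m <- pi_moments(p)
  num <- n^3 * (2 * m["a2"]^2 - m["a4"]) - 2 * n^2 * (m["a3"] + 2 * m["a2"]) +
    n * (9 * m["a2"] + 2) - 6
  unname(num / ((n - 1) * (n - 2) * (n - 3)))
}

## single-locus probability of identity among full siblings
pisibs_locus <- function(p) {
  a2 <- sum(p^2); a4 <- sum(p^4)
  0.25 + 0.5 * a2 + 0.5 * a2^2 - 0.25 * a4
}

#' Probability-of-identity statistics
#'
#' `unbiased_pi()` computes the sample-size-corrected (unbiased) probability
#' that two unrelated individuals share a genotype, per locus and as the
#' multi-locus product; as the per-locus sample size grows it converges to
#' the classical `2 (sum p^2)^2 - sum p^4`. Loci typed in fewer than four
#' individuals are flagged and excluded from the product with a warning.
#' `pi_sibs()` is the full-sibling variant
#' `0.25 + 0.5 sum p^2 + 0.5 (sum p^2)^2 - 0.25 sum p^4`, which bounds the
#' identity probability from above for related individuals.
#'
#' @param freq_table a pooled `allele_freq_table` (one group)
#' @return list with `per_locus` (named vector) and `total` (product over
#'   usable loci)
#' @export
unbiased_pi <- function(freq_table) {
  gp <- freq_table$groups[1]
  vals <- vapply(freq_table$loci, function(l) {
    p <- af_freq(freq_table, gp, l)
    if (!length(p)) return(NA_real_)
    upi_locus(p, freq_table$n_genes[gp, l] / 2)
  }, 0.0)
  if (anyNA(vals))
    warning("loci excluded from uPI (untyped or n < 4): ",
            paste(names(vals)[is.na(vals)], collapse = ", "))
  list(per_locus = vals, total = prod(vals, na.rm = TRUE))
}

#' @rdname unbiased_pi
#' @export
pi_sibs <- function(freq_table) {
  gp <- freq_table$groups[1]
  vals <- vapply(freq_table$loci, function(l) {
    p <- af_freq(freq_table, gp, l)
    if (!length(p)) return(NA_real_)
    pisibs_locus(p)
  }, 0.0)
  list(per_locus = vals, total = prod(vals, na.rm = TRUE))
}

#' Minimum loci needed for a target sibling identity probability
#'
#' Orders loci by ascending single-locus PIsibs (most informative first, the
#' "optimized" ordering), accumulates the cumulative products of uPI and
#' PIsibs, and reports the smallest locus count whose cumulative PIsibs
#' falls below `threshold` (`NA` when not reached).
#'
#' @param freq_table a pooled `allele_freq_table`
#' @param threshold conservative PIsibs target (default 0.01)
#' @return object of class `pi_curve`: data frame with the ordered loci and
#'   cumulative `uPI`/`PIsibs`, with attribute `min_loci`
#' @export
min_loci_curve <- function(freq_table, threshold = 0.01) {
  upi <- unbiased_pi(freq_table)$per_locus
  sib <- pi_sibs(freq_table)$per_locus
  usable <- !is.na(sib)
  ord <- order(sib[usable])
  loci <- names(sib[usable])[ord]
  cum_sib <- cumprod(sib[usable][ord])
  cum_upi <- cumprod(ifelse(is.na(upi[usable][ord]), 1, upi[usable][ord]))
  out <- data.frame(k = seq_along(loci), locus = loci,
                    cum_uPI = cum_upi, cum_PIsibs = cum_sib,
                    row.names = NULL, stringsAsFactors = FALSE)
  hit <- which(cum_sib < threshold)
  attr(out, "min_loci") <- if (length(hit)) min(hit) else NA_integer_
  attr(out, "threshold") <- threshold
  class(out) <- c("pi_curve", "data.frame")
  out
}

#' @export
print.pi_curve <- function(x, ...) {
  k <- attr(x, "min_loci")
  cat("pi_curve over", nrow(x), "loci; PIsibs <", attr(x, "threshold"),
      "reached at k =", if (is.na(k)) "not reached" else k, "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
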