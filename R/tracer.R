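# Trade tracing: observed private alleles, generalized rarefaction of
# private-allele measures over population combinations, trend
# classification, cross-validated locus selection, and assignment of
# market individuals to source populations.

#' Observed private alleles per reference population
#'
#' An allele is private to population P when its gene-copy count is positive
#' in P and zero in every other reference population. Market samples must
#' not be part of the reference partition that built `freq_table`.
#'
#' @param freq_table an `allele_freq_table` over the forest (reference)
#'   partition, with at least two populations
#' @return object of class `private_allele_catalog`: data frame with
#'   columns `locus`, `allele`, `population`
#' @export
observed_private_alleles <- function(freq_table) {
  if (length(freq_table$groups) < 2)
    stop("need at least two reference populations")
  rows <- list()
  for (l in freq_table$loci) {
    per_group <- lapply(freq_table$groups, function(gp)
      names(freq_table$counts[[gp]][[l]]))
    names(per_group) <- freq_table$groups
    all_alleles <- unique(unlist(per_group))
    for (al in all_alleles) {
      holders <- freq_table$groups[vapply(per_group, function(x) al %in% x, TRUE)]
      if (length(holders) == 1)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = l, allele = as.integer(al), population = holders,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), allele = integer(0),
               population = character(0), stringsAsFactors = FALSE)
  class(out) <- c("private_allele_catalog", "data.frame")
  out
}

#' Probability an allele appears in a rarefied subsample
#'
#' `Q = 1 - C(N_total - N_allele, g) / C(N_total, g)`: the probability that
#' at least one of the `N_allele` copies of an allele is included in a
#' uniform subsample of `g` of the `N_total` gene copies.
#'
#' @param n_total total gene copies in the population at the locus
#' @param n_allele copies of the allele (`0 <= n_allele <= n_total`)
#' @param g subsample size in gene copies (`1 <= g <= n_total`)
#' @return probability in `[0, 1]`
#' @export
presence_probability <- function(n_total, n_allele, g) {
  stopifnot(all(n_allele >= 0), all(n_allele <= n_total),
            all(g >= 1), all(g <= n_total))
  1 - choose_ratio(n_total - n_allele, n_total, g)
}

#' Rarefaction curves of private-allele measures over population subsets
#'
#' For every locus, every subset S of K populations (K in `K_range`) and
#' every population j in S, computes two expected private-allele measures in
#' subsamples of g individuals (2g gene copies) per population, for g from 2
#' to `g_max`:
#' \describe{
#'   \item{richness}{`sum_a Q_j,a(2g) prod_{j' != j} (1 - Q_j',a(2g))` - the
#'     expected number of alleles present in j's subsample and absent from
#'     every other subsample (the ADZE private allelic richness).}
#'   \item{frequency}{`sum_a p_j,a Q_j,a(2g) prod_{j' != j} (1 - Q_j',a(2g))`
#'     - the expected frequency mass, in population j, of alleles that
#'     appear private at subsample size g; lives on `[0, 1]` so the
#'     plateau/exponential selection thresholds read as percentages.}
#' }
#' Curves are averaged over all K-subsets containing j. A locus is skipped
#' (and logged) for a subset whose members have fewer than `g_max` typed
#' individuals there.
#'
#' @param freq_table an `allele_freq_table` over the reference populations
#' @param g_max maximum subsample size in individuals (default 7)
#' @param K_range subset sizes to evaluate (default `2:J`)
#' @return object of class `rarefaction_result`: long data frame with
#'   columns `locus`, `population`, `K`, `g`, `richness`, `frequency`,
#'   averaged over subsets; skipped locus/subset pairs in attribute
#'   `"skipped"`
#' @export
private_richness_curves <- function(freq_table, g_max = 7,
                                    K_range = NULL) {
  pops <- freq_table$groups
  J <- length(pops)
  if (is.null(K_range)) K_range <- 2:J
  if (any(K_range > J)) stop("K exceeds the number of populations (", J, ")")
  if (any(K_range < 2)) stop("K must be at least 2")
  gs <- 2:g_max
  acc <- list(); skipped <- list()
  for (l in freq_table$loci) {
    alleles <- unique(unlist(lapply(pops, function(gp)
      names(freq_table$counts[[gp]][[l]]))))
    if (!length(alleles)) next
    ## Q[pop, allele, g]: presence probability of each allele in a 2g-copy
    ## subsample of each population
    N <- freq_table$n_genes[pops, l]
    cnt <- sapply(alleles, function(al) vapply(pops, function(gp) {
      v <- freq_table$counts[[gp]][[l]][al]; if (is.na(v)) 0L else as.integer(v)
    }, 0L))
    cnt <- matrix(cnt, nrow = J, dimnames = list(pops, alleles))
    Q <- array(0, c(J, length(alleles), length(gs)),
               dimnames = list(pops, alleles, gs))
    ok_pop <- N >= 2 * g_max
    for (gi in seq_along(gs)) {
      for (j in seq_len(J)) {
        if (!ok_pop[j]) next
        Q[j, , gi] <- presence_probability(N[j], cnt[j, ], 2 * gs[gi])
      }
    }
    pfreq <- cnt / N
    for (K in K_range) {
      subsets <- utils::combn(J, K, simplify = FALSE)
      for (ss in subsets) {
        if (!all(ok_pop[ss])) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            locus = l, K = K, subset = paste(pops[ss], collapse = "+"),
            stringsAsFactors = FALSE)
          next
        }
        for (j in ss) {
          others <- setdiff(ss, j)
          for (gi in seq_along(gs)) {
            pr_absent <- if (length(others) == 1) 1 - Q[others, , gi] else
              apply(1 - Q[others, , gi, drop = FALSE], 2, prod)
            rich <- sum(Q[j, , gi] * pr_absent)
            freqm <- sum(pfreq[j, ] * Q[j, , gi] * pr_absent)
            acc[[length(acc) + 1L]] <- data.frame(
              locus = l, population = pops[j], K = K, g = gs[gi],
              richness = rich, frequency = freqm, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(acc))
    stop("no locus/subset combination had enough typed individuals")
  long <- do.call(rbind, acc)
  ## average across subsets containing each population
  agg <- stats::aggregate(long[c("richness", "frequency")],
                          long[c("locus", "population", "K", "g")], mean)
  agg <- agg[order(agg$locus, agg$population, agg$K, agg$g), ]
  rownames(agg) <- NULL
  attr(agg, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(agg, "g_max") <- g_max
  class(agg) <- c("rarefaction_result", "data.frame")
  agg
}

#' Classify the shape of a rarefaction curve
#'
#' Formalises the visual reading of private-allele rarefaction curves. With
#' `v` the final value and `d_last`, `d_prev` the last two increments:
#' decreasing when `d_last < 0`; plateau when `|d_last| <=
#' flat_eps * max(v, eps)` and `v >= plateau_thresh`; exponential when
#' `d_last > 0`, `d_last >= d_prev` and `v >= expo_thresh`; rejected
#' otherwise. The default thresholds are the 50% (plateau) and 45%
#' (exponential) selection bounds.
#'
#' @param curve numeric vector of at least 3 curve values (increasing g)
#' @param plateau_thresh minimum final value for a plateau call
#' @param expo_thresh minimum final value for an exponential call
#' @param flat_eps relative flatness tolerance for the plateau call
#' @return one of `"plateau"`, `"exponential"`, `"decreasing"`, `"rejected"`
#' @export
classify_trend <- function(curve, plateau_thresh = 0.50, expo_thresh = 0.45,
                           flat_eps = 0.05) {
  stopifnot(length(curve) >= 3)
  m <- length(curve)
  v <- curve[m]
  d_last <- curve[m] - curve[m - 1]
  d_prev <- curve[m - 1] - curve[m - 2]
  flat <- abs(d_last) <= flat_eps * max(v, 1e-12)
  ## flatness is judged before the sign of the last increment: saturating
  ## curves end with a tiny negative drift that is a plateau, not a decline
  if (flat && v >= plateau_thresh) return("plateau")
  if (d_last < 0) return("decreasing")
  if (d_last > 0 && d_last >= d_prev && v >= expo_thresh)
    return("exponential")
  "rejected"
}

#' Cross-validated selection of tracing loci
#'
#' Retains a (locus, population) pair when its rarefaction curve at the
#' largest population-combination level classifies as plateau or exponential
#' AND the population has at least one observed private allele at that locus
#' in the catalog - the cross-validation of rarefaction potential against
#' observed data.
#'
#' @param rarefaction a [private_richness_curves()] result
#' @param catalog an [observed_private_alleles()] catalog on the same
#'   partition
#' @param measure which rarefaction measure the trend reading uses
#'   (`"frequency"`, the default, or `"richness"`)
#' @param K combination level to read (default: the maximum available)
#' @inheritParams classify_trend
#' @return data frame `locus`, `population`, `allele`, `trend` of selected
#'   private alleles (one row per observed private allele at a selected
#'   locus/population)
#' @export
select_tracing_loci <- function(rarefaction, catalog,
                                measure = c("frequency", "richness"),
                                K = NULL, plateau_thresh = 0.50,
                                expo_thresh = 0.45, flat_eps = 0.05) {
  measure <- match.arg(measure)
  if (is.null(K)) K <- max(rarefaction$K)
  cur <- rarefaction[rarefaction$K == K, ]
  out <- list()
  for (key in unique(paste(cur$locus, cur$population, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    l <- parts[1]; pop <- parts[2]
    sl <- cur[cur$locus == l & cur$population == pop, ]
    sl <- sl[order(sl$g), ]
    if (nrow(sl) < 3) next
    trend <- classify_trend(sl[[measure]], plateau_thresh, expo_thresh, flat_eps)
    if (!trend %in% c("plateau", "exponential")) next
    obs <- catalog[catalog$locus == l & catalog$population == pop, ]
    if (!nrow(obs)) next
    obs$trend <- trend
    out[[length(out) + 1L]] <- obs
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus = character(0), allele = integer(0),
               population = character(0), trend = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Trace market individuals through selected private alleles
#'
#' Screens the genotypes of market individuals for the selected private
#' alleles. A hit is a carried selected allele; an individual is `traced`
#' to a population when it has at least one hit and all hits agree on that
#' population, `ambiguous` when hits point to several populations, and
#' `untraceable` with no hits. Ambiguity is reported, never resolved
#' silently.
#'
#' @param ds a [geno_dataset()]; only samples with `site_class == "market"`
#'   are screened
#' @param selected data frame with columns `locus`, `allele`, `population`
#'   (from [select_tracing_loci()] or an [observed_private_alleles()]
#'   catalog)
#' @return object of class `trace_report`: data frame with one row per
#'   market individual (`sample_id`, `verdict`, `source`, `n_hits`,
#'   `hits` as "locus:allele->population" strings)
#' @export
trace_individuals <- function(ds, selected) {
  if (!nrow(selected)) stop("no selected private alleles to screen for")
  market <- which(ds$meta$site_class == "market")
  rows <- list()
  for (i in market) {
    hits <- character(0); hit_pops <- character(0)
    for (s in seq_len(nrow(selected))) {
      j <- match(selected$locus[s], locus_names(ds))
      if (is.na(j)) next
      a <- ds$a1[i, j]; b <- ds$a2[i, j]
      if (is.na(a)) next
      if (a == selected$allele[s] || b == selected$allele[s]) {
        hits <- c(hits, paste0(selected$locus[s], ":", selected$allele[s],
                               "->", selected$population[s]))
        hit_pops <- c(hit_pops, selected$population[s])
      }
    }
    verdict <- if (!length(hits)) "untraceable"
      else if (length(unique(hit_pops)) == 1) "traced" else "ambiguous"
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = ds$meta$sample_id[i], verdict = verdict,
      source = if (verdict == "traced") hit_pops[1]
               else if (verdict == "ambiguous")
                 paste(sort(unique(hit_pops)), collapse = "|")
               else NA_character_,
      n_hits = length(hits),
      hits = paste(hits, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), verdict = character(0),
               source = character(0), n_hits = integer(0),
               hits = character(0), stringsAsFactors = FALSE)
  class(out) <- c("trace_report", "data.frame")
  out
}
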