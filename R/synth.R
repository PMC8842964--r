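# Seeded generators: Balding-Nichols microsatellite datasets with planted
# private alleles and market sampling, and Kingman-coalescent mtDNA samples.

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1   # degenerate tiny-alpha guard
  x / sum(x)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the microsatellite generator.
#' The defaults emulate the study design this package is built around:
#' six forest populations of unequal size (104 reference individuals), 20
#' multi-allelic loci, weak differentiation, substantial inbreeding, a few
#' loci carrying population-private alleles, market individuals drawn from
#' known source populations, and sporadic missing data.
#'
#' @param n_pops number of source (forest) populations J
#' @param pop_sizes integer vector of individuals per population (length
#'   `n_pops`)
#' @param n_loci number of microsatellite loci
#' @param alleles_per_locus ancestral alleles per locus
#' @param fst_target Balding-Nichols differentiation parameter in \[0, 1)
#' @param fis_target per-individual autozygosity probability in \[0, 1)
#' @param private_plan data frame with columns `locus` (index), `population`
#'   (label `"P<i>"`), `freq` in (0, 1): alleles planted private to one
#'   population at the stated frequency (other frequencies renormalised)
#' @param market_plan data frame with columns `market` (label), `n`
#'   (individuals); each market individual's source population is drawn from
#'   `weights` (matrix `nrow(market_plan)` x `n_pops`, rows summing to 1;
#'   default uniform)
#' @param weights optional mixture-weight matrix for `market_plan`
#' @param missing_rate MCAR missing-call probability in \[0, 1)
#' @param seed integer seed; all randomness flows from it
#' @return a `sim_config` list
#' @export
simulation_config <- function(n_pops = 6,
                              pop_sizes = c(30, 25, 15, 12, 12, 10),
                              n_loci = 20,
                              alleles_per_locus = 6,
                              fst_target = 0.10,
                              fis_target = 0.17,
                              private_plan = default_private_plan(),
                              market_plan = default_market_plan(),
                              weights = NULL,
                              missing_rate = 0.05,
                              seed = 1L) {
  stopifnot(n_pops >= 1, length(pop_sizes) == n_pops, all(pop_sizes >= 1),
            n_loci >= 1, alleles_per_locus >= 1,
            fst_target >= 0, fst_target < 1,
            fis_target >= 0, fis_target <= 1,
            missing_rate >= 0, missing_rate < 1)
  pops <- paste0("P", seq_len(n_pops))
  if (!is.null(private_plan)) {
    private_plan <- as.data.frame(private_plan)
    stopifnot(all(c("locus", "population", "freq") %in% names(private_plan)))
    if (any(private_plan$freq <= 0 | private_plan$freq >= 1))
      stop("planted private-allele frequencies must lie in (0, 1)")
    if (any(!private_plan$population %in% pops))
      stop("private_plan names unknown populations")
    if (any(private_plan$locus < 1 | private_plan$locus > n_loci))
      stop("private_plan names loci outside 1..n_loci")
  }
  if (!is.null(market_plan)) {
    market_plan <- as.data.frame(market_plan)
    stopifnot(all(c("market", "n") %in% names(market_plan)), all(market_plan$n >= 1))
    if (is.null(weights))
      weights <- matrix(1 / n_pops, nrow(market_plan), n_pops)
    weights <- as.matrix(weights)
    stopifnot(nrow(weights) == nrow(market_plan), ncol(weights) == n_pops)
    if (any(abs(rowSums(weights) - 1) > 1e-8))
      stop("market mixture weights must sum to 1 per market")
  }
  structure(list(n_pops = n_pops, pop_sizes = pop_sizes, pops = pops,
                 n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 fst_target = fst_target, fis_target = fis_target,
                 private_plan = private_plan, market_plan = market_plan,
                 weights = weights, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname simulation_config
#' @export
default_private_plan <- function() {
  ## seven loci carrying private alleles in four of the six populations,
  ## frequencies in the range where rarefaction curves plateau or climb
  data.frame(
    locus = c(1, 4, 7, 10, 13, 16, 19),
    population = c("P1", "P3", "P4", "P6", "P1", "P3", "P4"),
    freq = c(0.50, 0.45, 0.40, 0.35, 0.35, 0.30, 0.30),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulation_config
#' @export
default_market_plan <- function() {
  ## 65 market individuals across three trade endpoints, sourced from the
  ## whole range (uniform mixture weights by default)
  data.frame(market = c("M1", "M2", "M3"), n = c(25, 22, 18),
             stringsAsFactors = FALSE)
}

draw_genotypes <- function(freqs, n_ind, fis) {
  ## freqs: named frequency vector; returns 2-column matrix of allele labels
  labels <- as.integer(names(freqs))
  auto <- stats::runif(n_ind) < fis
  g1 <- sample(labels, n_ind, replace = TRUE, prob = freqs)
  g2 <- sample(labels, n_ind, replace = TRUE, prob = freqs)
  g2[auto] <- g1[auto]
  cbind(g1, g2)
}

#' Simulate a structured microsatellite dataset with known truth
#'
#' Draws ancestral allele frequencies per locus from a flat Dirichlet, then
#' population frequencies from the Balding-Nichols distribution
#' `Dirichlet(p_anc * (1 - F) / F)` with `F = fst_target` (populations copy
#' the ancestral frequencies when `F = 0`). Planted private alleles are
#' inserted as labels absent everywhere else at the planned frequency, with
#' the population's other frequencies renormalised. Genotypes are drawn with
#' inbreeding as per-individual autozygosity: with probability `fis_target`
#' one allele is drawn and duplicated, otherwise two independent draws.
#' Market individuals are drawn from the frequencies of a source population
#' sampled from the market's mixture weights and labelled
#' `site_class = "market"`. Missing calls are applied MCAR. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [simulation_config()]
#' @return list with `dataset` (a [geno_dataset()]) and `truth` (per-
#'   population allele frequencies actually used, the true source population
#'   of every market individual, and the planted private alleles)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_pops; L <- config$n_loci; K <- config$alleles_per_locus
  pops <- config$pops
  F <- config$fst_target

  ## per-locus allele labels mimic fragment sizes on disjoint ranges
  pop_freqs <- vector("list", L)
  for (l in seq_len(L)) {
    labels <- 100L + 50L * l + 2L * seq_len(K)
    p_anc <- rdirichlet1(rep(1, K))
    freqs <- matrix(0, J, K, dimnames = list(pops, labels))
    for (j in seq_len(J)) {
      freqs[j, ] <- if (F == 0) p_anc else rdirichlet1(p_anc * (1 - F) / F)
    }
    pop_freqs[[l]] <- freqs
  }

  planted <- config$private_plan
  if (!is.null(planted) && nrow(planted)) {
    planted$allele <- NA_integer_
    for (i in seq_len(nrow(planted))) {
      l <- planted$locus[i]; pop <- planted$population[i]; f <- planted$freq[i]
      if (f >= 1) stop("cannot accommodate private allele at frequency >= 1")
      lab <- 9000L + 10L * l + match(pop, pops)  # label absent everywhere else
      fr <- pop_freqs[[l]]
      fr <- cbind(fr, 0)
      colnames(fr)[ncol(fr)] <- lab
      fr[pop, ] <- c(fr[pop, -ncol(fr)] * (1 - f), f)
      pop_freqs[[l]] <- fr
      planted$allele[i] <- lab
    }
  }

  ## forest individuals
  n_forest <- sum(config$pop_sizes)
  ids <- character(0); pop_lab <- character(0); cls <- character(0)
  a1 <- NULL; a2 <- NULL
  g1 <- matrix(NA_integer_, n_forest, L); g2 <- g1
  row <- 0L
  for (j in seq_len(J)) {
    nj <- config$pop_sizes[j]
    for (l in seq_len(L)) {
      gg <- draw_genotypes(pop_freqs[[l]][j, ], nj, config$fis_target)
      g1[row + seq_len(nj), l] <- gg[, 1]
      g2[row + seq_len(nj), l] <- gg[, 2]
    }
    ids <- c(ids, paste0(pops[j], "_", seq_len(nj)))
    pop_lab <- c(pop_lab, rep(pops[j], nj))
    cls <- c(cls, rep("forest", nj))
    row <- row + nj
  }

  ## market individuals with recorded true sources
  sources <- character(0)
  mk <- config$market_plan
  if (!is.null(mk) && nrow(mk)) {
    m1 <- matrix(NA_integer_, sum(mk$n), L); m2 <- m1
    mrow <- 0L
    for (m in seq_len(nrow(mk))) {
      for (i in seq_len(mk$n[m])) {
        src <- sample(pops, 1, prob = config$weights[m, ])
        mrow <- mrow + 1L
        for (l in seq_len(L)) {
          gg <- draw_genotypes(pop_freqs[[l]][src, ], 1L, config$fis_target)
          m1[mrow, l] <- gg[1]; m2[mrow, l] <- gg[2]
        }
        sources <- c(sources, src)
        ids <- c(ids, paste0(mk$market[m], "_", i))
        pop_lab <- c(pop_lab, mk$market[m])
        cls <- c(cls, "market")
      }
    }
    g1 <- rbind(g1, m1); g2 <- rbind(g2, m2)
  }
  names(sources) <- ids[cls == "market"]

  ## coordinates: population centres on a rough south-north transect with
  ## within-forest scatter; markets get their own locations
  centre_lat <- stats::setNames(seq(6.4, 9.6, length.out = J), pops)
  centre_lon <- stats::setNames(2 + 0.8 * ((seq_len(J) %% 3) - 1), pops)
  lat <- numeric(length(ids)); lon <- numeric(length(ids))
  for (i in seq_along(ids)) {
    if (cls[i] == "forest") {
      lat[i] <- centre_lat[pop_lab[i]] + stats::runif(1, -0.08, 0.08)
      lon[i] <- centre_lon[pop_lab[i]] + stats::runif(1, -0.08, 0.08)
    } else {
      lat[i] <- stats::runif(1, 6.3, 9.7); lon[i] <- stats::runif(1, 1.2, 2.8)
    }
  }

  ## MCAR missingness
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(g1)) < config$missing_rate, nrow(g1))
    g1[drop] <- NA_integer_; g2[drop] <- NA_integer_
  }

  colnames(g1) <- colnames(g2) <- paste0("L", seq_len(L))
  ds <- geno_dataset(g1, g2, data.frame(
    sample_id = ids, population = pop_lab, site_class = cls,
    lat = lat, lon = lon, stringsAsFactors = FALSE))
  truth <- list(pop_freqs = pop_freqs,
                market_sources = sources,
                private_alleles = planted,
                config = config)
  list(dataset = ds, truth = truth)
}

#' Simulate a neutral-coalescent sequence sample
#'
#' Builds a Kingman coalescent genealogy for `n_seqs` lineages (exponential
#' waiting times with rate `choose(k, 2)` in coalescent units) and places
#' exactly `n_segsites` mutations uniformly on the total branch length
#' (conditioning on the observed number of segregating sites, the DnaSP-style
#' null), each at a distinct site under the infinite-sites model.
#' Alternatively, when `theta` is supplied, the mutation count is drawn as
#' Poisson with mean `theta / 2` per unit branch length. Binary sites are
#' rendered as ancestral `A` / derived `T`; with `seq_length` larger than the
#' number of variant sites the remaining positions are monomorphic `A`.
#'
#' @param n_seqs number of sequences (>= 2)
#' @param n_segsites number of segregating sites (>= 0); ignored when
#'   `theta` is given
#' @param seed optional integer seed
#' @param seq_length total sequence length (default: the number of variant
#'   sites, minimum 1)
#' @param theta optional scaled mutation rate for theta-conditioning
#' @return a [hap_alignment()]
#' @export
simulate_coalescent_sample <- function(n_seqs, n_segsites, seed = NULL,
                                       seq_length = NULL, theta = NULL) {
  stopifnot(n_seqs >= 2, is.null(theta) || theta >= 0)
  if (is.null(theta)) stopifnot(n_segsites >= 0)
  if (!is.null(seed)) set.seed(seed)

  ## coalescent genealogy: collect (branch length, leaf set) pairs
  active <- lapply(seq_len(n_seqs), function(i) i)
  birth <- rep(0, n_seqs)
  t_now <- 0
  branch_len <- numeric(0)
  branch_leaves <- list()
  k <- n_seqs
  while (k > 1) {
    t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    for (p in pair) {
      branch_len <- c(branch_len, t_now - birth[p])
      branch_leaves[[length(branch_leaves) + 1L]] <- active[[p]]
    }
    merged <- c(active[[pair[1]]], active[[pair[2]]])
    active <- c(active[-pair], list(merged))
    birth <- c(birth[-pair], t_now)
    k <- k - 1L
  }
  total_len <- sum(branch_len)
  S <- if (is.null(theta)) as.integer(n_segsites)
       else stats::rpois(1, theta / 2 * total_len)

  len <- max(1L, if (is.null(seq_length)) S else as.integer(seq_length))
  if (S > len) stop("seq_length smaller than the number of segregating sites")
  m <- matrix("A", n_seqs, len,
              dimnames = list(paste0("seq", seq_len(n_seqs)), NULL))
  if (S > 0) {
    hit <- sample.int(length(branch_len), S, replace = TRUE, prob = branch_len)
    pos <- if (len == S) seq_len(S) else sort(sample.int(len, S))
    for (s in seq_len(S)) {
      m[branch_leaves[[hit[s]]], pos[s]] <- "T"
    }
  }
  hap_alignment(m)
}
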