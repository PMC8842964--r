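# Isolation by distance: Edwards' chord genetic distance, great-circle
# geographic distances, Mantel permutation test.

#' Edwards' chord genetic distance
#'
#' `D(x, y) = sqrt(1 - (1/L) sum_l sum_a sqrt(p_x,l,a * p_y,l,a))` over the
#' loci typed in both units. At the population level the frequencies come
#' from an `allele_freq_table`; at the individual level each individual is
#' a 2-gene sample with within-individual frequencies 0, 0.5 or 1, and loci
#' missing in either member of a pair are dropped pairwise. Pairs with no
#' shared typed locus get an `NA` entry with a warning.
#'
#' @param x an `allele_freq_table` (population level) or a [geno_dataset()]
#'   (individual level)
#' @return symmetric distance matrix with zero diagonal
#' @export
edwards_distance <- function(x) {
  if (inherits(x, "allele_freq_table")) {
    units <- x$groups
    freq_fun <- function(u, l) af_freq(x, u, l)
    loci <- x$loci
  } else if (inherits(x, "geno_dataset")) {
    units <- x$meta$sample_id
    loci <- locus_names(x)
    freq_fun <- function(u, l) {
      i <- match(u, x$meta$sample_id); j <- match(l, loci)
      a <- x$a1[i, j]; b <- x$a2[i, j]
      if (is.na(a)) return(stats::setNames(numeric(0), character(0)))
      if (a == b) stats::setNames(1, a) else stats::setNames(c(0.5, 0.5), c(a, b))
    }
  } else stop("x must be an allele_freq_table or a geno_dataset")
  n <- length(units)
  d <- matrix(0, n, n, dimnames = list(units, units))
  for (i in seq_len(max(n - 1, 0))) {
    for (h in (i + 1):n) {
      tot <- 0; L <- 0
      for (l in loci) {
        pi <- freq_fun(units[i], l); ph <- freq_fun(units[h], l)
        if (!length(pi) || !length(ph)) next
        shared <- union(names(pi), names(ph))
        a <- stats::setNames(rep(0, length(shared)), shared)
        b <- a
        a[names(pi)] <- pi; b[names(ph)] <- ph
        tot <- tot + sum(sqrt(a * b))
        L <- L + 1
      }
      if (L == 0) {
        warning("no shared typed loci between ", units[i], " and ", units[h])
        d[i, h] <- d[h, i] <- NA_real_
      } else {
        d[i, h] <- d[h, i] <- sqrt(max(0, 1 - tot / L))
      }
    }
  }
  d
}

#' Great-circle geographic distances (km)
#'
#' Haversine distances on a sphere of radius 6371 km. At the population
#' level, unit coordinates are the centroids of member sample coordinates
#' unless centres are supplied.
#'
#' @param ds a [geno_dataset()] with coordinates
#' @param partition optional `sample_id -> group` mapping; when given,
#'   distances are between population centroids (or `centres`)
#' @param centres optional data frame `population, lat, lon` overriding
#'   centroids
#' @return symmetric matrix of distances in km
#' @export
geographic_distances <- function(ds, partition = NULL, centres = NULL) {
  if (is.null(partition)) {
    units <- ds$meta$sample_id
    lat <- ds$meta$lat; lon <- ds$meta$lon
  } else {
    units <- sort(unique(unname(partition)))
    lat <- lon <- numeric(length(units))
    for (k in seq_along(units)) {
      if (!is.null(centres) && units[k] %in% centres$population) {
        row <- centres[centres$population == units[k], ][1, ]
        lat[k] <- row$lat; lon[k] <- row$lon
      } else {
        ids <- names(partition)[partition == units[k]]
        idx <- match(ids, ds$meta$sample_id)
        lat[k] <- mean(ds$meta$lat[idx]); lon[k] <- mean(ds$meta$lon[idx])
      }
    }
  }
  if (anyNA(lat) || anyNA(lon)) {
    bad <- units[is.na(lat) | is.na(lon)]
    stop("missing coordinates for: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  n <- length(units)
  d <- matrix(0, n, n, dimnames = list(units, units))
  for (i in seq_len(max(n - 1, 0))) {
    for (h in (i + 1):n) {
      km <- geosphere::distHaversine(c(lon[i], lat[i]), c(lon[h], lat[h]),
                                     r = 6371000) / 1000
      d[i, h] <- d[h, i] <- km
    }
  }
  d
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation `r` between the upper-triangle entries of two
#' distance matrices; significance by jointly permuting rows and columns of
#' one matrix, `p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1)` (one-sided,
#' positive association).
#'
#' @param gen,geo symmetric matrices with matching dimensions and unit order
#' @param n_perm number of permutations
#' @param seed optional integer seed
#' @return list with `r`, `p_value`, `n_perm`
#' @export
mantel_test <- function(gen, geo, n_perm = 10000, seed = NULL) {
  stopifnot(is.matrix(gen), is.matrix(geo), all(dim(gen) == dim(geo)),
            nrow(gen) >= 3)
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(gen)
  x <- gen[ut]; y <- geo[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a distance matrix; Mantel r undefined")
    return(list(r = NA_real_, p_value = NA_real_, n_perm = n_perm))
  }
  r_obs <- stats::cor(x, y)
  hits <- 0L
  n <- nrow(gen)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    rp <- stats::cor(gen[perm, perm][ut], y)
    if (rp >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}
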