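# Builders for small in-code fixtures.

## build a geno_dataset from a list of "a/b" call strings per sample:
## calls = list(S1 = c("210/214", "./."), ...)
make_ds <- function(calls, population = NULL, site_class = NULL,
                    lat = NULL, lon = NULL,
                    loci = paste0("L", seq_along(calls[[1]]))) {
  n <- length(calls)
  L <- length(calls[[1]])
  a1 <- matrix(NA_integer_, n, L, dimnames = list(NULL, loci))
  a2 <- a1
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      cell <- calls[[i]][j]
      if (cell != "./.") {
        ab <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
        a1[i, j] <- ab[1]; a2[i, j] <- ab[2]
      }
    }
  }
  geno_dataset(a1, a2, data.frame(
    sample_id = names(calls),
    population = population %||% rep("P1", n),
    site_class = site_class %||% rep("forest", n),
    lat = lat %||% rep(NA_real_, n), lon = lon %||% rep(NA_real_, n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## alignment from a character vector of equal-length strings
make_aln <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- ids
  hap_alignment(m)
}

## exhaustive-enumeration oracle: exact probability that an allele with
## n_allele copies out of n_total appears in a uniform g-subsample
enum_presence_prob <- function(n_total, n_allele, g) {
  copies <- c(rep(1, n_allele), rep(0, n_total - n_allele))
  subs <- utils::combn(n_total, g)
  mean(apply(subs, 2, function(ix) any(copies[ix] == 1)))
}

## exhaustive oracle for expected private-allele count in population j of a
## two-population system: enumerate all joint subsamples
enum_private_richness_2pop <- function(counts1, counts2, g) {
  genes1 <- rep(as.integer(names(counts1)), counts1)
  genes2 <- rep(as.integer(names(counts2)), counts2)
  s1 <- utils::combn(length(genes1), g)
  s2 <- utils::combn(length(genes2), g)
  tot <- 0; nn <- 0
  for (i in seq_len(ncol(s1))) {
    al1 <- unique(genes1[s1[, i]])
    for (h in seq_len(ncol(s2))) {
      al2 <- unique(genes2[s2[, h]])
      tot <- tot + length(setdiff(al1, al2))
      nn <- nn + 1
    }
  }
  tot / nn
}
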