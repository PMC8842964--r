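#' Diploid microsatellite genotype dataset
#'
#' Container for diploid allele-size calls at a fixed set of microsatellite
#' loci, together with per-sample metadata (population, forest/market class,
#' optional coordinates). Calls are stored as two integer matrices `a1`/`a2`
#' (samples x loci) with the canonical ordering `a1 <= a2`; a missing call is
#' `NA` in both slots (half-typed calls are rejected).
#'
#' @param a1,a2 integer matrices of allele labels (e.g. fragment sizes),
#'   samples in rows, loci in columns. `NA` marks a missing call; a cell must
#'   be `NA` in both or neither matrix.
#' @param meta data frame with columns `sample_id`, `population`,
#'   `site_class` (one of `"forest"`, `"market"`) and optionally `lat`, `lon`
#'   in decimal degrees.
#' @return An object of class `geno_dataset`.
#' @examples
#' ds <- geno_dataset(
#'   a1 = matrix(c(210, 214), 2, 1, dimnames = list(NULL, "L1")),
#'   a2 = matrix(c(214, 214), 2, 1),
#'   meta = data.frame(sample_id = c("S1", "S2"), population = "P1",
#'                     site_class = "forest")
#' )
#' n_samples(ds)
#' @export
geno_dataset <- function(a1, a2, meta) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices a1 and a2 must have identical dimensions")
  if (is.null(colnames(a1)) && !is.null(colnames(a2))) colnames(a1) <- colnames(a2)
  if (is.null(colnames(a1)))
    colnames(a1) <- paste0("L", seq_len(ncol(a1)))
  colnames(a2) <- colnames(a1)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "site_class")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(a1))
    stop("metadata rows (", nrow(meta), ") do not match genotype rows (", nrow(a1), ")")
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (any(!nzchar(meta$population) | is.na(meta$population)))
    stop("population labels must be non-empty")
  bad <- xor(is.na(a1), is.na(a2))
  if (any(bad))
    stop("half-typed calls (one allele missing) are not allowed; first at sample ",
         meta$sample_id[which(bad, arr.ind = TRUE)[1, 1]])
  if (!all(c("lat", "lon") %in% names(meta))) { meta$lat <- NA_real_; meta$lon <- NA_real_ }
  ## canonical unordered pair: a1 <= a2
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  rownames(a1) <- rownames(a2) <- meta$sample_id
  structure(list(a1 = a1, a2 = a2, meta = meta), class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("geno_dataset:", nrow(x$a1), "samples x", ncol(x$a1), "loci\n")
  cat("  site classes:", paste(names(table(x$meta$site_class)),
                               table(x$meta$site_class), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(x$a1)), "/", length(x$a1), "\n")
  invisible(x)
}

#' @rdname geno_dataset
#' @param ds a `geno_dataset`
#' @export
n_samples <- function(ds) nrow(ds$a1)

#' @rdname geno_dataset
#' @export
n_loci <- function(ds) ncol(ds$a1)

#' @rdname geno_dataset
#' @export
locus_names <- function(ds) colnames(ds$a1)

#' Subset a genotype dataset by sample id
#'
#' @param ds a `geno_dataset`
#' @param ids character vector of sample ids to keep (order preserved as given)
#' @return a `geno_dataset` restricted to `ids`
#' @export
subset_samples <- function(ds, ids) {
  idx <- match(ids, ds$meta$sample_id)
  if (anyNA(idx)) stop("unknown sample ids: ", paste(ids[is.na(idx)], collapse = ", "))
  geno_dataset(ds$a1[idx, , drop = FALSE], ds$a2[idx, , drop = FALSE],
               ds$meta[idx, , drop = FALSE])
}

parse_native_cell <- function(cell, row, col) {
  cell <- trimws(cell)
  if (cell == "./." || cell == "" || is.na(cell)) return(c(NA_integer_, NA_integer_))
  m <- regmatches(cell, regexec("^([0-9]+)/([0-9]+)$", cell))[[1]]
  if (length(m) != 3)
    stop("malformed allele cell at row ", row, ", column '", col, "': '", cell, "'")
  as.integer(m[2:3])
}

#' Read a genotype table
#'
#' Reads a wide genotype CSV in either of two dialects. `"native"`: columns
#' `sample_id, population, site_class, lat, lon` followed by one column per
#' locus containing `"a1/a2"` calls with `"./."` for missing. `"genalex"`:
#' the same metadata columns followed by two adjacent integer columns per
#' locus (GenAlEx export convention) where `0` codes a missing allele; the
#' locus name is taken from the first column of each pair, and a pair with
#' exactly one zero is rejected as half-typed. Lines starting with `#` are
#' ignored in both dialects.
#'
#' @param path path to a CSV file
#' @param dialect `"native"` or `"genalex"`
#' @return a [geno_dataset()]
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, dialect = c("native", "genalex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  metacols <- c("sample_id", "population", "site_class", "lat", "lon")
  miss <- setdiff(metacols[1:3], names(raw))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  for (mc in c("lat", "lon")) if (!mc %in% names(raw)) raw[[mc]] <- NA
  meta <- data.frame(sample_id = raw$sample_id, population = raw$population,
                     site_class = raw$site_class,
                     lat = suppressWarnings(as.numeric(raw$lat)),
                     lon = suppressWarnings(as.numeric(raw$lon)),
                     stringsAsFactors = FALSE)
  loccols <- setdiff(names(raw), metacols)
  if (!length(loccols)) stop("no locus columns found")
  if (dialect == "native") {
    L <- length(loccols)
    a1 <- matrix(NA_integer_, nrow(raw), L, dimnames = list(NULL, loccols))
    a2 <- a1
    for (j in seq_len(L)) {
      cells <- raw[[loccols[j]]]
      for (i in seq_along(cells)) {
        ab <- parse_native_cell(cells[i], i, loccols[j])
        a1[i, j] <- ab[1]; a2[i, j] <- ab[2]
      }
    }
  } else {
    if (length(loccols) %% 2 != 0)
      stop("genalex dialect requires an even number of allele columns")
    first <- loccols[seq(1, length(loccols), by = 2)]
    second <- loccols[seq(2, length(loccols), by = 2)]
    L <- length(first)
    a1 <- matrix(NA_integer_, nrow(raw), L, dimnames = list(NULL, first))
    a2 <- a1
    for (j in seq_len(L)) {
      v1 <- suppressWarnings(as.integer(raw[[first[j]]]))
      v2 <- suppressWarnings(as.integer(raw[[second[j]]]))
      bad <- which(is.na(v1) | is.na(v2))
      if (length(bad))
        stop("malformed allele cell at row ", bad[1], ", column '", first[j], "'")
      half <- which(xor(v1 == 0, v2 == 0))
      if (length(half))
        stop("half-typed genalex call at row ", half[1], ", locus '", first[j], "'")
      v1[v1 == 0] <- NA; v2[v2 == 0] <- NA
      a1[, j] <- v1; a2[, j] <- v2
    }
  }
  geno_dataset(a1, a2, meta)
}

#' Write a genotype table in the native CSV dialect
#'
#' Emits the wide `"a1/a2"` CSV read by [read_genotype_table()], preceded by a
#' `#` provenance comment recording the package version (and seed, if given).
#' A write/read round trip reproduces calls, metadata and ordering exactly.
#'
#' @param ds a [geno_dataset()]
#' @param path output path
#' @param seed optional seed recorded in the provenance header
#' @export
write_genotype_table <- function(ds, path, seed = NULL) {
  cells <- matrix("./.", n_samples(ds), n_loci(ds),
                  dimnames = list(NULL, locus_names(ds)))
  typed <- !is.na(ds$a1)
  cells[typed] <- paste0(ds$a1[typed], "/", ds$a2[typed])
  df <- cbind(ds$meta[c("sample_id", "population", "site_class", "lat", "lon")],
              as.data.frame(cells, stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Consensus genotypes from PCR triplicates
#'
#' Applies the replicate-consensus rule used for low-quality (dried or
#' chemically treated) samples: an allele enters the consensus call for a
#' sample x locus cell if and only if it is present in at least two of the
#' three replicate calls. Two qualifying alleles give a heterozygous call,
#' one gives a homozygous call, none gives a missing call. More than two
#' qualifying alleles is a scoring conflict: the cell is set missing with a
#' warning.
#'
#' @param replicates list of exactly three [geno_dataset()] objects with
#'   identical samples and loci (metadata taken from the first)
#' @return a consensus [geno_dataset()]
#' @export
consensus_from_replicates <- function(replicates) {
  if (length(replicates) != 3) stop("exactly 3 replicate datasets are required")
  ref <- replicates[[1]]
  for (r in replicates[-1]) {
    if (!identical(locus_names(r), locus_names(ref)) ||
        !identical(r$meta$sample_id, ref$meta$sample_id))
      stop("replicates must share identical samples and loci")
  }
  n <- n_samples(ref); L <- n_loci(ref)
  a1 <- matrix(NA_integer_, n, L, dimnames = list(NULL, locus_names(ref)))
  a2 <- a1
  n_conflict <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      present <- unlist(lapply(replicates, function(r) {
        al <- c(r$a1[i, j], r$a2[i, j])
        unique(al[!is.na(al)])
      }))
      if (!length(present)) next
      tab <- table(present)
      qual <- as.integer(names(tab)[tab >= 2])
      if (length(qual) == 0) next
      if (length(qual) > 2) { n_conflict <- n_conflict + 1L; next }
      if (length(qual) == 1) qual <- c(qual, qual)
      a1[i, j] <- min(qual); a2[i, j] <- max(qual)
    }
  }
  if (n_conflict > 0)
    warning(n_conflict, " cell(s) had >2 alleles supported by >=2 replicates; set missing")
  geno_dataset(a1, a2, ref$meta)
}

#' Filter samples by genotyping completeness
#'
#' Keeps samples typed at a minimum fraction of loci (default 0.75, i.e. at
#' least 15 of 20 loci), the quality bound applied before any downstream
#' analysis. Idempotent.
#'
#' @param ds a [geno_dataset()]
#' @param min_fraction minimum fraction of typed loci in (0, 1]
#' @return the filtered [geno_dataset()]
#' @export
filter_by_completeness <- function(ds, min_fraction = 0.75) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(ds$a1))
  keep <- frac >= min_fraction
  message("completeness filter (>= ", min_fraction, "): retained ", sum(keep),
          ", removed ", sum(!keep), " samples")
  if (!any(keep)) {
    warning("no samples pass the completeness filter")
  }
  geno_dataset(ds$a1[keep, , drop = FALSE], ds$a2[keep, , drop = FALSE],
               ds$meta[keep, , drop = FALSE])
}

#' Sample partitions
#'
#' A partition maps sample ids to group labels (each sample to at most one
#' group). `pooled_partition()` puts every sample in one group,
#' `population_partition()` groups samples by their population label,
#' optionally restricted to a site class.
#'
#' @param ds a [geno_dataset()]
#' @param site_class optional class filter (`"forest"` or `"market"`)
#' @param group_name label for the pooled group
#' @return named character vector mapping `sample_id` to group label
#' @export
pooled_partition <- function(ds, group_name = "all") {
  stats::setNames(rep(group_name, n_samples(ds)), ds$meta$sample_id)
}

#' @rdname pooled_partition
#' @export
population_partition <- function(ds, site_class = NULL) {
  keep <- rep(TRUE, n_samples(ds))
  if (!is.null(site_class)) keep <- ds$meta$site_class %in% site_class
  stats::setNames(ds$meta$population[keep], ds$meta$sample_id[keep])
}

#' Per-partition allele counts and frequencies
#'
#' Tabulates gene-copy counts of every allele per group x locus over
#' non-missing calls; `n_genes` is twice the number of typed individuals.
#' Frequencies are counts / n_genes and sum to one wherever `n_genes > 0`;
#' group x locus cells with no typed individual are flagged undefined.
#'
#' @param ds a [geno_dataset()]
#' @param partition named character vector `sample_id -> group` (see
#'   [pooled_partition()]); samples absent from the partition are ignored
#' @return an object of class `allele_freq_table` with elements `groups`,
#'   `loci`, `counts` (nested list `[[group]][[locus]]` of named gene-copy
#'   counts), `n_genes` (group x locus matrix) and `undefined` (logical
#'   matrix of flagged empty cells)
#' @export
allele_frequencies <- function(ds, partition = pooled_partition(ds)) {
  ids <- names(partition)
  unknown <- setdiff(ids, ds$meta$sample_id)
  if (length(unknown)) stop("partition names unknown samples: ",
                            paste(utils::head(unknown, 3), collapse = ", "))
  groups <- unique(unname(partition))
  loci <- locus_names(ds)
  n_genes <- matrix(0L, length(groups), length(loci),
                    dimnames = list(groups, loci))
  counts <- stats::setNames(vector("list", length(groups)), groups)
  idx_of <- match(ids, ds$meta$sample_id)
  for (gp in groups) {
    rows <- idx_of[partition == gp]
    counts[[gp]] <- stats::setNames(vector("list", length(loci)), loci)
    for (j in seq_along(loci)) {
      al <- c(ds$a1[rows, j], ds$a2[rows, j])
      al <- al[!is.na(al)]
      n_genes[gp, j] <- length(al)
      counts[[gp]][[j]] <- if (length(al)) {
        tb <- table(al)
        stats::setNames(as.integer(tb), names(tb))
      } else stats::setNames(integer(0), character(0))
    }
  }
  structure(list(groups = groups, loci = loci, counts = counts,
                 n_genes = n_genes, undefined = n_genes == 0,
                 partition = partition),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", length(x$groups), "group(s) x",
      length(x$loci), "loci\n")
  if (any(x$undefined))
    cat("  flagged undefined (no typed individuals):", sum(x$undefined), "cells\n")
  invisible(x)
}

#' Allele frequencies for one group x locus cell
#'
#' @param tab an `allele_freq_table`
#' @param group,locus group and locus names
#' @return named numeric vector of relative allele frequencies (empty when
#'   the cell has no typed individuals)
#' @export
af_freq <- function(tab, group, locus) {
  cts <- tab$counts[[group]][[locus]]
  n <- tab$n_genes[group, locus]
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  cts / n
}

#' Read an aligned FASTA file
#'
#' Reads aligned DNA sequences (equal lengths enforced), restricted to the
#' alphabet `A, C, G, T, N, -`. Returns a `hap_alignment`: an uppercase
#' character matrix (sequences x sites) with sequence ids as row names.
#'
#' @param path FASTA file path
#' @return a `hap_alignment`
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE),
    error = function(e)
      stop("could not parse FASTA file '", path, "': ", conditionMessage(e)))
  if (length(dna) == 0) stop("empty FASTA file: ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1)
    stop("sequences are not aligned (unequal lengths): ",
         paste(names(dna)[lens != max(lens)], collapse = ", "))
  m <- toupper(do.call(rbind, lapply(dna, as.character)))
  rownames(m) <- names(dna)
  hap_alignment(m)
}

#' @rdname read_alignment
#' @param m character matrix of aligned sequences (rows = sequences); values
#'   must be in `A, C, G, T, N, -` (case-insensitive)
#' @export
hap_alignment <- function(m) {
  m <- toupper(as.matrix(m))
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty alignment")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alignment contains characters outside {A,C,G,T,N,-}: ",
         paste(bad, collapse = ", "))
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  structure(m, class = c("hap_alignment", "matrix"))
}

#' Write a `hap_alignment` to FASTA
#'
#' @param aln a `hap_alignment`
#' @param path output path
#' @export
write_alignment <- function(aln, path) {
  lines <- character(0)
  for (i in seq_len(nrow(aln))) {
    lines <- c(lines, paste0(">", rownames(aln)[i]),
               paste(aln[i, ], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}
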