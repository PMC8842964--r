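# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

## numerically stable log(exp(a) + exp(b)), vectorised over a
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

## deterministic child seed for a named pipeline stage; keeps results < 2^31
substream_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 48271 + h) %% 2147483629
}

## cheap deterministic content hash for provenance headers (no timestamps so
## reports are byte-identical under the same seed)
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

provenance_header <- function(seed = NULL, extra = NULL) {
  bits <- c(
    paste0("pangotrace ", as.character(utils::packageVersion("pangotrace"))),
    if (!is.null(seed)) paste0("seed=", seed),
    extra
  )
  paste0("# ", paste(bits, collapse = "; "))
}

write_table_with_header <- function(df, path, seed = NULL, extra = NULL,
                                    sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ratio C(a, g) / C(b, g) in log space; returns 0 when a < g
choose_ratio <- function(a, b, g) {
  out <- exp(lchoose(a, g) - lchoose(b, g))
  out[a < g] <- 0
  out
}
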