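# Internal helpers shared across the package.

# Deterministic 31-bit seed derived from a master seed and up to three
# stream keys (site index, group index, subject index). Keeps independent
# per-subject streams so adding subjects to one site never perturbs
# another. Chained multiply-mod steps keep every intermediate below 2^53,
# so the keys are never rounded away even for 31-bit masters.
derive_seed <- function(master, a = 0L, b = 0L, c = 0L) {
  m <- 2147483563
  x <- as.numeric(master) %% m
  for (key in c(a, b, c)) x <- (x * 69069 + as.numeric(key) + 1) %% m
  as.integer(x) + 1L
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so simulation helpers have no side effects.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Atomic table write: temp file in the target directory, then rename, so an
# interrupted run never leaves a truncated table behind.
write_table_atomic <- function(x, path, sep = "\t", row.names = FALSE,
                               col.names = TRUE, header_lines = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, "w")
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(x, con, sep = sep, quote = FALSE,
                     row.names = row.names, col.names = col.names)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

# Mann-Whitney AUC of `score` for separating positives from negatives;
# used to summarise how well the meta-analysis ranks planted regions.
rank_auc <- function(score, positive) {
  positive <- as.logical(positive)
  stopifnot(length(score) == length(positive))
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative cases")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
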