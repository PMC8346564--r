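# internal helpers shared across modules

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stop_myelo <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "myelotrace_error")))
}

check_subtype <- function(subtype) {
  bad <- setdiff(unique(as.character(subtype)), MYELO_SUBTYPES)
  if (length(bad) > 0L) {
    stop_myelo("unknown subtype label(s): %s (allowed: %s)",
               "myelo_subtype_error",
               paste(bad, collapse = ", "), paste(MYELO_SUBTYPES, collapse = ", "))
  }
  invisible(as.character(subtype))
}

check_region <- function(region) {
  bad <- setdiff(unique(as.character(region)), MYELO_REGIONS)
  if (length(bad) > 0L) {
    stop_myelo("unknown region label(s): %s (allowed: %s)",
               "myelo_region_error",
               paste(bad, collapse = ", "), paste(MYELO_REGIONS, collapse = ", "))
  }
  invisible(as.character(region))
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_myelo("file not found: %s", "myelo_io_error", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop_myelo("%s: missing column(s): %s", "myelo_io_error",
               path, paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))
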