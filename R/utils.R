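# shared internal helpers

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_arg <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop_arg("`%s` must be a single integer >= %d (got %s)", name, min,
             paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_arg("`%s` must be a single value in [0, 1]", name)
  }
  as.numeric(x)
}

# deterministic TSV writer used by all serializers
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# stable md5 of an R object via its canonical JSON serialization
object_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
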