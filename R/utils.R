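# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  if (is.null(old)) {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  } else {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive a per-unit substream seed from a global seed. Fixed offsets mean
# that adding a mouse (or a stage) never changes the draws of earlier ones.
# 104729 is prime; results stay inside the 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647L)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic TSV writer used for every exported table.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}
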