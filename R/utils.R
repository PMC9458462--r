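#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

## Error conditions carry classes so the command-line wrapper can map them
## to distinct exit codes (usage vs input format vs computation).
format_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("inoscan_format_error", "inoscan_error", "error")))
}

usage_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("inoscan_usage_error", "inoscan_error", "error")))
}

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## DNA -> RNA alphabet normalization used at every reader boundary.
normalize_rna <- function(x) {
  chartr("tT", "uU", toupper(x))
}

check_base <- function(b, arg = deparse(substitute(b))) {
  b <- normalize_rna(b)
  if (!all(b %in% RNA_BASES))
    stop(sprintf("`%s` must be one of A, C, G, U (got %s)",
                 arg, paste(setdiff(b, RNA_BASES), collapse = ", ")))
  b
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
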