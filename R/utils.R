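# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators behave as pure functions of (args, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# UniProt accession: 6-character core pattern (covers O/P/Q and A-N,R-Z
# series; 10-character accessions also accepted).
.uniprot_regex <- paste0(
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|",
  "[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
)

is_uniprot_accession <- function(x) {
  grepl(.uniprot_regex, x)
}

# Uppercase gene symbols; matching everywhere is exact string equality
# after this normalization.
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_parse <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
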