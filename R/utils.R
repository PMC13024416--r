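# Internal helpers: seeded evaluation, reverse complement, sequence checks.

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a deterministic per-stage seed from the top-level seed so that
# stages re-run in isolation reproduce the pipeline run. Kept below 2^31.
stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 100000L) * 17989L +
    (sum(utf8ToInt(stage)) %% 17989L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Characters accepted in DNA input: IUPAC ambiguity codes plus gap.
.iupac_chars <- "ACGTUNRYSWKMBDHV"

is_dna_string <- function(x) {
  !grepl(sprintf("[^%s%s]", .iupac_chars, tolower(.iupac_chars)), x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
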