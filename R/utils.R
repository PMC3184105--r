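# Internal helpers shared across modules.

# Deterministic sub-seed for a named generator substream, so one global seed
# reproducibly drives several independent generators. Polynomial string hash
# folded into [0, 2^31 - 2].
.substreamSeed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483646) + 1L
}

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG state.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.geomean <- function(x) exp(mean(log(x)))

.checkAlphabet <- function(seq_chr, where = "sequence") {
  bad <- setdiff(unique(strsplit(seq_chr, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("%s contains characters outside A/C/G/T/N: %s",
                 where, paste(bad, collapse = ",")), call. = FALSE)
  invisible(TRUE)
}

.revcomp <- function(seq_chr) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
}

# Mismatches between a fixed pattern and the same-length substring of `subject`
# starting at `at` (characters, not Biostrings views; N never matches).
.mismatchAt <- function(pattern_chars, subject_chars, at) {
  sum(pattern_chars != subject_chars[at:(at + length(pattern_chars) - 1L)])
}

# 1-based inclusive -> 0-based half-open (internal convenience; the public
# surface is 1-based inclusive throughout).
.toHalfOpen <- function(start, end) cbind(start - 1L, end)
.fromHalfOpen <- function(lo, hi) cbind(lo + 1L, hi)

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
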