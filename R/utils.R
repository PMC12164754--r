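## Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulate_* calls are deterministic
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# The 61 sense codons and their amino acids, from the standard genetic code.
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

codon_to_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# Six serine codons (standard code).
SERINE_CODONS <- c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC")

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

# Split a CDS string into codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' @importFrom utils head tail
log2fc <- function(num, den) log2(num / den)

# Named-vector lookup that errors on missing keys.
lookup <- function(map, keys, what = "key") {
  idx <- match(keys, names(map))
  if (anyNA(idx)) {
    stop("unresolvable ", what, ": ",
         paste(unique(keys[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  unname(map[idx])
}
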