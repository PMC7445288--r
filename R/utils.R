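# Internal helpers: seeded evaluation, deterministic string hashing, small checks.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state, so library functions never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else
      suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Polynomial rolling hash of a string into [1, 2^31 - 2]. Exact in double
# precision (intermediate values stay below 2^53), so identical on all
# platforms; used to key derived seeds, never for security.
.hash_string <- function(s) {
  p <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (b in utf8ToInt(enc2utf8(s))) h <- (h * 131 + b) %% p
  as.integer(h %% (p - 1) + 1)
}

#' Derive a child seed from a global seed and a label
#'
#' Stable derivation keyed by label so that stages (or restarts) consume
#' independent, reproducible randomness regardless of execution order.
#'
#' @param seed integer master seed.
#' @param label character key (e.g. a stage name).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  p <- 2147483647
  as.integer((((as.numeric(seed) %% p) * 48271) %% p + .hash_string(label)) %% (p - 1) + 1)
}

.is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Fixed amino-acid alphabet used by the surrogate predictor weight matrices.
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.valid_nt <- function(s) !is.na(s) && nzchar(s) && !grepl("[^ACGT]", s)

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
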