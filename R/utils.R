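#' @keywords internal
"_PACKAGE"

# Reported percentages are truncated (not rounded) to one decimal: this is
# the convention under which 80/120 prints as 66.6%, and it is applied to
# every cross-stage ratio the pipeline reports.
pct_1dp <- function(num, den) {
  if (den == 0) return(0)
  trunc(1000 * num / den) / 10
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

clip01 <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seed derivation, kept within 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}
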