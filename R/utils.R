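#' @keywords internal
"_PACKAGE"

# stop() with sprintf formatting, no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# x must be a single finite number
assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("'%s' must be a single finite number", name)
  invisible(x)
}

assert_character <- function(x, name) {
  if (!is.character(x) || anyNA(x))
    abort("'%s' must be a character vector without NA", name)
  invisible(x)
}

# derive a per-stage seed from a global seed; keeps results of earlier
# stages unchanged when later stages are added (fixed offsets, not a shared
# stream); result stays inside the 32-bit integer range set.seed() accepts
derive_seed <- function(seed, stage) {
  assert_scalar_num(seed, "seed")
  as.integer((as.double(seed) + 99991 * stage) %% 2147483647)
}
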