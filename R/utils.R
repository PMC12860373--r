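# internal helpers shared across modules

# Deterministic 29-bit string hash (polynomial, base 31). Exact in doubles:
# intermediate values stay below 2^36, so no precision loss before the modulus.
str_hash <- function(s, salt = 0L) {
  stopifnot(length(s) == 1L, is.character(s))
  h <- as.double(salt) %% 536870912
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 536870912
  h
}

# Derive a stage seed from a global seed and a stage name; stays within
# 32-bit integer range so it is usable with set.seed().
fan_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 2147483 + str_hash(stage)) %% 2147483647L)
}

# round() in R is round-half-even; printed accuracies use half-up.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

assert_that <- function(ok, msg, class = "coformerscout_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}
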