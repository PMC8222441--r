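# Counter-based uniform generator.
#
# The cohort simulator samples every field of every row from
# u = hash(seed, row, field), so a value depends only on its coordinates:
# reordering rows, adding fields, or generating rows lazily never changes
# any other sampled value, and the same seed reproduces the stream exactly
# on any platform. The hash is the murmur3 32-bit finalizer applied to the
# mixed key; arithmetic is done in doubles mod 2^32 (exact: all
# intermediates stay below 2^53).

.M32 <- 2^32

# 32-bit modular multiply via 16-bit split (keeps products < 2^48).
mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (lo * b + ((hi * b) %% 65536) * 65536) %% .M32
}

xor32 <- function(a, b) {
  ai <- as.integer(a - ifelse(a >= 2^31, .M32, 0))
  bi <- as.integer(b - ifelse(b >= 2^31, .M32, 0))
  r <- bitwXor(ai, bi)
  r + ifelse(r < 0, .M32, 0)
}

fmix32 <- function(h) {
  h <- xor32(h, h %/% 2^16)
  h <- mul32(h, 0x85ebca6b)
  h <- xor32(h, h %/% 2^13)
  h <- mul32(h, 0xc2b2ae35)
  xor32(h, h %/% 2^16)
}

# Uniform in (0, 1); vectorised over row (and field if same length).
ctr_unif <- function(seed, row, field) {
  h <- fmix32((seed %% .M32 + 0x9e3779b9) %% .M32)
  h <- fmix32((xor32(h, row %% .M32) + 0x85ebca6b) %% .M32)
  h <- fmix32((xor32(h, field %% .M32) + 0xc2b2ae35) %% .M32)
  (h + 0.5) / .M32
}

# Categorical sample by inverse CDF; probs need not be normalised.
ctr_sample <- function(seed, row, field, probs, labels = seq_along(probs)) {
  cdf <- cumsum(probs) / sum(probs)
  labels[findInterval(ctr_unif(seed, row, field), cdf) + 1L]
}

ctr_bern <- function(seed, row, field, p) {
  ctr_unif(seed, row, field) < p
}

# Field registry: stable integer ids for sampled fields (appending is safe,
# reordering is not).
ctr_field <- function(name) {
  fields <- c("level", "resources_used", "admitted", "admit_type",
              "sex", "age", "trigger", "spo2_missing", "spo2_value",
              "chief_complaint", "underlying", "underlying_resp",
              "accessory", "wheezing", "crying", "trauma",
              "temp_jitter", "hr_jitter", "rr_jitter", "sbp_jitter",
              "workday", "shift", "self_transport", "nurse_exp",
              "overcrowded", "predicted_extra")
  i <- match(name, fields)
  if (is.na(i)) stop("unknown RNG field: ", name, call. = FALSE)
  i
}
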