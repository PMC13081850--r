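# Reproducible randomness.
#
# Every random draw in the package is keyed by a stable hash of
# (master seed, node id, internal state [, purpose tag]), so a given
# sequence's random choices are identical regardless of generation order,
# of which other sequences were generated, and of process restarts.

.HASH_MOD <- 2147483647  # 2^31 - 1

str_hash <- function(...) {
  s <- paste(..., sep = "\r")
  b <- utf8ToInt(s)
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% .HASH_MOD
  h
}

rng_key <- function(master_seed, node_id, istate = 0, tag = "") {
  ist <- if (is_bigint(istate)) format(istate) else sprintf("%.0f", istate)
  as.integer(str_hash(sprintf("%.0f", master_seed), node_id, ist, tag))
}

# Seed the session RNG for one keyed draw stream. generate() saves and
# restores the caller's .Random.seed around the whole pass.
seed_stream <- function(master_seed, node_id, istate = 0, tag = "") {
  set.seed(rng_key(master_seed, node_id, istate, tag))
}
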