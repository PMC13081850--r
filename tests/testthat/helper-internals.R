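# Aliases for internal helpers exercised directly by the unit tests.
# The suite runs against the installed package, so internals are reached
# through the namespace.

bi_add <- oligopool:::bi_add
bi_sub <- oligopool:::bi_sub
bi_mul <- oligopool:::bi_mul
bi_divmod <- oligopool:::bi_divmod
bi_to_double <- oligopool:::bi_to_double
sn_mul <- oligopool:::sn_mul
sn_sub <- oligopool:::sn_sub
sn_coerce <- oligopool:::sn_coerce
sn_format <- oligopool:::sn_format
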