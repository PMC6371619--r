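`%||%` <- function(x, y) if (is.null(x)) y else x

## draw one integer sub-seed (< 2^31) from the current RNG stream
derive_seed <- function() sample.int(.Machine$integer.max, 1L)
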