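# Round half away from zero, the convention used in the printed tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() without the "Error in f(...)" call prefix
abort <- function(...) stop(..., call. = FALSE)
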