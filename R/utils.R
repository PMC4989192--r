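`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# tolerance used when matching sample times (ms) against window edges
.time_eps <- 1e-6

stop_posterp <- function(...) stop(..., call. = FALSE)
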