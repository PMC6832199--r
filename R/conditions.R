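# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish configuration, schema, degenerate-input and plain input errors.

mirscore_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "mirscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_config     <- function(msg) mirscore_abort(msg, "mirscore_config_error")
stop_schema     <- function(msg) mirscore_abort(msg, "mirscore_schema_error")
stop_degenerate <- function(msg) mirscore_abort(msg, "mirscore_degenerate_error")
stop_input      <- function(msg) mirscore_abort(msg, "mirscore_input_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up to `digits` decimals (R's round() is round-half-even;
# printed mortality percentages follow the half-up convention)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
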