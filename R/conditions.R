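# Classed conditions used across the package. Every user-facing failure mode
# named in the module contracts gets its own condition class so callers (and
# the CLI exit-code mapping) can dispatch on it.

semiperm_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("semiperm_", class), "semiperm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_alignment  <- function(msg, ...) semiperm_abort("alignment_error", msg, ...)
abort_alphabet   <- function(msg, ...) semiperm_abort("alphabet_error", msg, ...)
abort_metadata   <- function(msg, ...) semiperm_abort("metadata_error", msg, ...)
abort_schema     <- function(msg, ...) semiperm_abort("schema_error", msg, ...)
abort_ploidy     <- function(msg, ...) semiperm_abort("ploidy_error", msg, ...)
abort_input      <- function(msg, ...) semiperm_abort("input_error", msg, ...)
abort_undefined  <- function(msg, ...) semiperm_abort("undefined_error", msg, ...)
abort_usage      <- function(msg, ...) semiperm_abort("usage_error", msg, ...)
abort_config     <- function(msg, ...) semiperm_abort("config_error", msg, ...)
abort_simulation <- function(msg, ...) semiperm_abort("simulation_error", msg, ...)
abort_bootstrap  <- function(msg, ...) semiperm_abort("bootstrap_error", msg, ...)
abort_unresolved_ancestry <- function(msg, ...)
  semiperm_abort("unresolved_ancestry_error", msg, ...)
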