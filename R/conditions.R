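# Typed error conditions used across the package. Every reader/validator
# failure carries a subclass so callers (and tests) can branch on the kind
# of failure rather than on message text.

ic_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "immunocyt_error", "error")))
}

ic_format_error       <- function(msg, ...) ic_stop("immunocyt_format_error", msg, ...)
ic_parse_error        <- function(msg, ...) ic_stop("immunocyt_parse_error", msg, ...)
ic_duplicate_error    <- function(msg, ...) ic_stop("immunocyt_duplicate_key_error", msg, ...)
ic_missing_gene_error <- function(msg, ...) ic_stop("immunocyt_missing_gene_error", msg, ...)
ic_degenerate_error   <- function(msg, ...) ic_stop("immunocyt_degenerate_input_error", msg, ...)
ic_config_error       <- function(msg, ...) ic_stop("immunocyt_config_error", msg, ...)
ic_alignment_error    <- function(msg, ...) ic_stop("immunocyt_alignment_error", msg, ...)
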