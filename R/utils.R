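# Classed conditions so callers (and the CLI wrapper) can map error families
# to exit codes without string matching.
abort <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "lipidcontrast_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Normalise a (cell_line, treatment) group key to a length-2 character vector.
as_group_key <- function(group) {
  if (is.list(group)) group <- unlist(group, use.names = FALSE)
  group <- as.character(group)
  if (length(group) != 2L || anyNA(group) || any(!nzchar(group))) {
    abort("validation_error",
          "a group key must be c(cell_line, treatment), e.g. c('HUH7', 'none')")
  }
  group
}

group_label <- function(group) {
  group <- as_group_key(group)
  if (identical(group[2], "none")) group[1] else paste(group[1], group[2], sep = "+")
}
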