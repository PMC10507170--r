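# Internal helpers.

# classed condition so callers (e.g. imputation) can intercept specific
# failure modes with tryCatch
md_condition <- function(msg, class) {
  structure(class = c(class, "markerdigest_error", "error", "condition"),
            list(message = msg, call = NULL))
}

md_stop <- function(msg, class) stop(md_condition(msg, class))

`%||%` <- function(a, b) if (is.null(a)) b else a

# short config fingerprint for output file headers
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(x, give.attr = TRUE)), f)
  unname(tools::md5sum(f))
}
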