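# internal helpers shared across modules

# round half-up (report parity with printed tables; base round() is half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

stop_schema <- function(missing, where) {
  stop(sprintf("schema error in %s: missing column(s) %s", where,
               paste(sQuote(missing), collapse = ", ")), call. = FALSE)
}

check_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop_schema(missing, where)
  invisible(TRUE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a probability in [0, 1]")
  invisible(TRUE)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config(field, "must be > 0")
  invisible(TRUE)
}
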