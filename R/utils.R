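# Accept either a numeric vector or a data frame with a `value` column.
as_values <- function(x, arg = "series") {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) {
      stop("`", arg, "` data frame must have a `value` column.", call. = FALSE)
    }
    return(as.numeric(x$value))
  }
  as.numeric(x)
}

check_scalar_prob_coef <- function(x, name, open_unit = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("`", name, "` must be a single finite number.", call. = FALSE)
  }
  if (open_unit && abs(x) >= 1) {
    stop("`", name, "` must satisfy |", name, "| < 1.", call. = FALSE)
  }
  invisible(x)
}
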