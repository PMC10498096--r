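`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || any(!is.finite(x)) || any(!lo_ok) || any(!hi_ok)) {
    stop2(sprintf("`%s` must lie in %s0, 1%s", name,
                  if (open_left) "(" else "[", if (open_right) ")" else "]"))
  }
  invisible(x)
}

# deterministic number formatting used for text artifacts (TSV/HTML/JSON)
fmt_num <- function(x, digits = 10) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- NA_character_
  out
}
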