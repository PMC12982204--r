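#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows distinct row_number n lag lead
#'   across all_of first last pull rename relocate
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_chr map_dbl map_int map_lgl map2 pmap imap keep
#' @importFrom stats setNames runif
#' @importFrom utils head tail packageVersion modifyList
NULL

# locale-independent ordering everywhere (radix = C collation)
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# numeric formatter used by every text export: fixed 3 decimals, "" for NA
fmt_ms <- function(x) {
  out <- sprintf("%.3f", x)
  out[is.na(x)] <- ""
  out
}

# shortest decimal representation that round-trips the double exactly
fmt_num_exact <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("null")
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    for (d in c(6L, 10L, 15L, 17L)) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 22, format = "g")
  }, character(1))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# tibble() without the construction overhead; recycles length-1 inputs
fast_tbl <- function(...) {
  l <- list(...)
  n <- if (length(l)) max(lengths(l)) else 0L
  l <- lapply(l, function(v) if (length(v) == n) v else
    rep(v, length.out = n))
  tibble::new_tibble(l, nrow = n)
}

stopf <- function(fmt, ..., class = "scarfkit_error") {
  abort(sprintf(fmt, ...), class = class)
}

validation_error <- function(fmt, ...) {
  stopf(fmt, ..., class = c("scarfkit_validation_error", "scarfkit_error"))
}
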