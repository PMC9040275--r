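# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
dn_msg <- function(..., verbose = getOption("dnburden.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Harmonic number H_k = sum_{i=1}^{k} 1/i
#' @keywords internal
harmonic_number <- function(k) {
  stop_if_not(is_number(k) && k >= 0 && k == floor(k),
              "k must be a nonnegative integer")
  if (k == 0) return(0)
  sum(1 / seq_len(k))
}
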