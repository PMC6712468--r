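#' Round half away from zero
#'
#' Percentages are reported rounded half-up (0.125 -> 0.13 at 2 digits),
#' matching conventional manuscript formatting rather than R's banker's
#' rounding.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @examples
#' roundHalfUp(85.3195, 2)  # 85.32
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop unless all named conditions hold; names become the message
check_that <- function(...) {
  conds <- c(...)
  if (!all(conds)) {
    stop(paste(names(conds)[!conds], collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

revcomp_str <- function(s) {
  vapply(strsplit(s, ""), function(ch)
    paste(rev(unname(comp_base(ch))), collapse = ""), character(1))
}
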