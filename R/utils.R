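#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used by most
#' assembly/report tools when printing percentages), as opposed to [round()]'s
#' banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small guard against binary representation of exact halves
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Contig N50
#'
#' The length L such that contigs of length >= L together contain at least half
#' of the total assembled bases (ties resolved toward the larger N50).
#'
#' @param lengths numeric vector of sequence lengths.
#' @return the N50 length (0 for an empty vector).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) return(0)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Format a fraction as a percentage string
#'
#' @param frac fraction in `[0, 1]` (may be NA).
#' @param digits decimals to print (half-up rounding).
#' @return character like `"0.025%"`.
#' @export
format_percent <- function(frac, digits = 3) {
  ifelse(is.na(frac), NA_character_,
         paste0(formatC(round_half_up(100 * frac, digits),
                        format = "f", digits = digits), "%"))
}

# merge possibly-overlapping 0-based half-open intervals; matrix with cols start,end
merge_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals[, 1] + 1,
                                         end = intervals[, 2]))
  cbind(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
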