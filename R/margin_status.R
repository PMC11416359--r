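#' Margin classification configuration
#'
#' Margins below 5 mm are conventionally reported as "close" (UK Royal
#' College of Pathologists); a margin of 0 means tumor at the resection
#' surface ("involved"). The involved threshold is an extension for
#' completeness: the clinical convention only names "close".
#'
#' @param threshold_close mm; margins `>=` this are clear (default 5).
#' @param threshold_involved mm; margins `<=` this are involved (default 0).
#' @return object of class `margin_status`.
#' @export
margin_status <- function(threshold_close = 5, threshold_involved = 0) {
  if (!is_scalar_number(threshold_close) || !is_scalar_number(threshold_involved))
    stopf("thresholds must be finite scalars")
  if (threshold_involved >= threshold_close)
    stopf("threshold_involved (%g) must be < threshold_close (%g)",
          threshold_involved, threshold_close)
  structure(list(threshold_close = threshold_close,
                 threshold_involved = threshold_involved),
            class = "margin_status")
}

#' Classify a resection margin as clear, close or involved
#'
#' `clear` iff margin >= `threshold_close`; `involved` iff margin <=
#' `threshold_involved`; `close` otherwise. Vectorized over `margin`.
#'
#' @param margin margin distance(s), mm, non-negative.
#' @param status_config a [margin_status()].
#' @return character vector in \{"clear", "close", "involved"\}.
#' @examples
#' classify_margin(c(4.9, 5, 0))
#' @export
classify_margin <- function(margin, status_config = margin_status()) {
  if (any(!is.finite(margin)) || any(margin < 0))
    stopf("margins must be finite and >= 0")
  ifelse(margin >= status_config$threshold_close, "clear",
         ifelse(margin <= status_config$threshold_involved, "involved", "close"))
}
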