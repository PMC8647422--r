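# MR severity grading from regurgitant volume.

#' Classify MR severity from regurgitant volume
#'
#' Grades MR volume (mL) as none (< 10), mild (10-30), moderate
#' (30-60) or severe (>= 60). The printed grade boundaries overlap at
#' 30 and 60 mL; they are resolved as half-open intervals closed on the
#' left, consistent with the "< 10" and ">= 60" endpoints. Negative
#' inputs (possible from the indirect method) are treated as 0.
#'
#' @param mrVolume numeric vector of MR volumes in mL (finite).
#' @return ordered factor with levels none < mild < moderate < severe.
#' @examples
#' classifyMRSeverity(c(0, 16, 30, 60))
#' @export
classifyMRSeverity <- function(mrVolume) {
  if (any(!is.finite(mrVolume)))
    stop("MR volume must be finite")
  v <- pmax(mrVolume, 0)
  lv <- c("none", "mild", "moderate", "severe")
  g <- ifelse(v < 10, "none",
       ifelse(v < 30, "mild",
       ifelse(v < 60, "moderate", "severe")))
  factor(g, levels = lv, ordered = TRUE)
}

#' Severity category levels
#'
#' The fixed ordered category set used for severity cross-tabulations.
#' @return character(4).
#' @export
severityLevels <- function() c("none", "mild", "moderate", "severe")
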