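#' Sleep stage levels
#'
#' The five AASM sleep stages used throughout the package, in canonical
#' order: Wake, N1, N2, N3 (non-REM depth levels) and REM.
#'
#' @return Character vector of length 5.
#' @export
stage_levels <- function() c("Wake", "N1", "N2", "N3", "REM")

as_stage_factor <- function(x) {
  f <- factor(as.character(x), levels = stage_levels())
  if (anyNA(f) && !anyNA(x)) {
    bad <- unique(setdiff(as.character(x), stage_levels()))
    stop("unknown sleep stage label(s): ", paste(bad, collapse = ", "))
  }
  f
}

#' Harmonize Rechtschaffen & Kales labels to AASM stages
#'
#' Maps the older 8-mode R&K hypnogram vocabulary onto the five AASM stages:
#' S1 -> N1, S2 -> N2, and both S3 and S4 -> N3 (slow-wave sleep is merged
#' under the AASM standard). `movement` and `unknown` epochs carry no usable
#' stage and are dropped; their positions are returned so callers can drop
#' the matching signal epochs.
#'
#' @param raw_labels Character vector with values in
#'   `wake, S1, S2, S3, S4, REM, movement, unknown` (case-insensitive for
#'   `wake`/`REM`/`movement`/`unknown`).
#' @return A list with `labels` (factor over [stage_levels()]) and
#'   `dropped` (integer indices of removed epochs, possibly empty).
#' @export
#' @examples
#' harmonize_labels(c("wake", "S1", "S2", "S3", "S4", "REM"))
harmonize_labels <- function(raw_labels) {
  raw <- as.character(raw_labels)
  key <- tolower(raw)
  map <- c(wake = "Wake", s1 = "N1", s2 = "N2", s3 = "N3", s4 = "N3",
           rem = "REM", movement = NA, unknown = NA)
  unknown_sym <- setdiff(unique(key), names(map))
  if (length(unknown_sym) > 0) {
    stop("unknown hypnogram symbol(s): ", paste(unknown_sym, collapse = ", "),
         "; expected wake, S1, S2, S3, S4, REM, movement, unknown")
  }
  mapped <- unname(map[key])
  dropped <- which(is.na(mapped))
  if (length(dropped) > 0) {
    message(length(dropped), " movement/unknown epoch(s) dropped at index: ",
            paste(dropped, collapse = ", "))
  }
  list(labels = as_stage_factor(mapped[!is.na(mapped)]),
       dropped = dropped)
}
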