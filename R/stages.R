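# Stage vocabularies.
#
# AASM5 is the reference (PSG) vocabulary: wake plus the four AASM sleep
# stages scored in 30-s epochs.  DEV4 is the consumer-device vocabulary:
# wake, merged light (N1+N2), deep (N3) and REM, reported in 1-min epochs.
# UNSCORED marks epochs no annotation covers (gaps in an export).

#' Stage vocabularies
#'
#' Stage label sets used throughout the package. `AASM5` is the
#' polysomnography vocabulary (`W`, `N1`, `N2`, `N3`, `REM`); `DEV4` is the
#' 4-stage device vocabulary (`WAKE`, `LIGHT`, `DEEP`, `REM`). The special
#' label `UNSCORED` is permitted in either and marks epochs not covered by
#' any annotation.
#'
#' @format Character vectors of stage codes.
#' @name stage_vocabularies
NULL

#' @rdname stage_vocabularies
#' @export
AASM5 <- c("W", "N1", "N2", "N3", "REM")

#' @rdname stage_vocabularies
#' @export
DEV4 <- c("WAKE", "LIGHT", "DEEP", "REM")

UNSCORED <- "UNSCORED"

#' @rdname stage_vocabularies
#' @export
DEV4_SLEEP <- c("LIGHT", "DEEP", "REM")

vocab_levels <- function(vocabulary) {
  switch(vocabulary,
    AASM5 = AASM5,
    DEV4  = DEV4,
    stop("unknown vocabulary: ", vocabulary, call. = FALSE)
  )
}

check_stages <- function(stages, vocabulary) {
  ok <- stages %in% c(vocab_levels(vocabulary), UNSCORED)
  if (!all(ok)) {
    stop("stage label(s) not in vocabulary ", vocabulary, ": ",
         paste(unique(stages[!ok]), collapse = ", "), call. = FALSE)
  }
  invisible(stages)
}

# AASM5 -> DEV4 merge map (N1 and N2 collapse into LIGHT).
MERGE_AASM5_TO_DEV4 <- c(
  W = "WAKE", N1 = "LIGHT", N2 = "LIGHT", N3 = "DEEP", REM = "REM",
  UNSCORED = "UNSCORED"
)
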