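#' GENIA event schema
#'
#' The nine event types of the GENIA event-extraction task, grouped into
#' three classes: simple events (SVT) with a single protein Theme, Binding
#' (BIND) with up to two protein Themes, and regulation (REG) with a Theme
#' and an optional Cause, either of which may reference a protein or
#' another event.
#'
#' @return A data.frame with one row per event type and columns
#'   \code{type}, \code{class} (\code{"SVT"}, \code{"BIND"} or
#'   \code{"REG"}), \code{max_themes}, \code{allows_cause} and
#'   \code{theme_can_be_event}.
#' @export
event_schema <- function() {
  data.frame(
    type = c("Gene_expression", "Transcription", "Localization",
             "Protein_catabolism", "Phosphorylation",
             "Binding",
             "Regulation", "Positive_regulation", "Negative_regulation"),
    class = c(rep("SVT", 5L), "BIND", rep("REG", 3L)),
    max_themes = c(rep(1L, 5L), 2L, rep(1L, 3L)),
    allows_cause = c(rep(FALSE, 6L), rep(TRUE, 3L)),
    theme_can_be_event = c(rep(FALSE, 6L), rep(TRUE, 3L)),
    stringsAsFactors = FALSE
  )
}

#' Event type names
#'
#' @param class Optional event class (\code{"SVT"}, \code{"BIND"},
#'   \code{"REG"}) to restrict to.
#' @return Character vector of event type names.
#' @export
event_types <- function(class = NULL) {
  sch <- event_schema()
  if (!is.null(class)) sch <- sch[sch$class %in% class, , drop = FALSE]
  sch$type
}

#' Class of an event type
#'
#' @param type Character vector of event type names.
#' @return Character vector of classes, one per input type.
#' @export
event_class <- function(type) {
  sch <- event_schema()
  idx <- match(type, sch$type)
  if (anyNA(idx)) {
    stop("unknown event type(s): ", paste(unique(type[is.na(idx)]), collapse = ", "))
  }
  sch$class[idx]
}

is_reg_type <- function(type) event_class(type) == "REG"
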