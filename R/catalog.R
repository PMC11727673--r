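#' Outcome item catalog for total joint arthroplasty quality of care
#'
#' Returns the packaged catalog of 13 quality-of-care outcome attributes
#' used in the total joint arthroplasty (TJA) preference study that this
#' package emulates. Each row is one choice item of the best-worst scaling
#' questionnaire. Three items are "quick" variants that add a speed
#' component to an outcome (quick return of daily function, quick pain
#' relief, quick return to hobbies).
#'
#' @return A data frame with one row per item and columns
#'   \describe{
#'     \item{item_id}{short stable token used in all files and results}
#'     \item{label}{display name}
#'     \item{description}{one-sentence plain-language definition}
#'     \item{is_quick_variant}{logical, whether the item is a "quick" variant}
#'   }
#' @examples
#' cat13 <- tja_outcomes()
#' nrow(cat13)            # 13
#' sum(cat13$is_quick_variant)  # 3
#' @export
tja_outcomes <- function() {
  out <- data.frame(
    item_id = c("adl", "pain", "reint", "comp", "qadl", "hobby", "qpain",
                "qhobby", "comm", "know", "heard", "pos", "neg"),
    label = c("ADL", "Pain", "Reintervention", "Complication", "qADL",
              "Hobby", "qPain", "qHobby", "Communication", "Knowledge",
              "Heard", "Positive", "Negative"),
    description = c(
      "Improved motion and daily function (e.g. stairs, getting out of a chair)",
      "Relief of pain",
      "Avoiding a repeat surgery in the future",
      "Avoiding complications (e.g. infection, readmission)",
      "Quick improvement in motion and daily function",
      "Improved ability to participate in hobbies, sports and other activities",
      "Quick resolution of pain",
      "Quick improvement in ability to participate in hobbies and activities",
      "Open, frequent communication with the care team",
      "Gaining knowledge and feeling informed about surgical care",
      "Feeling heard and respected by the care team",
      "Increased positive emotions (confidence, peace of mind)",
      "Minimized negative emotions (fear, uncertainty, sadness)"),
    is_quick_variant = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                         TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  validate_catalog(out)
  out
}

#' Validate a choice-item catalog
#'
#' Checks the structural invariants of an item catalog: required columns
#' present, item ids unique and non-empty.
#'
#' @param catalog a data frame with at least an `item_id` column.
#' @return the catalog, invisibly, if valid; otherwise an error.
#' @export
validate_catalog <- function(catalog) {
  if (!is.data.frame(catalog) || !"item_id" %in% names(catalog))
    stop("catalog must be a data frame with an 'item_id' column")
  ids <- as.character(catalog$item_id)
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop("catalog item_id entries must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate item_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(catalog)
}
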