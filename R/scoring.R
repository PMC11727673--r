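#' Best-minus-worst counting scores
#'
#' Tallies, for every item, the number of times it was picked as most
#' important (`n_best`) and least important (`n_worst`) over all
#' respondents and choice sets, and computes the best-minus-worst count
#' `bw = n_best - n_worst` and the availability-standardized score
#' `bw / (r * n_respondents)`, where `r` is the design's replication
#' number (each respondent sees each item `r` times). The standardized
#' score is bounded in [-1, +1]; on complete data the scores sum to zero
#' across items because every block contributes exactly one +1 and one
#' -1.
#'
#' Incomplete respondents are rejected rather than partially counted:
#' filter with [filter_complete()] first. This keeps the availability
#' denominator exact.
#'
#' @param x a `"bws_study"` object, or a long response data frame
#'   (columns `respondent_id`, `block`, `best`, `worst`).
#' @param design the `"bibd"` design (taken from `x` when it is a study).
#' @param items item ids (taken from `x` when it is a study).
#' @return An object of class `"bws_scores"`: a data frame with one row
#'   per item and columns `item_id`, `n_best`, `n_worst`, `bw`,
#'   `availability`, `standardized`, `rank`, sorted by rank.
#' @examples
#' st <- filter_complete(study_emulation(master_seed = 1))$included
#' head(count_scores(st), 4)
#' @export
count_scores <- function(x, design = NULL, items = NULL) {
  d <- .as_response_data(x, design, items)
  resp <- d$responses; design <- d$design; items <- d$items

  if (any(is.na(resp$best) | is.na(resp$worst)))
    stop("incomplete responses present; apply filter_complete() before scoring")
  .check_picks_in_blocks(resp, design, items)

  n_resp <- length(unique(resp$respondent_id))
  availability <- design$r * n_resp
  n_best <- table(factor(resp$best, levels = items))
  n_worst <- table(factor(resp$worst, levels = items))
  out <- data.frame(item_id = items,
                    n_best = as.integer(n_best),
                    n_worst = as.integer(n_worst),
                    stringsAsFactors = FALSE)
  out$bw <- out$n_best - out$n_worst
  out$availability <- availability
  out$standardized <- out$bw / availability
  out <- out[order(-out$standardized, out$item_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_respondents") <- n_resp
  class(out) <- c("bws_scores", "data.frame")
  out
}

#' Rank items by score or estimated utility
#'
#' Stable descending sort of items by their standardized counting score
#' (for `"bws_scores"`) or estimated utility (for `"maxdiff_fit"` or any
#' data frame with `item_id` and a `beta` or `standardized` column).
#' Ties are broken by lexicographic item id.
#'
#' @param x scores or estimation results.
#' @return A data frame with `item_id`, `score` and `rank` (1 = highest).
#' @export
rank_items <- function(x) {
  if (inherits(x, "maxdiff_fit")) x <- x$coefficients
  if (!is.data.frame(x) || !"item_id" %in% names(x))
    stop("need a data frame with an item_id column")
  score <- if ("beta" %in% names(x)) x$beta
  else if ("standardized" %in% names(x)) x$standardized
  else stop("no 'beta' or 'standardized' column to rank on")
  if (anyDuplicated(x$item_id))
    stop("duplicate item ids: ",
         paste(unique(x$item_id[duplicated(x$item_id)]), collapse = ", "))
  ord <- order(-score, x$item_id)
  out <- data.frame(item_id = x$item_id[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out
}

# Normalise study / data.frame inputs into (responses, design, items)
.as_response_data <- function(x, design = NULL, items = NULL) {
  if (inherits(x, "bws_study"))
    return(list(responses = x$responses, design = x$design, items = x$items))
  if (is.data.frame(x)) {
    if (is.null(design)) stop("a design must be supplied with a raw ",
                              "response data frame")
    if (is.null(items)) items <- sprintf("item%02d", seq_len(design$v))
    need <- c("respondent_id", "block", "best", "worst")
    miss <- setdiff(need, names(x))
    if (length(miss)) stop("response data lacks column(s): ",
                           paste(miss, collapse = ", "))
    return(list(responses = x, design = design, items = as.character(items)))
  }
  stop("expected a 'bws_study' or a long response data frame")
}

# Data-integrity check: each pick must name an item inside its block and
# best != worst; errors name the respondent and block.
.check_picks_in_blocks <- function(resp, design, items) {
  ok <- !is.na(resp$best) & !is.na(resp$worst)
  if (!any(ok)) return(invisible(TRUE))
  r <- resp[ok, , drop = FALSE]
  bi <- match(r$best, items); wi <- match(r$worst, items)
  blk <- design$blocks[r$block, , drop = FALSE]
  in_best <- !is.na(bi) & (rowSums(blk == bi) > 0L)
  in_worst <- !is.na(wi) & (rowSums(blk == wi) > 0L)
  bad <- which(!in_best | !in_worst | r$best == r$worst)
  if (length(bad)) {
    b1 <- bad[1L]
    stop("invalid pick for respondent ", r$respondent_id[b1], ", block ",
         r$block[b1], ": best='", r$best[b1], "', worst='", r$worst[b1],
         "' (must be two distinct items of that block)")
  }
  invisible(TRUE)
}

#' @export
print.bws_scores <- function(x, digits = 3, ...) {
  n <- attr(x, "n_respondents", exact = TRUE)
  cat("Best-worst counting scores",
      if (!is.null(n)) sprintf(" (%d respondents)", n), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = digits)
  invisible(x)
}
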