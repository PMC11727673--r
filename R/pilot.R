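#' Screen pilot Likert ratings into a final item list
#'
#' Applies the pilot-phase ceiling screen: candidate outcomes are rated
#' on a 1-10 Likert scale by pilot respondents, and items whose average
#' rating falls below the cutoff are dropped from the final
#' questionnaire. An item whose mean is exactly the cutoff is retained
#' (only items averaging strictly less are removed). The input order of
#' the retained items is preserved.
#'
#' @param table pilot ratings: a data frame or matrix with respondents
#'   in rows and candidate items in columns, values in `[1, 10]`.
#' @param cutoff retention threshold on the item mean (default 8).
#' @param na_policy `"forbid"` (default; any missing rating is an error)
#'   or `"available"` (item means computed over available ratings).
#' @return An object of class `"pilot_screen"`: list with `retained` and
#'   `dropped` (character vectors of item names, input order preserved)
#'   and `means` (named numeric vector of item means).
#' @examples
#' ratings <- example_pilot()
#' sc <- screen_pilot(ratings)
#' length(sc$retained)   # 13
#' @export
screen_pilot <- function(table, cutoff = 8, na_policy = c("forbid",
                                                          "available")) {
  na_policy <- match.arg(na_policy)
  m <- as.matrix(table)
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("item%02d", seq_len(ncol(m)))
  if (nrow(m) < 1L) stop("need at least one pilot respondent")
  storage.mode(m) <- "double"

  bad <- which(!is.na(m) & (m < 1 | m > 10), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "rating out of the 1-10 range at respondent %s, item '%s' (value %g)",
      rownames(m)[bad[1L, 1L]] %||% bad[1L, 1L],
      colnames(m)[bad[1L, 2L]], m[bad[1L, 1L], bad[1L, 2L]]))
  }
  if (na_policy == "forbid" && anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf(
      "missing rating at respondent %s, item '%s' (set na_policy = 'available' to allow)",
      rownames(m)[miss[1L, 1L]] %||% miss[1L, 1L],
      colnames(m)[miss[1L, 2L]]))
  }

  means <- colMeans(m, na.rm = (na_policy == "available"))
  keep <- means >= cutoff
  structure(list(retained = colnames(m)[keep],
                 dropped = colnames(m)[!keep],
                 means = means, cutoff = cutoff),
            class = "pilot_screen")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pilot_screen <- function(x, ...) {
  cat(sprintf("Pilot screen (cutoff %g): %d retained, %d dropped\n",
              x$cutoff, length(x$retained), length(x$dropped)))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped: ", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic pilot rating table
#'
#' Generates the packaged synthetic pilot dataset: 20 respondents rating
#' 19 candidate outcomes on the 1-10 scale, constructed so that the 13
#' items of the final catalog average at least 8 and six additional
#' candidates average below 8. A few respondents rate every item 10,
#' reproducing the ceiling effect that motivates best-worst scaling over
#' Likert rating. Individual ratings are synthetic; only the 19-to-13
#' screening structure is anchored to the emulated study.
#'
#' @param seed integer seed.
#' @param n_respondents number of pilot respondents (default 20).
#' @param n_ceiling how many respondents rate everything 10 (default 3).
#' @return A data frame (`n_respondents` rows, 19 columns) of ratings;
#'   the first 13 columns carry the final catalog's item ids.
#' @export
example_pilot <- function(seed = 1L, n_respondents = 20L, n_ceiling = 3L) {
  stopifnot(n_respondents > n_ceiling)
  final_items <- tja_outcomes()$item_id
  extra_items <- c("scar", "stay", "opioid", "work", "sleep", "cost")
  items <- c(final_items, extra_items)
  target <- c(stats::setNames(rep(c(9.4, 9.0, 8.6), length.out = 13),
                              final_items),
              stats::setNames(rep(c(6.2, 6.8, 5.8), length.out = 6),
                              extra_items))

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n_free <- n_respondents - n_ceiling
  m <- matrix(10, nrow = n_respondents, ncol = length(items),
              dimnames = list(sprintf("P%02d", seq_len(n_respondents)),
                              items))
  for (j in seq_along(items)) {
    # ceiling raters contribute 10s; the rest scatter around a level
    # chosen so the overall mean stays on the intended side of 8
    lvl <- (target[j] * n_respondents - 10 * n_ceiling) / n_free
    vals <- round(lvl + stats::runif(n_free, -1.2, 1.2))
    m[(n_ceiling + 1L):n_respondents, j] <- pmin(10, pmax(1, vals))
  }
  as.data.frame(m)
}
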