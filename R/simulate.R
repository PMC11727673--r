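# Probability of each ordered (best, worst) pair within one block under
# the MaxDiff rule: P(best=i, worst=j) proportional to exp(u_i - u_j)
# over all ordered pairs of distinct items in the block. Returns a data
# frame of pairs with probabilities summing to 1.
maxdiff_pair_probs <- function(u) {
  k <- length(u)
  idx <- which(outer(seq_len(k), seq_len(k), "!="), arr.ind = TRUE)
  w <- exp(u[idx[, 1L]] - u[idx[, 2L]])
  data.frame(best = idx[, 1L], worst = idx[, 2L], prob = w / sum(w))
}

#' Simulate one respondent's best/worst picks
#'
#' Draws one complete response set over all blocks of a questionnaire.
#' Respondent-level utilities are the profile means plus one normal
#' perturbation per item (sd = `heterogeneity_sd` of the profile), drawn
#' once for the respondent. Within each block the ordered (best, worst)
#' pair is drawn with probability proportional to
#' `exp(u_best - u_worst)` over all ordered pairs of distinct items in
#' the block (the MaxDiff choice rule). Reproducible given `rng_seed`.
#'
#' @param x a `"questionnaire"` or `"bibd"` object.
#' @param profile a `"utility_profile"` covering every item.
#' @param rng_seed integer seed for this respondent.
#' @param respondent_id token recorded in the output.
#' @param items item ids (required when `x` is a bare design without ids).
#' @return A data frame in long format with one row per block and columns
#'   `respondent_id`, `phase`, `block`, `best`, `worst` (item ids).
#' @export
simulate_response <- function(x, profile, rng_seed,
                              respondent_id = "R001", items = NULL) {
  qd <- .as_design_items(x, items)
  design <- qd$design; items <- qd$items
  stopifnot(inherits(profile, "utility_profile"))
  missing_items <- setdiff(items, names(profile$utility))
  if (length(missing_items))
    stop("profile does not cover item(s): ",
         paste(missing_items, collapse = ", "))

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  u <- profile$utility[items]
  if (profile$heterogeneity_sd > 0)
    u <- u + stats::rnorm(length(u), sd = profile$heterogeneity_sd)

  best <- character(design$b); worst <- character(design$b)
  for (i in seq_len(design$b)) {
    blk <- design$blocks[i, ]
    pp <- maxdiff_pair_probs(u[blk])
    pick <- sample.int(nrow(pp), 1L, prob = pp$prob)
    best[i] <- items[blk[pp$best[pick]]]
    worst[i] <- items[blk[pp$worst[pick]]]
  }
  data.frame(respondent_id = respondent_id, phase = profile$phase,
             block = seq_len(design$b), best = best, worst = worst,
             stringsAsFactors = FALSE)
}

.as_design_items <- function(x, items = NULL) {
  if (inherits(x, "questionnaire"))
    return(list(design = x$design, items = x$items))
  if (inherits(x, "bibd")) {
    if (is.null(items)) items <- sprintf("item%02d", seq_len(x$v))
    return(list(design = x, items = as.character(items)))
  }
  stop("expected a 'questionnaire' or 'bibd' object")
}

#' Simulate a phase-stratified best-worst scaling study
#'
#' Generates a synthetic study dataset: for each phase stratum the
#' requested number of complete respondents whose picks follow that
#' phase's latent utility profile, plus `n_submitted_extra` respondents
#' with incomplete questionnaires. Incompleteness is missing completely
#' at random: each incomplete respondent has 1 to 3 whole block picks
#' (best and worst) deleted. A single `master_seed` fans out to
#' per-respondent child seeds through a counter, so the dataset is fully
#' reproducible and each respondent independently re-simulable.
#'
#' @param x a `"questionnaire"` or `"bibd"` object.
#' @param strata_counts named integer vector, phase label -> number of
#'   complete respondents (e.g. `c(pre_op = 36, short_post = 55,
#'   long_post = 62)`).
#' @param profiles named list of `"utility_profile"` objects covering
#'   every phase in `strata_counts`; defaults to [default_profile()] per
#'   phase.
#' @param n_submitted_extra number of additional, incomplete respondents
#'   (spread across the strata proportionally to `strata_counts`).
#' @param missing_blocks integer vector of possible per-respondent counts
#'   of deleted block picks for the incomplete respondents.
#' @param master_seed integer master seed.
#' @param items item ids when `x` is a bare design.
#' @return An object of class `"bws_study"`: list with `design`, `items`,
#'   `responses` (long data frame: `respondent_id`, `phase`, `block`,
#'   `best`, `worst`, with `NA` picks for deleted blocks), `strata_counts`,
#'   `n_submitted`, `profiles` (provenance) and `master_seed`.
#' @seealso [study_emulation()], [filter_complete()]
#' @export
simulate_study <- function(x, strata_counts, profiles = NULL,
                           n_submitted_extra = 0L, missing_blocks = 1:3,
                           master_seed = 1L, items = NULL) {
  qd <- .as_design_items(x, items)
  phases <- names(strata_counts)
  if (is.null(phases) || any(!nzchar(phases)))
    stop("strata_counts must be a named vector of phase labels")
  if (any(strata_counts < 1L)) stop("strata counts must be positive")
  if (is.null(profiles))
    profiles <- stats::setNames(lapply(phases, default_profile), phases)
  missing_profiles <- setdiff(phases, names(profiles))
  if (length(missing_profiles))
    stop("no profile supplied for phase(s): ",
         paste(missing_profiles, collapse = ", "))
  for (p in phases) {
    gap <- setdiff(qd$items, names(profiles[[p]]$utility))
    if (length(gap))
      stop("profile for phase '", p, "' does not cover item(s): ",
           paste(gap, collapse = ", "))
  }

  # proportional allocation of the incomplete extras across strata
  # (largest-remainder rounding so the total is exact)
  extra <- .apportion(n_submitted_extra, strata_counts)

  master_seed <- as.integer(master_seed)
  child_seed <- function(counter)
    as.integer((as.numeric(master_seed) + 99991 * counter) %% 2147483647)

  rows <- list(); counter <- 0L; rid <- 0L
  for (p in phases) {
    for (i in seq_len(strata_counts[[p]] + extra[[p]])) {
      counter <- counter + 1L; rid <- rid + 1L
      id <- sprintf("R%03d", rid)
      resp <- simulate_response(x, profiles[[p]], child_seed(counter),
                                respondent_id = id, items = qd$items)
      if (i > strata_counts[[p]]) {          # incomplete extra
        old <- .save_rng()
        set.seed(child_seed(counter) %/% 2L + 1L)
        ndrop <- if (length(missing_blocks) == 1L) missing_blocks else
          sample(missing_blocks, 1L)
        drop <- sample.int(qd$design$b, ndrop)
        .restore_rng(old)
        resp$best[drop] <- NA_character_
        resp$worst[drop] <- NA_character_
      }
      rows[[length(rows) + 1L]] <- resp
    }
  }
  responses <- do.call(rbind, rows)
  structure(list(design = qd$design, items = qd$items,
                 responses = responses,
                 strata_counts = strata_counts,
                 n_submitted = sum(strata_counts) + sum(extra),
                 profiles = lapply(profiles[phases], function(pr)
                   list(phase = pr$phase,
                        heterogeneity_sd = pr$heterogeneity_sd)),
                 master_seed = master_seed),
            class = "bws_study")
}

# integer apportionment by largest remainder (deterministic; ties go to
# the earlier stratum)
.apportion <- function(total, weights) {
  total <- as.integer(total)
  if (total == 0L) return(stats::setNames(integer(length(weights)),
                                          names(weights)))
  q <- total * weights / sum(weights)
  base <- floor(q)
  left <- total - sum(base)
  if (left > 0L) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Study-emulation preset
#'
#' Builds the packaged synthetic dataset emulating the structure of the
#' TJA quality-of-care study: the 13-item catalog laid out in the
#' (v=13, b=13, k=4, r=4, lambda=1) design, 153 complete respondents in
#' three phase strata (36 preoperative, 55 short-term postoperative, 62
#' long-term postoperative), each stratum driven by its phase profile,
#' plus 15 additional respondents with incomplete questionnaires, for 168
#' submitted in total.
#'
#' @param master_seed integer master seed.
#' @param heterogeneity_sd respondent-level perturbation sd passed to the
#'   phase profiles.
#' @return A `"bws_study"` object (see [simulate_study()]).
#' @examples
#' st <- study_emulation(master_seed = 7)
#' st$n_submitted                  # 168
#' nrow(filter_complete(st)$included$responses) / st$design$b  # 153
#' @export
study_emulation <- function(master_seed = 1L, heterogeneity_sd = 0.3) {
  design <- bibd(13L, 4L)
  qn <- questionnaire(design, items = tja_outcomes()$item_id,
                      layout_seed = master_seed)
  strata <- c(pre_op = 36L, short_post = 55L, long_post = 62L)
  profiles <- stats::setNames(
    lapply(names(strata), default_profile,
           heterogeneity_sd = heterogeneity_sd),
    names(strata))
  simulate_study(qn, strata, profiles = profiles, n_submitted_extra = 15L,
                 master_seed = master_seed)
}

#' Split a study into complete and incomplete respondents
#'
#' Applies the enrollment completeness rule: a respondent is included
#' only if every block has both a best and a worst pick. The partition is
#' exhaustive and disjoint: every submitted respondent lands in exactly
#' one side.
#'
#' @param study a `"bws_study"` object.
#' @return A list with `included` (a `"bws_study"` restricted to the
#'   complete respondents, with updated `strata_counts`) and `excluded`
#'   (long data frame of the incomplete respondents' rows).
#' @export
filter_complete <- function(study) {
  stopifnot(inherits(study, "bws_study"))
  resp <- study$responses
  bad <- is.na(resp$best) | is.na(resp$worst)
  incomplete_ids <- unique(resp$respondent_id[bad])
  keep <- !(resp$respondent_id %in% incomplete_ids)
  included <- study
  included$responses <- resp[keep, , drop = FALSE]
  rownames(included$responses) <- NULL
  kept_ids <- unique(included$responses$respondent_id)
  ph <- resp$phase[match(kept_ids, resp$respondent_id)]
  included$strata_counts <- stats::setNames(
    as.integer(table(factor(ph, levels = names(study$strata_counts)))),
    names(study$strata_counts))
  list(included = included,
       excluded = resp[!keep, , drop = FALSE])
}

#' @export
print.bws_study <- function(x, ...) {
  n <- length(unique(x$responses$respondent_id))
  cat(sprintf("BWS study: %d respondents over %d blocks of %d items\n",
              n, x$design$b, x$design$k))
  cat("  strata:", paste(sprintf("%s=%d", names(x$strata_counts),
                                 x$strata_counts), collapse = ", "), "\n")
  ninc <- sum(is.na(x$responses$best) | is.na(x$responses$worst))
  if (ninc > 0L) cat("  block picks missing:", ninc, "\n")
  invisible(x)
}
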