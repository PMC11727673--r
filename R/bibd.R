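#' Construct a balanced incomplete block design
#'
#' Finds a balanced incomplete block design (BIBD) arranging `v` items
#' into blocks of size `k` such that every item appears in the same
#' number `r` of blocks and every unordered pair of items co-occurs in
#' the same number `lambda` of blocks. The admissibility identities
#' `v r = b k` and `lambda (v - 1) = r (k - 1)` are enforced. The search
#' proceeds over increasing `lambda` (hence increasing block count `b`)
#' and returns the first design found, so the returned design has the
#' minimal `b` the search can reach.
#'
#' Construction strategy: for symmetric parameter sets (`b == v`) a cyclic
#' difference-set search is tried first, which instantly yields classical
#' designs such as the (7,7,3,3,1) Fano plane and the (13,13,4,4,1) design
#' used for a 13-item questionnaire with blocks of 4. Otherwise (or if no
#' difference set exists) a deterministic lexicographic backtracking
#' search with pair-count and replication pruning is used, bounded by
#' `max_nodes`. The generator involves no randomness: the same `(v, k)`
#' always yields the same design.
#'
#' @param v number of items (treatments), `v >= 2`.
#' @param k block size, `2 <= k <= v`.
#' @param max_lambda largest pairwise co-occurrence count to try.
#' @param max_nodes node budget for the backtracking search; exceeding it
#'   for every admissible `lambda` is an error, never a silent fallback.
#' @return An object of class `"bibd"`: a list with elements `v`, `b`,
#'   `k`, `r`, `lambda` and `blocks`, a `b x k` integer matrix whose rows
#'   are the blocks (item indices `1..v`, each row sorted increasing).
#' @examples
#' d <- bibd(7, 3)   # Fano plane: b = 7, r = 3, lambda = 1
#' d$b
#' validate_bibd(d)$pass
#' @seealso [validate_bibd()], [questionnaire()]
#' @export
bibd <- function(v, k, max_lambda = 6L, max_nodes = 2e6) {
  if (!is.numeric(v) || !is.numeric(k) || length(v) != 1L || length(k) != 1L ||
      v != round(v) || k != round(k))
    stop("v and k must be single integers")
  v <- as.integer(v); k <- as.integer(k)
  if (k < 2L) stop("block size k must be at least 2")
  if (k > v) stop("block size k cannot exceed the number of items v (k=",
                  k, ", v=", v, ")")

  for (lambda in seq_len(max_lambda)) {
    r_num <- lambda * (v - 1L)
    if (r_num %% (k - 1L) != 0L) next
    r <- r_num %/% (k - 1L)
    if ((v * r) %% k != 0L) next
    b <- (v * r) %/% k

    if (b == v) {
      blocks <- .bibd_difference_set(v, k, lambda)
      if (!is.null(blocks))
        return(.new_bibd(v, b, k, r, lambda, blocks))
    }
    blocks <- .bibd_backtrack(v, b, k, r, lambda, max_nodes)
    if (!is.null(blocks))
      return(.new_bibd(v, b, k, r, lambda, blocks))
  }
  stop("no balanced incomplete block design found for v=", v, ", k=", k,
       " with lambda <= ", max_lambda, " within a budget of ", max_nodes,
       " search nodes")
}

.new_bibd <- function(v, b, k, r, lambda, blocks) {
  blocks <- t(apply(blocks, 1L, sort))
  if (k == 1L) blocks <- matrix(blocks, ncol = 1L)
  structure(list(v = v, b = b, k = k, r = r, lambda = lambda,
                 blocks = blocks),
            class = "bibd")
}

# Cyclic construction: find a k-subset D of Z_v whose pairwise differences
# cover every nonzero residue exactly lambda times, then develop D + t
# (t = 0..v-1). Only attempted when b == v. Deterministic: subsets are
# visited in the lexicographic order of utils::combn.
.bibd_difference_set <- function(v, k, lambda) {
  if (choose(v - 1L, k - 1L) > 5e5) return(NULL)
  cands <- utils::combn(v - 1L, k - 1L)
  for (j in seq_len(ncol(cands))) {
    D <- c(0L, cands[, j])
    diffs <- outer(D, D, "-")
    diffs <- diffs[row(diffs) != col(diffs)] %% v
    tab <- tabulate(diffs, nbins = v - 1L)
    if (all(tab == lambda)) {
      blocks <- matrix(0L, nrow = v, ncol = k)
      for (t in 0L:(v - 1L)) blocks[t + 1L, ] <- ((D + t) %% v) + 1L
      return(blocks)
    }
  }
  NULL
}

# Deterministic depth-first search over blocks in nondecreasing
# lexicographic order; prunes on replication counts (<= r) and pair
# co-occurrence counts (<= lambda). Counts visited nodes against the
# budget; returns NULL when exhausted or over budget.
.bibd_backtrack <- function(v, b, k, r, lambda, max_nodes) {
  all_blocks <- utils::combn(v, k)      # columns in lexicographic order
  nb <- ncol(all_blocks)
  pair_idx <- utils::combn(k, 2L)

  rep_count <- integer(v)
  pair_count <- matrix(0L, v, v)
  chosen <- integer(b)
  nodes <- 0L

  block_ok <- function(col) {
    blk <- all_blocks[, col]
    if (any(rep_count[blk] >= r)) return(FALSE)
    for (p in seq_len(ncol(pair_idx))) {
      i <- blk[pair_idx[1L, p]]; j <- blk[pair_idx[2L, p]]
      if (pair_count[i, j] >= lambda) return(FALSE)
    }
    TRUE
  }
  place <- function(col, sign) {
    blk <- all_blocks[, col]
    rep_count[blk] <<- rep_count[blk] + sign
    for (p in seq_len(ncol(pair_idx))) {
      i <- blk[pair_idx[1L, p]]; j <- blk[pair_idx[2L, p]]
      pair_count[i, j] <<- pair_count[i, j] + sign
      pair_count[j, i] <<- pair_count[j, i] + sign
    }
  }

  search <- function(depth, from) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) return(NA)       # budget exhausted
    if (depth > b) {
      if (all(rep_count == r)) return(TRUE) else return(FALSE)
    }
    # not enough remaining slots to finish every item
    remaining <- (b - depth + 1L) * k
    if (sum(r - rep_count) != remaining) {
      # counts can still work out only if the deficit equals the slots
      if (sum(r - rep_count) > remaining) return(FALSE)
    }
    for (col in from:nb) {
      if (!block_ok(col)) next
      place(col, 1L)
      chosen[depth] <<- col
      res <- search(depth + 1L, col)   # nondecreasing order, repeats allowed
      if (isTRUE(res) || is.na(res)) return(res)
      place(col, -1L)
    }
    FALSE
  }

  res <- search(1L, 1L)
  if (!isTRUE(res)) return(NULL)
  t(all_blocks[, chosen, drop = FALSE])
}

#' Validate a block design against the BIBD invariants
#'
#' Recounts, directly from the blocks, the per-item replication numbers
#' and the full pairwise co-occurrence matrix, and checks every BIBD
#' invariant: constant block size with distinct items, equal replication
#' `r` for all items, equal co-occurrence `lambda` for all pairs, and the
#' admissibility identities `v r = b k` and `lambda (v-1) = r (k-1)`.
#' Invalid designs produce a failing report (never an error), listing the
#' offending items and pairs.
#'
#' @param design an object of class `"bibd"`, or any list with elements
#'   `v`, `k` and a `blocks` matrix (claimed `r`/`lambda` are checked if
#'   present, otherwise inferred).
#' @return An object of class `"bibd_report"`: list with `pass` (logical),
#'   `replication` (per-item counts), `cooccurrence` (v x v matrix),
#'   `checks` (data frame of named invariant checks) and `violations`
#'   (character vector of human-readable failures).
#' @export
validate_bibd <- function(design) {
  blocks <- design$blocks
  if (is.null(blocks) || nrow(blocks) == 0L) stop("design has no blocks")
  v <- design$v
  k <- design$k
  b <- nrow(blocks)

  replication <- integer(v)
  cooc <- matrix(0L, v, v)
  distinct_ok <- TRUE
  for (i in seq_len(b)) {
    blk <- blocks[i, ]
    if (anyDuplicated(blk)) distinct_ok <- FALSE
    replication[blk] <- replication[blk] + 1L
    for (a in seq_len(length(blk) - 1L))
      for (bb in (a + 1L):length(blk)) {
        cooc[blk[a], blk[bb]] <- cooc[blk[a], blk[bb]] + 1L
        cooc[blk[bb], blk[a]] <- cooc[blk[bb], blk[a]] + 1L
      }
  }

  r_claim <- if (!is.null(design$r)) design$r else replication[1L]
  lam_claim <- if (!is.null(design$lambda)) design$lambda else
    cooc[1L, min(2L, v)]

  off <- cooc[row(cooc) != col(cooc)]
  violations <- character()
  if (!distinct_ok)
    violations <- c(violations, "some block contains a repeated item")
  if (ncol(blocks) != k)
    violations <- c(violations, sprintf("blocks have %d columns, k = %d",
                                        ncol(blocks), k))
  bad_rep <- which(replication != r_claim)
  if (length(bad_rep)) {
    over <- bad_rep[replication[bad_rep] > r_claim]
    under <- bad_rep[replication[bad_rep] < r_claim]
    if (length(over))
      violations <- c(violations, sprintf(
        "over-replicated item(s): %s (count %s, expected %d)",
        paste(over, collapse = ","),
        paste(replication[over], collapse = ","), r_claim))
    if (length(under))
      violations <- c(violations, sprintf(
        "under-replicated item(s): %s (count %s, expected %d)",
        paste(under, collapse = ","),
        paste(replication[under], collapse = ","), r_claim))
  }
  if (v > 1L && any(off != lam_claim)) {
    bad <- which(cooc != lam_claim & row(cooc) != col(cooc), arr.ind = TRUE)
    bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE]
    violations <- c(violations, sprintf(
      "pair(s) with co-occurrence != %d: %s", lam_claim,
      paste(apply(bad, 1L, function(x)
        sprintf("{%d,%d}=%d", x[1L], x[2L], cooc[x[1L], x[2L]])),
        collapse = " ")))
  }
  id1 <- v * r_claim == b * k
  id2 <- lam_claim * (v - 1L) == r_claim * (k - 1L)
  if (!id1) violations <- c(violations, "identity v*r = b*k fails")
  if (!id2) violations <- c(violations, "identity lambda*(v-1) = r*(k-1) fails")

  checks <- data.frame(
    invariant = c("blocks_distinct_size_k", "equal_replication",
                  "equal_cooccurrence", "vr_eq_bk", "lambda_identity"),
    pass = c(distinct_ok && ncol(blocks) == k,
             length(bad_rep) == 0L,
             v == 1L || all(off == lam_claim),
             id1, id2),
    stringsAsFactors = FALSE)

  structure(list(pass = all(checks$pass), replication = replication,
                 cooccurrence = cooc, checks = checks,
                 violations = violations),
            class = "bibd_report")
}

#' @export
print.bibd <- function(x, ...) {
  cat(sprintf("Balanced incomplete block design: v=%d b=%d k=%d r=%d lambda=%d\n",
              x$v, x$b, x$k, x$r, x$lambda))
  invisible(x)
}

#' @export
print.bibd_report <- function(x, ...) {
  cat("BIBD validation:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$checks, row.names = FALSE)
  if (length(x$violations)) cat(paste0("  - ", x$violations, "\n"), sep = "")
  invisible(x)
}

#' Lay out a questionnaire from a block design
#'
#' Wraps a design with a presentation layout: a seeded random order of the
#' blocks and a random order of the items within each block. The layout
#' affects only how the questionnaire is displayed; the design (and hence
#' every item's availability) is unchanged. Reproducible given
#' `layout_seed`.
#'
#' @param design a `"bibd"` object.
#' @param items optional character vector of `v` item ids (e.g.
#'   `tja_outcomes()$item_id`); defaults to `item01 ...`-style tokens.
#' @param layout_seed integer seed controlling the shuffles.
#' @return An object of class `"questionnaire"`: list with `design`,
#'   `items`, `block_order` (permutation of `1..b`), `within_block_orders`
#'   (list of permutations of `1..k`) and `layout_seed`.
#' @export
questionnaire <- function(design, items = NULL, layout_seed = 1L) {
  stopifnot(inherits(design, "bibd"))
  if (is.null(items))
    items <- sprintf("item%02d", seq_len(design$v))
  items <- as.character(items)
  if (length(items) != design$v)
    stop("need exactly v=", design$v, " item ids, got ", length(items))
  if (anyDuplicated(items)) stop("item ids must be unique")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(layout_seed))
  block_order <- sample.int(design$b)
  within <- lapply(seq_len(design$b), function(i) sample.int(design$k))
  structure(list(design = design, items = items, block_order = block_order,
                 within_block_orders = within,
                 layout_seed = as.integer(layout_seed)),
            class = "questionnaire")
}

#' @export
print.questionnaire <- function(x, ...) {
  cat(sprintf("BWS questionnaire: %d blocks of %d items (layout seed %d)\n",
              x$design$b, x$design$k, x$layout_seed))
  for (pos in seq_along(x$block_order)) {
    bi <- x$block_order[pos]
    blk <- x$design$blocks[bi, ][x$within_block_orders[[bi]]]
    cat(sprintf("  Q%02d: %s\n", pos, paste(x$items[blk], collapse = ", ")))
  }
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
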