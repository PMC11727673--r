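# Shared fixtures and independent oracles for the test suite.

# Independent recount of replication and pairwise co-occurrence, written
# directly from the definition (never calls validate_bibd internals).
brute_design_counts <- function(blocks, v) {
  rep_count <- integer(v)
  cooc <- matrix(0L, v, v)
  for (i in seq_len(nrow(blocks))) {
    blk <- blocks[i, ]
    for (a in blk) rep_count[a] <- rep_count[a] + 1L
    for (a in blk) for (b in blk) if (a < b) {
      cooc[a, b] <- cooc[a, b] + 1L
      cooc[b, a] <- cooc[b, a] + 1L
    }
  }
  list(replication = rep_count, cooccurrence = cooc)
}

# Exhaustive enumeration of the MaxDiff ordered-pair distribution for
# one block: P(best=i, worst=j) = exp(u_i - u_j) / sum over ordered pairs.
enum_pair_probs <- function(u) {
  k <- length(u)
  out <- expand.grid(best = seq_len(k), worst = seq_len(k))
  out <- out[out$best != out$worst, ]
  w <- exp(u[out$best] - u[out$worst])
  out$prob <- w / sum(w)
  out
}

# Brute-force MaxDiff log-likelihood: loops row by row over the long
# responses, recomputing each block's denominator by full enumeration.
brute_loglik <- function(beta, resp, blocks, items) {
  ll <- 0
  for (i in seq_len(nrow(resp))) {
    blk <- blocks[resp$block[i], ]
    u <- beta[blk]
    pp <- enum_pair_probs(u)
    bi <- match(match(resp$best[i], items), blk)
    wi <- match(match(resp$worst[i], items), blk)
    ll <- ll + log(pp$prob[pp$best == bi & pp$worst == wi])
  }
  ll
}

# Brute-force best/worst tally: row-by-row recount over the long data.
brute_counts <- function(resp, items) {
  nb <- stats::setNames(integer(length(items)), items)
  nw <- nb
  for (i in seq_len(nrow(resp))) {
    nb[resp$best[i]] <- nb[resp$best[i]] + 1L
    nw[resp$worst[i]] <- nw[resp$worst[i]] + 1L
  }
  list(n_best = nb, n_worst = nw)
}

# Scripted (non-random given rng) complete response set on a design:
# each respondent picks uniformly among the legal ordered pairs.
scripted_responses <- function(design, items, n_resp, seed) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_resp)) {
    for (b in seq_len(design$b)) {
      blk <- design$blocks[b, ]
      pick <- sample(blk, 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        respondent_id = sprintf("S%03d", r), phase = "overall",
        block = b, best = items[pick[1L]], worst = items[pick[2L]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

design13 <- function() bibd(13, 4)
items13 <- function() tja_outcomes()$item_id
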