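#' Log-likelihood of best-worst responses under the MaxDiff model
#'
#' Evaluates the conditional-logit (MaxDiff) log-likelihood of a set of
#' complete best/worst responses at a given utility vector: the sum over
#' respondents and blocks of
#' `log[ exp(u_best - u_worst) / sum_{i != j in block} exp(u_i - u_j) ]`.
#' Because only utility differences enter, the value is invariant to
#' adding a constant to every utility; utilities are conventionally
#' centered to sum zero. The `"sequential"` alternative scores the best
#' pick as a logit choice over the block followed by the worst pick as a
#' logit choice (with negated utilities) over the remaining items.
#'
#' @param beta numeric utility vector, either named by item id or in the
#'   order of `items`.
#' @param x a `"bws_study"` or long response data frame (complete
#'   responses only).
#' @param design,items as in [count_scores()].
#' @param method `"maxdiff"` (joint ordered-pair rule, default) or
#'   `"sequential"` (best then worst).
#' @return The log-likelihood, a finite scalar for finite `beta`.
#' @examples
#' d <- bibd(4, 4)
#' one <- data.frame(respondent_id = "R001", block = 1,
#'                   best = "item01", worst = "item04")
#' maxdiff_loglik(rep(0, 4), one, design = d)  # log(1/12)
#' @export
maxdiff_loglik <- function(beta, x, design = NULL, items = NULL,
                           method = c("maxdiff", "sequential")) {
  method <- match.arg(method)
  d <- .as_response_data(x, design, items)
  if (any(is.na(d$responses$best) | is.na(d$responses$worst)))
    stop("incomplete responses present; apply filter_complete() first")
  .check_picks_in_blocks(d$responses, d$design, d$items)
  agg <- .aggregate_picks(d$responses, d$design, d$items)
  beta <- .match_beta(beta, d$items)
  .bws_loglik(beta, agg, method)
}

.match_beta <- function(beta, items) {
  if (!is.null(names(beta))) {
    miss <- setdiff(items, names(beta))
    if (length(miss)) stop("beta lacks item(s): ",
                           paste(miss, collapse = ", "))
    beta <- beta[items]
  }
  if (length(beta) != length(items))
    stop("beta must have one entry per item (", length(items), ")")
  as.numeric(beta)
}

# Collapse long responses to counts per (block, best item, worst item)
# cell; the likelihood then costs O(b * k^2) per evaluation regardless of
# the number of respondents.
.aggregate_picks <- function(resp, design, items) {
  bi <- match(resp$best, items)
  wi <- match(resp$worst, items)
  key <- (resp$block - 1L) * length(items)^2 +
    (bi - 1L) * length(items) + (wi - 1L)
  tab <- table(key)
  keyv <- as.numeric(names(tab))
  cells <- data.frame(
    block = keyv %/% length(items)^2 + 1L,
    best = (keyv %% length(items)^2) %/% length(items) + 1L,
    worst = keyv %% length(items) + 1L,
    n = as.integer(tab))
  list(cells = cells,
       by_block = split(cells, cells$block),
       blocks = design$blocks, v = length(items),
       n_obs = nrow(resp))
}

.bws_loglik <- function(beta, agg, method = "maxdiff") {
  ll <- 0
  for (cc in agg$by_block) {
    blk <- agg$blocks[cc$block[1L], ]
    u <- beta[blk]
    if (method == "maxdiff") {
      w <- exp(outer(u, u, "-")); diag(w) <- 0
      ll <- ll + sum(cc$n * (beta[cc$best] - beta[cc$worst])) -
        sum(cc$n) * log(sum(w))
    } else {
      lse_best <- log(sum(exp(u)))
      for (i in seq_len(nrow(cc))) {
        rest <- setdiff(blk, cc$best[i])
        ll <- ll + cc$n[i] * (beta[cc$best[i]] - lse_best -
                                beta[cc$worst[i]] -
                                log(sum(exp(-beta[rest]))))
      }
    }
  }
  ll
}

# Analytic gradient of the log-likelihood with respect to the full
# utility vector.
.bws_grad <- function(beta, agg, method = "maxdiff") {
  g <- numeric(agg$v)
  for (cc in agg$by_block) {
    blk <- agg$blocks[cc$block[1L], ]
    u <- beta[blk]
    nb <- sum(cc$n)
    if (method == "maxdiff") {
      w <- exp(outer(u, u, "-")); diag(w) <- 0
      P <- w / sum(w)
      g[blk] <- g[blk] - nb * (rowSums(P) - colSums(P))
    } else {
      # best pick: logit over the block
      g[blk] <- g[blk] - nb * exp(u) / sum(exp(u))
      # worst pick: logit with negated utilities over the block minus
      # the chosen best (denominator depends on which item was best)
      for (bitem in unique(cc$best)) {
        rows <- cc$best == bitem
        rest <- setdiff(blk, bitem)
        q <- exp(-beta[rest]) / sum(exp(-beta[rest]))
        g[rest] <- g[rest] + sum(cc$n[rows]) * q
      }
    }
    g <- g + tabulate(rep(cc$best, cc$n), nbins = agg$v)
    g <- g - tabulate(rep(cc$worst, cc$n), nbins = agg$v)
  }
  g
}

#' Fit the conditional-logit (MaxDiff) model to best-worst responses
#'
#' Maximum-likelihood estimation of per-item utilities from complete
#' best/worst responses under the MaxDiff pair rule (or the sequential
#' best-then-worst alternative). Identification uses effects coding: the
#' utilities are constrained to sum to zero, so estimates spread around
#' an implicit centre with both positive and negative values.
#' Optimisation is quasi-Newton (BFGS) with analytic gradient from a zero
#' start — deterministic, no random restarts. Standard errors come from
#' the observed information (inverse Hessian of the negative
#' log-likelihood in the free parameters) mapped through the sum-to-zero
#' constraint; 95% confidence intervals are `beta +/- 1.96 * se`.
#'
#' @param x a `"bws_study"` (complete; see [filter_complete()]) or a long
#'   response data frame.
#' @param design,items as in [count_scores()].
#' @param method `"maxdiff"` (default) or `"sequential"`.
#' @param tol convergence tolerance: the fit is flagged converged only if
#'   the gradient norm at the optimum is at most `tol`.
#' @param max_iter maximum BFGS iterations.
#' @param subgroup label recorded in the results (e.g. a phase of care).
#' @return An object of class `"maxdiff_fit"` with components
#'   `coefficients` (data frame: `item_id`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `rank`, `subgroup`, `n_respondents`), `vcov`, `loglik`,
#'   `converged`, `grad_norm`, `method`, `items`, `design` and the
#'   aggregated pick counts. Supports `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `confint`, `predict`, `plot`, `residuals` and
#'   `simulate`.
#' @examples
#' st <- filter_complete(study_emulation(master_seed = 1))$included
#' fit <- fit_maxdiff(st)
#' head(coef(summary(fit)), 4)
#' @seealso [fit_by_subgroup()], [compare_subgroups()], [maxdiff_loglik()]
#' @export
fit_maxdiff <- function(x, design = NULL, items = NULL,
                        method = c("maxdiff", "sequential"),
                        tol = 1e-6, max_iter = 500L, subgroup = "overall") {
  method <- match.arg(method)
  d <- .as_response_data(x, design, items)
  resp <- d$responses
  if (nrow(resp) == 0L) stop("no responses to fit")
  if (any(is.na(resp$best) | is.na(resp$worst)))
    stop("incomplete responses present; apply filter_complete() first")
  .check_picks_in_blocks(resp, d$design, d$items)
  agg <- .aggregate_picks(resp, d$design, d$items)
  v <- agg$v
  n_resp <- length(unique(resp$respondent_id))

  # separation: an item picked best at every appearance (or worst at
  # every appearance) has no finite maximiser
  nb <- tabulate(agg$cells$best[rep(seq_len(nrow(agg$cells)),
                                    agg$cells$n)], nbins = v)
  nw <- tabulate(agg$cells$worst[rep(seq_len(nrow(agg$cells)),
                                     agg$cells$n)], nbins = v)
  avail <- d$design$r * n_resp
  drift <- which(nb == avail | nw == avail)
  if (length(drift))
    warning("item(s) always picked best or always picked worst: ",
            paste(d$items[drift], collapse = ", "),
            "; their utility estimates drift to infinity")

  expand <- function(theta) c(theta, -sum(theta))
  negll <- function(theta) -.bws_loglik(expand(theta), agg, method)
  neggr <- function(theta) {
    g <- -.bws_grad(expand(theta), agg, method)
    g[seq_len(v - 1L)] - g[v]
  }

  opt <- stats::optim(rep(0, v - 1L), negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  # Newton polish: the log-likelihood is concave, so a few damped Newton
  # steps drive the gradient to numerical zero from the BFGS solution
  for (it in seq_len(25L)) {
    g <- neggr(opt$par)
    if (sqrt(sum(g^2)) <= tol / 10) break
    H <- stats::optimHess(opt$par, negll, neggr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- opt$par - step
    if (negll(cand) <= opt$value + 1e-9) {
      opt$par <- cand; opt$value <- negll(cand)
    } else break
  }
  beta <- expand(opt$par)
  gnorm <- sqrt(sum(neggr(opt$par)^2))
  converged <- (opt$convergence == 0L) && gnorm <= tol &&
    length(drift) == 0L
  if (!converged)
    warning("fit did not converge (gradient norm ", signif(gnorm, 3),
            ", optim code ", opt$convergence, ")")

  H <- stats::optimHess(opt$par, negll, neggr)
  Vth <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, v - 1L, v - 1L))
  L <- rbind(diag(v - 1L), rep(-1, v - 1L))
  Vb <- L %*% Vth %*% t(L)
  dimnames(Vb) <- list(d$items, d$items)
  se <- sqrt(pmax(diag(Vb), 0))

  coefs <- data.frame(item_id = d$items, beta = beta, se = se,
                      ci_low = beta - 1.96 * se,
                      ci_high = beta + 1.96 * se,
                      stringsAsFactors = FALSE)
  coefs <- coefs[order(-coefs$beta, coefs$item_id), , drop = FALSE]
  coefs$rank <- seq_len(v)
  coefs$subgroup <- subgroup
  coefs$n_respondents <- n_resp
  rownames(coefs) <- NULL

  structure(list(coefficients = coefs, vcov = Vb,
                 loglik = -opt$value, converged = converged,
                 grad_norm = gnorm, method = method, subgroup = subgroup,
                 n_respondents = n_resp, n_obs = agg$n_obs,
                 items = d$items, design = d$design, agg = agg),
            class = "maxdiff_fit")
}

.num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

#' Fit the MaxDiff model separately within each subgroup
#'
#' Splits a study by its phase label and fits the conditional-logit
#' model independently in every stratum, as in a subgroup re-analysis by
#' recovery timepoint.
#'
#' @param study a complete `"bws_study"`.
#' @param ... passed to [fit_maxdiff()].
#' @return A named list of `"maxdiff_fit"` objects (one per phase), of
#'   class `"maxdiff_fit_list"`.
#' @export
fit_by_subgroup <- function(study, ...) {
  stopifnot(inherits(study, "bws_study"))
  phases <- names(study$strata_counts)
  if (is.null(phases)) phases <- sort(unique(study$responses$phase))
  fits <- list()
  for (p in phases) {
    sub <- study$responses[study$responses$phase == p, , drop = FALSE]
    if (nrow(sub) == 0L) stop("subgroup '", p, "' is empty")
    fits[[p]] <- fit_maxdiff(sub, design = study$design,
                             items = study$items, subgroup = p, ...)
  }
  structure(fits, class = "maxdiff_fit_list")
}

#' Compare subgroup fits: top items and utility trajectories
#'
#' Builds a comparison of two or more subgroup fits: the top-`m` ranked
#' items per subgroup (with their utilities) and, per item, the utility
#' trajectory across subgroups.
#'
#' @param results a `"maxdiff_fit_list"` or named list of
#'   `"maxdiff_fit"` objects over the same item catalog.
#' @param top number of top-ranked items to tabulate per subgroup
#'   (default 4).
#' @return An object of class `"bws_comparison"`: list with `top` (data
#'   frame: subgroup, rank, item_id, beta) and `trajectory` (data frame:
#'   one row per item, one utility column per subgroup).
#' @export
compare_subgroups <- function(results, top = 4L) {
  if (inherits(results, "maxdiff_fit"))
    stop("need at least 2 subgroup fits")
  results <- unclass(results)
  if (length(results) < 2L) stop("need at least 2 subgroup fits")
  items <- results[[1L]]$items
  for (f in results)
    if (!identical(sort(f$items), sort(items)))
      stop("subgroup fits use different item catalogs")
  top <- min(as.integer(top), length(items))

  top_df <- do.call(rbind, lapply(names(results), function(p) {
    cf <- results[[p]]$coefficients
    data.frame(subgroup = p, rank = cf$rank[seq_len(top)],
               item_id = cf$item_id[seq_len(top)],
               beta = cf$beta[seq_len(top)], stringsAsFactors = FALSE)
  }))
  traj <- data.frame(item_id = sort(items), stringsAsFactors = FALSE)
  for (p in names(results)) {
    cf <- results[[p]]$coefficients
    traj[[p]] <- cf$beta[match(traj$item_id, cf$item_id)]
  }
  structure(list(top = top_df, trajectory = traj),
            class = "bws_comparison")
}

# ---- methods ---------------------------------------------------------

#' @export
print.maxdiff_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MaxDiff conditional logit fit [%s], %d respondents, logLik %.2f%s\n",
              x$subgroup, x$n_respondents, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print.data.frame(x$coefficients[, c("item_id", "beta", "se", "ci_low",
                                      "ci_high", "rank")],
                   row.names = FALSE, digits = digits)
  invisible(x)
}

#' @export
summary.maxdiff_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.maxdiff_fit")
}

#' @export
print.summary.maxdiff_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("method: %s; observations: %d; gradient norm: %.2e; sum(beta) = %.2e\n",
              f$method, f$n_obs, f$grad_norm,
              sum(f$coefficients$beta)))
  invisible(x)
}

#' @export
coef.maxdiff_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$item_id)
}

#' @export
coef.summary.maxdiff_fit <- function(object, ...) object$fit$coefficients

#' @export
vcov.maxdiff_fit <- function(object, ...) object$vcov

#' @export
logLik.maxdiff_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$items) - 1L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
confint.maxdiff_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf$beta - z * cf$se, cf$beta + z * cf$se)
  rownames(out) <- cf$item_id
  colnames(out) <- paste0(format(100 * c((1 - level) / 2,
                                         1 - (1 - level) / 2)), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Fitted ordered-pair probabilities per block
#'
#' @param object a `"maxdiff_fit"`.
#' @param ... unused.
#' @return Data frame with columns `block`, `best`, `worst`, `prob`: the
#'   fitted probability of each ordered (best, worst) pair within each
#'   block under the fitted utilities.
#' @export
predict.maxdiff_fit <- function(object, ...) {
  beta <- stats::setNames(numeric(length(object$items)), object$items)
  beta[object$coefficients$item_id] <- object$coefficients$beta
  out <- list()
  for (bi in seq_len(object$design$b)) {
    blk <- object$design$blocks[bi, ]
    pp <- maxdiff_pair_probs(beta[object$items[blk]])
    out[[bi]] <- data.frame(block = bi,
                            best = object$items[blk[pp$best]],
                            worst = object$items[blk[pp$worst]],
                            prob = pp$prob, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pearson residuals of the aggregated pair counts
#'
#' @param object a `"maxdiff_fit"`.
#' @param ... unused.
#' @return Data frame with one row per (block, ordered pair): observed
#'   count, expected count under the fit, and the Pearson residual
#'   `(obs - exp) / sqrt(exp (1 - p))`.
#' @export
residuals.maxdiff_fit <- function(object, ...) {
  pred <- predict(object)
  cells <- object$agg$cells
  obs <- integer(nrow(pred))
  key_p <- paste(pred$block, pred$best, pred$worst)
  key_c <- paste(cells$block, object$items[cells$best],
                 object$items[cells$worst])
  obs[match(key_c, key_p)] <- cells$n
  nb <- tapply(obs, pred$block, sum)[as.character(pred$block)]
  expd <- as.numeric(nb) * pred$prob
  pred$observed <- obs
  pred$expected <- expd
  pred$pearson <- (obs - expd) / sqrt(pmax(expd * (1 - pred$prob), 1e-12))
  pred
}

#' Simulate studies from a fitted model
#'
#' Draws new synthetic respondents from the fitted utilities (parametric
#' bootstrap style), using the same design and respondent count as the
#' original fit.
#'
#' @param object a `"maxdiff_fit"`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n_respondents respondents per dataset (default as fitted).
#' @param heterogeneity_sd respondent-level perturbation sd (default 0:
#'   draws from the point estimates).
#' @param ... unused.
#' @return A list of `nsim` `"bws_study"` objects (a single study if
#'   `nsim = 1`).
#' @export
simulate.maxdiff_fit <- function(object, nsim = 1, seed = 1L,
                                 n_respondents = object$n_respondents,
                                 heterogeneity_sd = 0, ...) {
  beta <- coef(object)
  prof <- utility_profile(beta[sort(names(beta))],
                          phase = object$subgroup,
                          heterogeneity_sd = heterogeneity_sd)
  prof$utility <- prof$utility[object$items]
  out <- lapply(seq_len(nsim), function(s)
    simulate_study(object$design,
                   stats::setNames(n_respondents, object$subgroup),
                   profiles = stats::setNames(list(prof), object$subgroup),
                   master_seed = as.integer(seed) + s - 1L,
                   items = object$items))
  if (nsim == 1) out[[1L]] else out
}

#' Coefficient plot of a MaxDiff fit
#'
#' Dot plot of the estimated utilities with 95% confidence bars, sorted
#' from highest to lowest — the usual presentation of standardized BWS
#' scores.
#'
#' @param x a `"maxdiff_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.maxdiff_fit <- function(x, ...) {
  cf <- x$coefficients[order(x$coefficients$beta), , drop = FALSE]
  n <- nrow(cf)
  graphics::plot(cf$beta, seq_len(n), yaxt = "n",
                 xlim = range(cf$ci_low, cf$ci_high),
                 xlab = "standardized score (utility)", ylab = "",
                 pch = 19, ...)
  graphics::axis(2, at = seq_len(n), labels = cf$item_id, las = 1)
  graphics::segments(cf$ci_low, seq_len(n), cf$ci_high, seq_len(n))
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' @export
print.maxdiff_fit_list <- function(x, ...) {
  for (p in names(x)) { print(x[[p]]); cat("\n") }
  invisible(x)
}

#' @export
print.bws_comparison <- function(x, digits = 3, ...) {
  cat("Top items by subgroup:\n")
  print.data.frame(x$top, row.names = FALSE, digits = digits)
  cat("\nUtility trajectories:\n")
  print.data.frame(x$trajectory, row.names = FALSE, digits = digits)
  invisible(x)
}
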