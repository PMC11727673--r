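# a degenerate "design" of 3 identical complete blocks over 3 items,
# used for enumeration and grid-search oracles
design3x3 <- function() {
  structure(list(v = 3L, b = 3L, k = 3L, r = 3L, lambda = 3L,
                 blocks = matrix(rep(1:3, each = 3), nrow = 3,
                                 byrow = FALSE)),
            class = "bibd")
}

test_that("the uniform null likelihood of one pick in a block of 4 is log(1/12)", {
  d <- bibd(4, 4)
  one <- data.frame(respondent_id = "R001", block = 1L,
                    best = "item01", worst = "item04",
                    stringsAsFactors = FALSE)
  expect_equal(maxdiff_loglik(rep(0, 4), one, design = d), log(1 / 12),
               tolerance = 1e-12)
})

test_that("the likelihood is invariant to a constant utility shift", {
  d <- bibd(13, 4)
  resp <- scripted_responses(d, items13(), n_resp = 4, seed = 21)
  set.seed(22)
  beta <- rnorm(13, sd = 0.8)
  for (shift in c(-3, 0.5, 10)) {
    expect_equal(maxdiff_loglik(beta, resp, design = d, items = items13()),
                 maxdiff_loglik(beta + shift, resp, design = d,
                                items = items13()),
                 tolerance = 1e-10)
    expect_equal(maxdiff_loglik(beta, resp, design = d, items = items13(),
                                method = "sequential"),
                 maxdiff_loglik(beta + shift, resp, design = d,
                                items = items13(), method = "sequential"),
                 tolerance = 1e-10)
  }
})

test_that("the likelihood matches brute-force pair enumeration", {
  d <- design3x3()
  items <- c("a", "b", "c")
  resp <- data.frame(
    respondent_id = rep(c("R001", "R002"), each = 3),
    block = rep(1:3, 2),
    best = c("a", "b", "a", "c", "a", "b"),
    worst = c("b", "c", "c", "a", "b", "a"),
    stringsAsFactors = FALSE)
  beta <- c(0.5, -0.2, -0.3)
  expect_equal(maxdiff_loglik(beta, resp, design = d, items = items),
               brute_loglik(beta, resp, d$blocks, items),
               tolerance = 1e-10)
  # and on a larger randomized dataset over the 13-item design
  d13 <- bibd(13, 4)
  resp13 <- scripted_responses(d13, items13(), n_resp = 2, seed = 77)
  set.seed(78)
  b13 <- rnorm(13)
  expect_equal(maxdiff_loglik(b13, resp13, design = d13, items = items13()),
               brute_loglik(b13, resp13, d13$blocks, items13()),
               tolerance = 1e-10)
})

test_that("the fitted optimum matches a dense grid search on 3 items", {
  d <- design3x3()
  items <- c("a", "b", "c")
  set.seed(5)
  resp <- scripted_responses(d, items, n_resp = 6, seed = 55)
  f <- suppressWarnings(fit_maxdiff(resp, design = d, items = items))
  beta_hat <- coef(f)[items]

  ll <- function(t1, t2) maxdiff_loglik(c(t1, t2, -t1 - t2), resp,
                                        design = d, items = items)
  # coarse grid over the centered 2-parameter space, then refinement
  g <- seq(-2, 2, by = 0.05)
  vals <- outer(g, g, Vectorize(ll))
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  g1 <- seq(g[best[1]] - 0.06, g[best[1]] + 0.06, by = 0.001)
  g2 <- seq(g[best[2]] - 0.06, g[best[2]] + 0.06, by = 0.001)
  vals2 <- outer(g1, g2, Vectorize(ll))
  best2 <- which(vals2 == max(vals2), arr.ind = TRUE)[1, ]
  expect_lt(abs(unname(beta_hat[1]) - g1[best2[1]]), 1e-3)
  expect_lt(abs(unname(beta_hat[2]) - g2[best2[2]]), 1e-3)
})

test_that("perfectly symmetric data give zero utilities and tie-break ranks", {
  d <- bibd(3, 3)
  items <- c("x", "y", "z")
  pairs <- expand.grid(best = items, worst = items,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$best != pairs$worst, ]
  resp <- data.frame(respondent_id = sprintf("R%03d", seq_len(nrow(pairs))),
                     block = 1L, best = pairs$best, worst = pairs$worst,
                     stringsAsFactors = FALSE)
  f <- fit_maxdiff(resp, design = d, items = items)
  expect_equal(unname(coef(f)), rep(0, 3), tolerance = 1e-6)
  expect_equal(f$coefficients$item_id, c("x", "y", "z"))  # lexicographic
  expect_true(f$converged)
})

test_that("utilities sum to zero and CIs bracket the estimate on every fit", {
  st <- filter_complete(study_emulation(master_seed = 4))$included
  f <- fit_maxdiff(st)
  expect_lt(abs(sum(coef(f))), 1e-8)
  expect_true(all(f$coefficients$ci_low <= f$coefficients$beta &
                    f$coefficients$beta <= f$coefficients$ci_high))
  expect_true(all(sort(f$coefficients$rank) == 1:13))
  expect_true(f$converged)
  expect_equal(f$loglik,
               maxdiff_loglik(coef(f), st$responses, design = st$design,
                              items = st$items),
               tolerance = 1e-8)
  f2 <- suppressWarnings(fit_maxdiff(st, method = "sequential"))
  expect_lt(abs(sum(coef(f2))), 1e-8)
})

test_that("observed-information standard errors match finite differences", {
  d <- bibd(13, 4)
  resp <- scripted_responses(d, items13(), n_resp = 8, seed = 41)
  f <- suppressWarnings(fit_maxdiff(resp, design = d, items = items13()))
  theta_hat <- unname(coef(f)[f$items])[seq_len(12)]
  negll <- function(th) -maxdiff_loglik(c(th, -sum(th)), resp, design = d,
                                        items = items13())
  # central second differences of the negative log-likelihood
  h <- 1e-4
  H <- matrix(0, 12, 12)
  for (i in 1:12) for (j in i:12) {
    ei <- ej <- numeric(12); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (negll(theta_hat + ei + ej) - negll(theta_hat + ei - ej) -
         negll(theta_hat - ei + ej) + negll(theta_hat - ei - ej)) / (4 * h^2)
  }
  V <- solve(H)
  L <- rbind(diag(12), rep(-1, 12))
  se_fd <- sqrt(diag(L %*% V %*% t(L)))
  se_fit <- f$coefficients$se[match(f$items, f$coefficients$item_id)]
  expect_true(all(abs(se_fit / se_fd - 1) < 0.01))
})

test_that("complete separation is flagged, never silently fit", {
  d <- bibd(13, 4)
  items <- items13()
  rows <- list()
  for (b in seq_len(d$b)) {
    blk <- d$blocks[b, ]
    best <- if (1L %in% blk) 1L else blk[1L]
    worst <- setdiff(blk, best)[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      respondent_id = "R001", block = b, best = items[best],
      worst = items[worst], stringsAsFactors = FALSE)
  }
  expect_warning(
    expect_warning(f <- fit_maxdiff(do.call(rbind, rows), design = d,
                                    items = items),
                   "always picked best"),
    "did not converge")
  expect_false(f$converged)
})

test_that("confidence intervals shrink like one over root n", {
  d <- bibd(13, 4)
  prof <- default_profile("overall")
  hw <- sapply(c(50, 200, 800), function(n) {
    st <- simulate_study(d, c(overall = as.integer(n)),
                         profiles = list(overall = prof),
                         master_seed = 61, items = items13())
    f <- fit_maxdiff(st)
    mean(f$coefficients$ci_high - f$coefficients$ci_low) / 2
  })
  expect_equal(hw[1] / hw[2], 2, tolerance = 0.25)
  expect_equal(hw[2] / hw[3], 2, tolerance = 0.25)
})

test_that("estimates recover the generating utilities at large n", {
  d <- bibd(13, 4)
  prof <- default_profile("overall", heterogeneity_sd = 0)
  st <- simulate_study(d, c(overall = 5000L),
                       profiles = list(overall = prof),
                       master_seed = 71, items = items13())
  f <- fit_maxdiff(st)
  cf <- f$coefficients
  truth <- prof$utility[cf$item_id]
  expect_true(all(abs(cf$beta - truth) <= 3 * cf$se))
  expect_gte(cor(cf$beta, truth, method = "spearman"), 0.99)
})

test_that("subgroup fits split the strata and compare correctly", {
  st <- filter_complete(study_emulation(master_seed = 8))$included
  sf <- fit_by_subgroup(st)
  expect_named(sf, c("pre_op", "short_post", "long_post"))
  expect_equal(sapply(sf, function(f) f$n_respondents),
               c(pre_op = 36L, short_post = 55L, long_post = 62L))
  cmp <- compare_subgroups(sf, top = 4)
  expect_equal(nrow(cmp$top), 12L)
  expect_equal(dim(cmp$trajectory), c(13L, 4L))
  expect_setequal(names(cmp$trajectory), c("item_id", names(sf)))

  # a single-phase dataset reproduces the overall fit
  d <- bibd(13, 4)
  st1 <- simulate_study(d, c(pre_op = 10L), master_seed = 5,
                        items = items13())
  one <- fit_by_subgroup(st1)
  whole <- fit_maxdiff(st1, subgroup = "pre_op")
  expect_equal(coef(one$pre_op), coef(whole), tolerance = 1e-9)

  # identical subgroup results give identical comparison columns
  twin <- structure(list(a = whole, b = whole), class = "maxdiff_fit_list")
  cmp2 <- compare_subgroups(twin)
  expect_identical(cmp2$trajectory$a, cmp2$trajectory$b)

  # mismatched catalogs are rejected
  d4 <- bibd(4, 4)
  other <- fit_maxdiff(scripted_responses(d4, c("A", "B", "C", "D"), 6, 1),
                       design = d4, items = c("A", "B", "C", "D"))
  expect_error(compare_subgroups(list(a = whole, b = other)), "different")
  expect_error(compare_subgroups(list(a = whole)), "at least 2")
  expect_error(fit_by_subgroup(
    structure(list(responses = st$responses[0, ], design = st$design,
                   items = st$items,
                   strata_counts = c(pre_op = 1L)),
              class = "bws_study")), "empty")
})

test_that("fit methods are coherent: predict, residuals, simulate, logLik", {
  st <- filter_complete(study_emulation(master_seed = 12))$included
  f <- fit_maxdiff(st)
  pr <- predict(f)
  expect_equal(as.vector(tapply(pr$prob, pr$block, sum)), rep(1, 13),
               tolerance = 1e-12)
  expect_equal(nrow(pr), 13 * 12)
  rs <- residuals(f)
  expect_equal(sum(rs$observed), nrow(st$responses))
  expect_equal(sum(rs$expected), nrow(st$responses), tolerance = 1e-8)
  expect_equal(as.numeric(logLik(f)), f$loglik)
  expect_equal(unname(confint(f)[, 1]),
               f$coefficients$beta - stats::qnorm(0.975) * f$coefficients$se,
               tolerance = 1e-12)
  sim <- simulate(f, seed = 3)
  expect_s3_class(sim, "bws_study")
  expect_equal(length(unique(sim$responses$respondent_id)), f$n_respondents)
})
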