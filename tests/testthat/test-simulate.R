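test_that("default profiles are centered and reproduce the anchored ordering", {
  for (ph in c("overall", "pre_op", "short_post", "long_post")) {
    p <- default_profile(ph)
    expect_equal(sum(p$utility), 0, tolerance = 1e-12)
    expect_identical(names(which.max(p$utility)), "adl")
    expect_identical(names(which.min(p$utility)), "neg")
  }
  ov <- default_profile("overall")$utility
  expect_true(ov["adl"] > ov["pain"])
  # the four headline items dominate the rest
  rest <- setdiff(names(ov), c("adl", "pain", "reint", "comp"))
  expect_true(min(ov[c("adl", "pain", "reint", "comp")]) > max(ov[rest]))
  # phase shifts: pain dips short-term, reintervention rises post-op,
  # complication falls post-op
  pre <- default_profile("pre_op")$utility
  sh <- default_profile("short_post")$utility
  lo <- default_profile("long_post")$utility
  expect_true(pre["pain"] > sh["pain"] && lo["pain"] > sh["pain"])
  expect_true(sh["reint"] > pre["reint"] && lo["reint"] > pre["reint"])
  expect_true(pre["comp"] > sh["comp"] && pre["comp"] > lo["comp"])
  expect_error(default_profile("post_op"), "arg")
})

test_that("maxdiff pair rule: uniform utilities give 12 equiprobable pairs", {
  d <- bibd(4, 4)
  prof <- utility_profile(c(A = 0, B = 0, C = 0, D = 0),
                          heterogeneity_sd = 0)
  n <- 12000
  picks <- character(n)
  for (i in seq_len(n)) {
    r <- simulate_response(d, prof, rng_seed = i, items = c("A", "B", "C", "D"))
    picks[i] <- paste(r$best, r$worst)
  }
  tab <- table(picks)
  expect_equal(length(tab), 12L)
  # each pair within 3 binomial standard errors of 1/12
  se <- sqrt((1 / 12) * (11 / 12) / n)
  expect_true(all(abs(tab / n - 1 / 12) < 3 * se + 1e-9))
})

test_that("a dominant utility wins every block and enumeration matches", {
  d <- bibd(4, 4)
  prof <- utility_profile(c(A = 10, B = 0, C = 0, D = 0),
                          heterogeneity_sd = 0)
  for (s in 1:50) {
    r <- simulate_response(d, prof, rng_seed = s,
                           items = c("A", "B", "C", "D"))
    expect_identical(r$best, "A")
  }
  # closed form for a 3-item block with u = (1, 0, 0)
  u <- c(1, 0, 0)
  pp <- bwspref:::maxdiff_pair_probs(u)
  oracle <- enum_pair_probs(u)
  expect_equal(pp$prob[pp$best == 1 & pp$worst == 2],
               exp(1) / (2 * exp(1) + 2 * exp(-1) + 2),
               tolerance = 1e-12)
  m <- merge(pp, oracle, by = c("best", "worst"))
  expect_equal(m$prob.x, m$prob.y, tolerance = 1e-12)
  expect_equal(sum(pp$prob), 1, tolerance = 1e-12)
})

test_that("study simulation is deterministic and respects strata", {
  d <- bibd(13, 4)
  st1 <- simulate_study(d, c(pre_op = 2L, short_post = 2L, long_post = 2L),
                        master_seed = 9, items = items13())
  st2 <- simulate_study(d, c(pre_op = 2L, short_post = 2L, long_post = 2L),
                        master_seed = 9, items = items13())
  expect_identical(st1$responses, st2$responses)
  expect_equal(length(unique(st1$responses$respondent_id)), 6L)
  expect_false(anyNA(st1$responses$best))
  st3 <- simulate_study(d, c(pre_op = 2L, short_post = 2L, long_post = 2L),
                        master_seed = 10, items = items13())
  expect_false(identical(st1$responses, st3$responses))
})

test_that("study-emulation preset reproduces the enrollment structure", {
  st <- study_emulation(master_seed = 3)
  expect_equal(st$n_submitted, 168L)
  expect_equal(length(unique(st$responses$respondent_id)), 168L)
  flt <- filter_complete(st)
  inc_ids <- unique(flt$included$responses$respondent_id)
  exc_ids <- unique(flt$excluded$respondent_id)
  expect_equal(length(inc_ids), 153L)
  expect_equal(length(exc_ids), 15L)
  # partition: exhaustive and disjoint
  expect_length(intersect(inc_ids, exc_ids), 0L)
  expect_setequal(c(inc_ids, exc_ids), unique(st$responses$respondent_id))
  expect_equal(flt$included$strata_counts,
               c(pre_op = 36L, short_post = 55L, long_post = 62L))
  # excluded respondents are exactly those with a missing pick
  expect_true(all(tapply(is.na(flt$excluded$best) | is.na(flt$excluded$worst),
                         flt$excluded$respondent_id, any)))
  expect_false(anyNA(flt$included$responses$best))
})

test_that("a single missing worst pick excludes only that respondent", {
  d <- bibd(13, 4)
  st <- simulate_study(d, c(overall = 5L), master_seed = 2,
                       profiles = list(overall = default_profile("overall")),
                       items = items13())
  st$responses$worst[st$responses$respondent_id == "R003" &
                       st$responses$block == 7] <- NA
  flt <- filter_complete(st)
  expect_identical(unique(flt$excluded$respondent_id), "R003")
  expect_equal(length(unique(flt$included$responses$respondent_id)), 4L)
})

test_that("profile coverage is enforced", {
  d <- bibd(13, 4)
  short <- utility_profile(c(adl = 1, pain = -1), heterogeneity_sd = 0)
  expect_error(simulate_response(d, short, 1, items = items13()),
               "does not cover")
  expect_error(simulate_study(d, c(overall = 2L),
                              profiles = list(overall = short),
                              items = items13()),
               "does not cover")
  expect_error(simulate_study(d, c(pre_op = 2L),
                              profiles = list(short_post = default_profile()),
                              master_seed = 1, items = items13()),
               "no profile supplied")
})
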