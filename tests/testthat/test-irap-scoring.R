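test_that("practice gate applies both criteria with literal boundary semantics", {
  # accuracies (0.875, 0.833)-ish and medians well below 2000: eligible
  good <- rbind(make_practice_pair("P1", 1, accuracy = 0.875, median_ms = 1800))
  expect_true(practice_gate(good)$eligible)

  # accuracy exactly 0.80 passes (inclusive) but median exactly 2000 fails
  # (strict): verify against a direct re-read of each block (20-trial
  # blocks so the 80% boundary is attainable exactly)
  boundary_block <- function(rule, lat) data.frame(
    participant_id = "P2", phase = "practice", pair_index = 1L,
    block_rule = rule, trial_type = rep(1:4, 5),
    latency_ms = rep(lat, 20), first_response_correct = rep(c(TRUE, FALSE), c(16, 4)),
    stringsAsFactors = FALSE)
  pair <- rbind(boundary_block("straight_block", 2000),
                boundary_block("lesbian_block", 1500))
  blk <- pair[pair$block_rule == "straight_block", ]
  expect_identical(mean(blk$first_response_correct), 0.8 + 0)
  expect_identical(median(blk$latency_ms), 2000 + 0)
  expect_false(practice_gate(pair)$eligible)
  # dropping the median to 1999 makes the same pair pass
  pair$latency_ms[pair$block_rule == "straight_block"] <- 1999
  expect_true(practice_gate(pair)$eligible)

  # three failing pairs: not eligible, pairs_used = 3
  fails <- do.call(rbind, lapply(1:3, function(k)
    make_practice_pair("P3", k, accuracy = 0.75, median_ms = 1500)))
  res <- practice_gate(fails)
  expect_false(res$eligible)
  expect_equal(res$pairs_used, 3L)

  # the first passing pair is reported
  mix <- rbind(make_practice_pair("P4", 1, accuracy = 0.70),
               make_practice_pair("P4", 2, accuracy = 0.92))
  expect_equal(practice_gate(mix)$pairs_used, 2L)

  expect_error(practice_gate(make_irap_participant("P5", seed = 1)[0, ]),
               "practice")
})

test_that("trial filter removes strictly-above-10s latencies only", {
  trials <- make_irap_block("P1", "test", 1, "straight_block",
                            latencies = c(10001, 10000, 9999, rep(1500, 21)))
  kept <- apply_trial_filter(trials)
  expect_equal(nrow(kept), 23L)
  expect_false(10001 %in% kept$latency_ms)
  expect_true(all(c(10000, 9999) %in% kept$latency_ms))
  # identity when nothing is above threshold
  clean <- make_irap_block("P1", "test", 1, "straight_block", latencies = 1500)
  expect_identical(apply_trial_filter(clean), clean)
})

test_that("fast-responder rule uses a strict 10% threshold over all test trials", {
  base <- make_irap_test("P1", function(p, tt, rule) rep(1500, 6))  # 144 trials
  lat <- base
  lat$latency_ms[seq_len(15)] <- 250           # 15/144 = 10.4% -> excluded
  expect_true(fast_responder_check(lat))
  lat$latency_ms[15] <- 1500                   # 14/144 = 9.7% -> retained
  expect_false(fast_responder_check(lat))
  expect_false(fast_responder_check(base))     # 0 fast trials
})

test_that("D scores match direct arithmetic on the worked four-latency cell", {
  cell_fun <- function(p, tt, rule) {
    if (rule == "straight_block") c(1000, 1200, 1000, 1200, 1000, 1200)[1:2] else
      c(1400, 1600)[1:2]
  }
  # two latencies per cell, identical in every (pair, trial type)
  trials <- do.call(rbind, lapply(1:3, function(p) {
    do.call(rbind, lapply(c("straight_block", "lesbian_block"), function(rule) {
      data.frame(participant_id = "P1", phase = "test", pair_index = p,
                 block_rule = rule, trial_type = rep(1:4, each = 2),
                 latency_ms = rep(cell_fun(p, 1, rule), 4),
                 first_response_correct = TRUE, stringsAsFactors = FALSE)
    }))
  }))
  ds <- compute_d_scores(trials)
  expected <- (1500 - 1100) / sd(c(1000, 1200, 1400, 1600))   # 400 / 258.199
  expect_equal(unname(ds$per_pair[1, 1]), expected, tolerance = 1e-12)
  expect_equal(expected, 1.549193, tolerance = 1e-6)
  expect_equal(ds$averaged, expected, tolerance = 1e-12)

  # identical latency multiset in both blocks: all 12 scores are zero
  same <- trials
  same$latency_ms <- rep(c(1000, 1200), length.out = nrow(same))
  ds0 <- compute_d_scores(same)
  expect_equal(unname(as.vector(ds0$per_pair)), rep(0, 12))
  expect_equal(ds0$averaged, 0)
})

test_that("D scores are scale- and shift-invariant and antisymmetric", {
  for (seed in 1:5) {
    trials <- make_irap_test("P1", function(p, tt, rule) {
      exp(rnorm(6, log(1500) + 0.2 * (rule == "lesbian_block"), 0.4))
    })
    ds <- compute_d_scores(trials)

    scaled <- trials; scaled$latency_ms <- trials$latency_ms * 3
    expect_equal(compute_d_scores(scaled)$per_pair, ds$per_pair, tolerance = 1e-12)

    shifted <- trials; shifted$latency_ms <- trials$latency_ms + 500
    expect_equal(compute_d_scores(shifted)$per_pair, ds$per_pair, tolerance = 1e-12)

    swapped <- trials
    swapped$block_rule <- ifelse(trials$block_rule == "straight_block",
                                 "lesbian_block", "straight_block")
    expect_equal(compute_d_scores(swapped)$per_pair, -ds$per_pair, tolerance = 1e-12)
  }
})

test_that("D scores equal the straight-line oracle on small cohorts", {
  set.seed(7)
  for (i in 1:5) {
    trials <- make_irap_test(sprintf("P%d", i), function(p, tt, rule) {
      exp(rnorm(6, log(1500) + 0.1 * tt * (rule == "lesbian_block"), 0.3))
    })
    ds <- compute_d_scores(trials)
    oracle <- oracle_d_scores(trials)
    expect_equal(unname(ds$per_pair), unname(oracle$per_pair), tolerance = 1e-12)
    expect_equal(ds$averaged, oracle$averaged, tolerance = 1e-12)
  }
})

test_that("scoring errors name the offending cell", {
  trials <- make_irap_test("P1", function(p, tt, rule) rep(1500, 6))
  # constant latencies -> zero pooled SD
  expect_error(compute_d_scores(trials), "pair 1, trial type 1")
  # too few latencies in one cell after heavy filtering
  trials2 <- make_irap_test("P1", function(p, tt, rule)
    exp(rnorm(6, log(1500), 0.3)))
  drop <- which(trials2$pair_index == 2 & trials2$trial_type == 3 &
                  trials2$block_rule == "lesbian_block")[1:5]
  expect_error(compute_d_scores(trials2[-drop, ]), "pair 2, trial type 3")
})

test_that("exclusion pipeline order does not change who is excluded", {
  set.seed(21)
  # fixture mix: a clean participant, a fast responder, a long-latency one
  clean <- make_irap_participant("CLEAN", effect = 0.2)
  fastr <- make_irap_participant("FASTR")
  idx <- which(fastr$phase == "test")[1:20]        # 20/144 = 14% fast
  fastr$latency_ms[idx] <- 250
  longl <- make_irap_participant("LONGL")
  idx <- which(longl$phase == "test")[c(1, 25, 49, 73, 97, 121)]  # one per block
  longl$latency_ms[idx] <- 12000
  trials <- rbind(clean, fastr, longl)

  scored <- score_irap(trials)
  expect_equal(scored$excluded_reason[scored$participant_id == "CLEAN"], "none")
  expect_equal(scored$excluded_reason[scored$participant_id == "FASTR"],
               "fast_responder")
  expect_equal(scored$excluded_reason[scored$participant_id == "LONGL"], "none")

  # permuting the two filters: fast-responder proportions computed after
  # the 10,000 ms filter flag the same participants on these fixtures
  for (pid in c("CLEAN", "FASTR", "LONGL")) {
    tp <- trials[trials$participant_id == pid & trials$phase == "test", ]
    expect_equal(fast_responder_check(apply_trial_filter(tp)),
                 fast_responder_check(tp))
  }
})

test_that("ineligible participants keep missing scores, eligible are scored", {
  set.seed(5)
  pass <- make_irap_participant("PASS", effect = 0.3)
  fail <- rbind(do.call(rbind, lapply(1:3, function(k)
    make_practice_pair("FAIL", k, accuracy = 0.6))))
  scored <- score_irap(rbind(pass, fail))
  expect_equal(scored$excluded_reason, c("none", "practice_fail"))
  expect_false(is.na(scored$d_avg[1]))
  expect_true(is.na(scored$d_avg[2]))
  expect_true(scored$d_avg[1] > 0)   # slower lesbian block -> positive score
  expect_equal(scored$d_male[1], mean(unlist(scored[1, c("d_tt1", "d_tt2")])))
})
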