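# Task design generation and the generative behavioral model.

test_that("exact allocation realizes the design probabilities exactly", {
  sp <- design_spec(n_blocks = 2, trials_per_block = 24, seed = 7,
                    hand_switch_block = 2)
  tab <- generate_design(sp)
  expect_equal(nrow(tab), 48)
  expect_equal(unname(table(tab$condition)[c("EG", "EC", "EN")]),
               rep(16L, 3), ignore_attr = TRUE)
  expect_true(all(tab$target_type[tab$condition == "EG"] == "standard"))
  expect_equal(sum(tab$target_type == "change") / sum(tab$condition == "EC"), 0.25)
  expect_equal(sum(tab$target_type == "nogo") / sum(tab$condition == "EN"), 0.25)
  # change targets only under EC, nogo only under EN
  expect_true(all(tab$condition[tab$target_type == "change"] == "EC"))
  expect_true(all(tab$condition[tab$target_type == "nogo"] == "EN"))
  # constant cue-to-target interval
  expect_true(all(abs((tab$target_onset_s - tab$cue_onset_s) - 1.1) < 1e-9))
  # hand switch at the configured block
  expect_equal(unique(tab$standard_hand[tab$block == 1]), "right")
  expect_equal(unique(tab$standard_hand[tab$block == 2]), "left")
})

test_that("unrealizable allocations fail with an informative error", {
  sp <- design_spec(n_blocks = 1, trials_per_block = 10, seed = 1,
                    hand_switch_block = 2)
  expect_error(generate_design(sp), "not realizable")
})

test_that("trial tables are byte-identical under the same seed", {
  sp <- design_spec(n_blocks = 2, trials_per_block = 12, seed = 123,
                    hand_switch_block = 2)
  expect_identical(generate_design(sp), generate_design(sp))
  sp2 <- design_spec(n_blocks = 2, trials_per_block = 12, seed = 124,
                     hand_switch_block = 2)
  expect_false(identical(generate_design(sp), generate_design(sp2)))
})

test_that("random allocation converges to the condition probabilities", {
  # chi-square goodness of fit should rarely reject at alpha = 0.01
  rejections <- 0L
  for (s in 1:40) {
    sp <- design_spec(n_blocks = 1, trials_per_block = 300, seed = s,
                      hand_switch_block = 2)
    tab <- generate_design(sp, exact_allocation = FALSE)
    counts <- table(factor(tab$condition, levels = c("EG", "EC", "EN")))
    p <- stats::chisq.test(counts, p = rep(1 / 3, 3))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 3L)
})

test_that("degenerate behavioral parameter settings behave as specified", {
  tab <- small_trials(24)
  p0 <- behavior_params(premature = c(EG = 0, EC = 0, EN = 0),
                        omission = c(go = 0, `no-change` = 0, `no-nogo` = 0, change = 0),
                        choice_error = c(go = 0, `no-change` = 0, `no-nogo` = 0, change = 0),
                        failed_inhibition = 0, seed = 2)
  tb <- simulate_behavior(tab, p0)
  expect_true(all(tb$correct[tb$target_type == "standard"]))
  expect_true(all(tb$response[derived_condition(tb) == "nogo"] == "none"))
  # RT present iff a button was pressed
  expect_identical(!is.na(tb$rt_ms), tb$response %in% c("left", "right"))

  p1 <- behavior_params(premature = c(EG = 1, EC = 0, EN = 0), seed = 2)
  tb1 <- simulate_behavior(tab, p1)
  expect_true(all(tb1$response[tb1$condition == "EG"] == "premature"))
})

test_that("behavioral summary matches an independent group-by oracle", {
  tab <- small_trials(48, seed = 9)
  tb <- simulate_behavior(tab, behavior_params(seed = 5))
  tb$subject <- 1L
  s <- behavioral_summary(tb)
  dc <- derived_condition(tb)
  for (cc in c("go", "no-change", "change")) {
    sel <- dc == cc & tb$correct & tb$response %in% c("left", "right")
    expected <- if (any(sel)) mean(tb$rt_ms[sel]) else NA_real_
    expect_equal(s[[paste0("rt_", cc)]], expected)
  }
  expect_equal(s$premature_EG, mean(tb$response[tb$condition == "EG"] == "premature"))
  # all RTs equal -> condition means equal that value
  tb2 <- tb
  tb2$rt_ms[!is.na(tb2$rt_ms)] <- 300
  s2 <- behavioral_summary(tb2)
  expect_true(all(abs(na.omit(unlist(s2[paste0("rt_", c("go", "no-change"))])) - 300) < 1e-12))
})

test_that("injected RT ordering is recovered across a simulated cohort", {
  tabs <- lapply(1:20, function(s) {
    tb <- simulate_behavior(small_trials(48, seed = s),
                            behavior_params(seed = 77), subject = s)
    tb$subject <- s
    tb
  })
  s <- behavioral_summary(do.call(rbind, tabs))
  ok <- stats::complete.cases(s$rt_go, s$`rt_no-change`, s$rt_change)
  t1 <- paired_t(s$`rt_no-change`[ok], s$rt_go[ok])
  t2 <- paired_t(s$rt_change[ok], s$`rt_no-change`[ok])
  expect_gt(t1$t, 2); expect_lt(t1$p, 0.05)
  expect_gt(t2$t, 2); expect_lt(t2$p, 0.05)
})

test_that("trial tables round-trip through TSV with a design sidecar", {
  sp <- design_spec(n_blocks = 1, trials_per_block = 12, seed = 3,
                    hand_switch_block = 2)
  tab <- generate_design(sp)
  path <- tempfile(fileext = ".tsv")
  write_trial_table(tab, path, spec = sp)
  tab2 <- read_trial_table(path)
  expect_equal(tab$condition, tab2$condition)
  expect_equal(tab$cue_onset_s, tab2$cue_onset_s, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$trials_per_block, 12)
})
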