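test_that("trigger requires both load and dominance to be exceeded", {
  rule <- surveillance_rule()
  # 75% load, 40% dominant share -> fires at the dominant taxon
  tr <- surveillance_trigger(ab(c(120, 60, 60, 60), 400), rule)
  expect_true(tr$fired); expect_identical(tr$target, 1L)
  # 75% load but flat community (25% shares) -> dominance unmet
  expect_false(surveillance_trigger(ab(rep(75, 4), 400), rule)$fired)
  # 50% load, 90% dominance -> load unmet
  expect_false(surveillance_trigger(ab(c(180, 20, 0, 0), 400), rule)$fired)
})

test_that("thresholds are strict: sitting exactly on the boundary never fires", {
  rule <- surveillance_rule()
  # exactly 70.0% load with clear dominance
  expect_false(surveillance_trigger(ab(c(140, 70, 35, 35), 400), rule)$fired)
  # exactly 30.0% dominant share with clear load
  expect_false(surveillance_trigger(ab(c(90, 90, 70, 50), 400), rule)$fired)
  # one cell above each boundary fires
  expect_true(surveillance_trigger(ab(c(141, 70, 35, 35), 400), rule)$fired)
})

test_that("trigger ties go to the lowest species id", {
  tr <- surveillance_trigger(ab(c(150, 150, 40, 20), 400), surveillance_rule())
  expect_true(tr$fired)
  expect_identical(tr$target, 1L)
})

test_that("penalization removes the rounded fraction of the target only", {
  lat <- make_fixture(20, 20, occupancy = 0.75, dominant_share = 200 / 300,
                      n_species = 4, dominant_id = 2, seed = 1)
  before <- count_abundances(lat)$counts
  expect_identical(before[2], 200L)
  set.seed(1)
  out <- penalize(lat, 2L, surveillance_rule())
  after <- count_abundances(out)$counts
  expect_identical(before[2] - after[2], 160L)  # exactly 80% of 200
  expect_identical(after[-2], before[-2])       # non-targets untouched
})

test_that("penalization rounding is half-away-from-zero and handles one cell", {
  lat <- single_species_lattice(5, 5, 1)
  set.seed(1)
  out <- penalize(lat, 1L, surveillance_rule())  # round(0.8) -> 1 removed
  expect_identical(count_abundances(out)$counts, 0L)

  # 5 cells at 50% removal: round-half-up gives 3, not banker's 2
  lat5 <- single_species_lattice(6, 6, 5)
  set.seed(1)
  out5 <- penalize(lat5, 1L, surveillance_rule(removal_fraction = 0.5))
  expect_identical(count_abundances(out5)$counts, 2L)

  expect_error(penalize(lat, 1L, surveillance_rule()) |> penalize(1L, surveillance_rule()),
               "absent")
})

test_that("whole-community policy removes the fraction from every species", {
  lat <- make_fixture(20, 20, occupancy = 0.75, dominant_share = 0.40,
                      seed = 2)
  before <- count_abundances(lat)$counts
  set.seed(3)
  out <- penalize(lat, NA, surveillance_rule(target_policy = "whole_community"))
  after <- count_abundances(out)$counts
  expect_identical(before - after,
                   as.integer(floor(0.8 * before + 0.5)))
})

test_that("schedules gate activation with half-open windows", {
  sch <- schedule("windows", default_windows)
  expect_false(is_active(sch, 199))
  expect_true(is_active(sch, 200))
  expect_true(is_active(sch, 399))
  expect_false(is_active(sch, 400))
  expect_false(is_active(sch, 500))
  expect_true(is_active(sch, 600))
  expect_false(is_active(sch, 800))
  expect_true(all(!is_active(schedule("off"), 0:100)))
  expect_true(all(is_active(schedule("always"), 0:100)))
  expect_error(schedule("windows", list(c(100, 50))), "start < end")
  expect_error(schedule("windows", list(c(0, 100), c(50, 200))),
               "non-overlapping")
})

test_that("penalization never fires outside active windows along a trajectory", {
  cfg <- small_config(n_steps = 200,
                      surveillance = list(mode = "windows",
                                          windows = list(c(50, 120))))
  tr <- ktw_run(cfg)$trajectory
  expect_true(any(tr$penalized))  # the window does see events
  expect_true(all(tr$step[tr$penalized] >= 50 & tr$step[tr$penalized] < 120))
})

test_that("a penalization event decreases only the dominant species", {
  cfg <- small_config(n_steps = 300)
  tr <- ktw_run(cfg)$trajectory
  fired <- which(tr$penalized)
  expect_gt(length(fired), 0)
  counts <- as.matrix(tr[paste0("count_", 1:4)])
  for (t in fired[fired > 1]) {
    if (any(counts[t - 1, ] < 20)) next  # skip noisy small-count steps
    ratio <- counts[t, ] / counts[t - 1, ]
    # exactly one species crashed (the 80% removal of the dominant taxon);
    # the others changed only through mortality and replication
    expect_identical(sum(ratio < 0.5), 1L)
    crashed <- which.min(ratio)
    # and the crashed species was the dominant one after the dynamics phases:
    # its pre-penalization count (about count[t]/0.2) tops the others
    expect_identical(unname(which.max(replace(counts[t, ], crashed,
                                              counts[t, crashed] / 0.2))),
                     unname(crashed))
  }
})

test_that("rule validation names the offending threshold", {
  expect_error(surveillance_rule(load_threshold = 1.5), "load_threshold")
  expect_error(surveillance_rule(dominance_threshold = 0), "dominance_threshold")
  expect_error(surveillance_rule(removal_fraction = -0.1), "removal_fraction")
})
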