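test_that("frozen dynamics leave the lattice unchanged", {
  lat <- initialize_lattice(10, 10, 2, 0.5, seed = 1)
  set.seed(1)
  out <- ktw_step(lat, replication_probs = c(0, 0), mortality = 0)
  expect_identical(out$occupancy, lat$occupancy)
})

test_that("a lone cell with certain replication yields exactly two cells", {
  lat <- single_species_lattice(5, 5, 1)
  set.seed(1)
  out <- ktw_step(lat, replication_probs = 1, mortality = 0)
  cnt <- count_abundances(out)$counts
  expect_identical(cnt, 2L)
  # offspring sits on one of the parent's six neighbors
  born <- setdiff(which(out$occupancy == 1L), 1L)
  expect_true(born %in% hex_neighbors(lat, 1L))
})

test_that("a full lattice cannot grow (space limitation)", {
  lat <- hex_lattice(6, 6, 2, occupancy = rep(c(1L, 2L), 18))
  set.seed(1)
  out <- ktw_step(lat, replication_probs = c(1, 1), mortality = 0)
  expect_identical(out$occupancy, lat$occupancy)
})

test_that("mortality-only dynamics are binomial thinning (ensemble oracle)", {
  # one step: E[survivors] = N(1 - d); 10,000 replicates of a 100-cell state
  lat <- single_species_lattice(20, 20, 100)
  d <- 0.05
  set.seed(2024)
  survivors <- replicate(10000, {
    count_abundances(ktw_step(lat, replication_probs = 0, mortality = d))$counts
  })
  se <- sd(survivors) / sqrt(length(survivors))
  expect_lt(abs(mean(survivors) - 100 * (1 - d)), 3 * se)

  # t steps: E[survivors] = N(1 - d)^t
  t_steps <- 10
  set.seed(2025)
  surv_t <- replicate(2000, {
    cur <- lat
    for (i in seq_len(t_steps))
      cur <- ktw_step(cur, replication_probs = 0, mortality = d)
    count_abundances(cur)$counts
  })
  se_t <- sd(surv_t) / sqrt(length(surv_t))
  expect_lt(abs(mean(surv_t) - 100 * (1 - d)^t_steps), 3 * se_t)
})

test_that("conservation and exclusion hold along a full run", {
  run <- ktw_run(small_config(surveillance = list(mode = "always")))
  tr <- run$trajectory
  counts <- as.matrix(tr[paste0("count_", 1:4)])
  expect_identical(unname(rowSums(counts)), as.numeric(tr$total))
  expect_true(all(tr$total <= 400))
  # final lattice agrees with the last recorded row
  expect_identical(count_abundances(run$final_lattice)$counts,
                   as.integer(counts[nrow(counts), ]))
})

test_that("with no mortality and no surveillance, species counts never decrease", {
  cfg <- ktw_config(width = 15, height = 15, mortality = 0, n_steps = 80,
                    seed = 5, init_occupancy = 0.2,
                    surveillance = list(mode = "off"))
  tr <- ktw_run(cfg)$trajectory
  for (col in paste0("count_", 1:4))
    expect_true(all(diff(tr[[col]]) >= 0), info = col)
})

test_that("runs are reproducible and reject invalid step counts", {
  cfg <- small_config()
  a <- ktw_run(cfg); b <- ktw_run(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_lattice$occupancy, b$final_lattice$occupancy)
  expect_error(ktw_config(n_steps = 0), "positive integer")
})

test_that("penalization substream does not shift the dynamics draws", {
  # same seed, surveillance on vs off: trajectories must agree exactly until
  # the first penalization event
  cfg_on <- small_config(n_steps = 300)
  cfg_off <- small_config(n_steps = 300, surveillance = list(mode = "off"))
  on <- ktw_run(cfg_on)$trajectory
  off <- ktw_run(cfg_off)$trajectory
  first <- which(on$penalized)[1]
  expect_false(is.na(first))  # the small run does trigger
  expect_gt(first, 1)
  pre <- seq_len(first - 1L)
  expect_identical(on[pre, ], off[pre, ])
  expect_false(isTRUE(all.equal(on[first, ], off[first, ],
                                check.attributes = FALSE)))
})

test_that("the fastest replicator wins when surveillance is off", {
  finals <- vapply(1:12, function(s) {
    cfg <- ktw_config(width = 25, height = 25, n_steps = 400, seed = s,
                      surveillance = list(mode = "off"))
    unlist(ktw_run(cfg)$trajectory[400, paste0("count_", 1:4)])
  }, numeric(4))
  med <- apply(finals, 1, median)
  expect_identical(unname(which.max(med)), 4L)
})
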