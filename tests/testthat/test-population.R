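test_that("relative fitness matches hand-evaluated cases", {
  expect_equal(relative_fitness(c(0, 0, 0)), rep(1 / 3, 3))
  # minfit = 0, allfit = 1 + 1.5, lethal individual gets zero weight
  expect_equal(relative_fitness(c(0, 0.5, -2)), c(0.4, 0.6, 0))
  expect_equal(relative_fitness(c(-1, 0.2)), c(0, 1))
})

test_that("relative fitness is a proper distribution with positive support", {
  set.seed(201)
  for (k in 1:50) {
    fit <- runif(20, -1.5, 0.5)
    fit[1] <- 0 # keep at least one viable individual
    rf <- relative_fitness(fit)
    expect_true(all(rf >= 0))
    expect_equal(sum(rf), 1)
    viable <- fit > -1
    # the least-fit viable individual keeps strictly positive weight
    expect_gt(min(rf[viable]), 0)
    expect_true(all(rf[!viable] == 0))
  }
  # a deleted individual (F = 0) outcompetes nobody but still reproduces
  rf <- relative_fitness(c(0, -0.5))
  expect_gt(rf[1], rf[2])
  expect_gt(rf[2], 0)
})

test_that("relative fitness signals extinction when nobody is viable", {
  expect_error(relative_fitness(c(-1, -2)), class = "gb_extinct")
})

test_that("the initial population is a clonal non-genic locus", {
  st <- initialize_population(sim_config(N = 10))
  expect_equal(st$F, rep(0, 10))
  expect_equal(st$E, rep(1e-3, 10))
  expect_equal(st$L, rep(1L, 10))
  expect_equal(state_adaptive_value(st), rep(0, 10))
})

test_that("parent selection follows the regime and the weights", {
  set.seed(202)
  low <- select_parents(rep(0.25, 4), "low", N = 10)
  expect_length(unique(low), 1)
  expect_equal(select_parents(c(1, 0, 0), "high", N = 5), rep(1L, 5))
  # empirical frequencies match the weights (multinomial LLN)
  draws <- select_parents(c(0.4, 0.6, 0), "high", N = 1e5)
  p_hat <- tabulate(draws, 3) / 1e5
  expect_lt(abs(p_hat[1] - 0.4), 3 * sqrt(0.4 * 0.6 / 1e5))
  expect_equal(p_hat[3], 0)
})

test_that("certain deletion wipes out the locus in one step", {
  set.seed(203)
  cfg <- small_config(d = 1)
  out <- advance_step(initialize_population(cfg), chlamy_dfe(), cfg)
  expect_true(all(out$state$L == 0L))
  expect_true(all(out$state$F == 0))
  expect_true(all(out$state$E == 0))
})

test_that("locus loss is hereditary and d = 0 keeps every carrier", {
  set.seed(204)
  cfg <- small_config(d = 0.3)
  st <- initialize_population(cfg)
  for (t in 1:10) {
    out <- advance_step(st, chlamy_dfe(), cfg)
    # no offspring of a locus-free parent carries the locus
    expect_true(all(out$state$L[st$L[out$parents] == 0L] == 0L))
    st <- out$state
  }
  cfg0 <- small_config(d = 0)
  r <- run_replicate(chlamy_dfe(), cfg0, seed = 1)
  expect_true(all(r$trajectory$n_carriers == cfg0$N))
})

test_that("the locus state invariants hold along a replicate", {
  set.seed(205)
  cfg <- small_config(d = 0.1)
  st <- initialize_population(cfg)
  for (t in 1:15) {
    st <- advance_step(st, chlamy_dfe(), cfg)$state
    lost <- st$L == 0L
    expect_true(all(st$F[lost] == 0) && all(st$E[lost] == 0))
    expect_true(all(st$E[!lost] >= cfg$E_min) &&
                  all(st$E[!lost] <= cfg$E_max))
    # F = A * E reconstructs exactly for carriers
    A <- state_adaptive_value(st)
    expect_equal(A[!lost] * st$E[!lost], st$F[!lost])
  }
})

test_that("compiled and reference steppers are bit-identical", {
  dfe <- chlamy_dfe()
  cases <- list(
    list(cfg = sim_config(N = 25, steps = 12, regime = "high", d = 0),
         jump = 0),
    list(cfg = sim_config(N = 25, steps = 12, regime = "high", d = 0.1),
         jump = 0),
    list(cfg = sim_config(N = 25, steps = 12, regime = "low", d = 0.05),
         jump = 0),
    list(cfg = sim_config(N = 25, steps = 12, regime = "high"),
         jump = 0.05))
  for (cs in cases) {
    set.seed(42)
    st <- initialize_population(cs$cfg)
    for (t in seq_len(cs$cfg$steps))
      st <- advance_step(st, dfe, cs$cfg, jump_prob = cs$jump)$state
    r <- run_replicate(dfe, cs$cfg, seed = 42, jump_prob = cs$jump)
    expect_identical(st$F, r$final$F)
    expect_identical(st$E, r$final$E)
    expect_identical(st$L, r$final$L)
  }
})

test_that("low-regime populations descend from a single ancestor per step", {
  r <- run_replicate(chlamy_dfe(), sim_config(N = 40, steps = 30,
                                              regime = "low"),
                     seed = 7, keep_ancestry = TRUE)
  expect_true(all(apply(r$parents, 1, function(x) length(unique(x))) == 1))
})

test_that("a uniformly lethal DFE drives the population extinct", {
  # every mutation costs ~5 fitness units: all lineages pass F = -1 at once
  lethal <- dfe_params(p = 1e-6, f = 0, n = 5, s = 0.9)
  r <- run_replicate(lethal, sim_config(N = 20, steps = 50), seed = 31)
  expect_true(r$extinct)
  expect_false(r$retained)
  expect_false(r$crossed)
  expect_lt(r$steps_run, 50)
  st <- list(F = r$final$F, E = r$final$E, L = r$final$L, t = r$steps_run)
  expect_error(advance_step(structure(st, class = "population_state"),
                            lethal, sim_config(N = 20, steps = 50)),
               class = "gb_extinct")
})

test_that("replicates replay bit-identically from their seed", {
  cfg <- small_config(regime = "high", d = 0.01)
  r1 <- run_replicate(chlamy_dfe(), cfg, seed = 99)
  r2 <- run_replicate(chlamy_dfe(), cfg, seed = 99)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final, r2$final)
  expect_identical(r1$lca_fitness, r2$lca_fitness)
})
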