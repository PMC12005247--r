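# The generalized life-history framework: N_min solvers, reproductive excess,
# bottlenecks, and the Wright-Fisher identities.

test_that("life cycles propagate stage sizes and reject bad inputs", {
  wf <- life_cycle(list(transition("birth", "reproduction", c(a = 2, b = 1)),
                        transition("death", "survival", c(a = 0.5, b = 0.5))),
                   n0 = 100, frequencies = c(a = 0.5, b = 0.5))
  expect_equal(wf$stage_sizes, c(100, 150, 75))
  expect_equal(unname(wf$freqs[, 2]), c(2 / 3, 1 / 3))
  expect_error(transition("t", "survival", 1.2), "k > 1")
  expect_error(life_cycle(list(transition("t", "survival", 0.5)), 10,
                          frequencies = c(a = 0.6, b = 0.6)), "sum to 1")
})

test_that("density-dependent multipliers are resolved on the baseline trajectory", {
  regrow <- function(stage_size, freqs) c(g1 = 1000 / stage_size)
  cyc <- life_cycle(list(transition("dilution", "survival", 0.01),
                         transition("regrowth", "reproduction", regrow)),
                    n0 = 1000, frequencies = c(g1 = 1))
  expect_equal(cyc$stage_sizes, c(1000, 10, 1000))
  expect_equal(unname(cyc$k[, "regrowth"]), 100)
})

test_that("N_min solvers reproduce the defining equations", {
  # all non-focal multipliers 1: no compensation elsewhere
  flat <- life_cycle(list(transition("focal", "reproduction", 2),
                          transition("other", "survival", 1)), n0 = 80)
  expect_equal(solve_nmin_actual(flat, 1), 80)
  # two genotypes, non-focal products {2, 1} at equal frequency
  mix <- life_cycle(list(transition("focal", "survival", c(a = 1, b = 1)),
                         transition("other", "reproduction", c(a = 2, b = 1))),
                    n0 = 90, frequencies = c(a = 0.5, b = 0.5))
  expect_equal(solve_nmin_actual(mix, 1), 90 / 1.5)
  expect_equal(solve_nmin_best(mix, 1), 90 / 2)
  # single genotype, non-focal product 4
  mono <- life_cycle(list(transition("focal", "survival", 0.5),
                          transition("q1", "reproduction", 8),
                          transition("q2", "survival", 0.5)), n0 = 100)
  expect_equal(solve_nmin_actual(mono, 1), 25)
  expect_equal(solve_nmin_best(mono, 1), solve_nmin_actual(mono, 1))
})

test_that("best-genotype N_min never exceeds actual N_min", {
  set.seed(42)
  for (i in 1:20) {
    cyc <- random_cycle(n_trans = sample(2:5, 1), genotypes = sample(2:4, 1))
    for (j in seq_along(cyc$transitions)) {
      expect_lte(solve_nmin_best(cyc, j), solve_nmin_actual(cyc, j) + 1e-12)
    }
  }
})

test_that("round trip: seeding a cycle with N_min returns the focal entry size", {
  set.seed(7)
  for (i in 1:20) {
    cyc <- random_cycle(n_trans = sample(2:6, 1), genotypes = sample(1:3, 1))
    j <- sample(seq_along(cyc$transitions), 1)
    for (mode in c("best", "actual")) {
      nmin <- solve_nmin(cyc, j, mode)
      expect_equal(simulate_from(cyc, j, nmin, mode), cyc$stage_sizes[j])
    }
  }
})

test_that("reproductive excess matches the worked cases", {
  # stationary monomorphic birth/death cycle: exactly replacing, RE = 0
  wf <- life_cycle(list(transition("birth", "reproduction", 2),
                        transition("death", "survival", 0.5)), n0 = 100)
  expect_equal(reproductive_excess(wf, 1), 0)
  expect_equal(reproductive_excess(wf, 2), 0)
  # k_j = 2, N_j = 100, downstream best product 1
  up <- life_cycle(list(transition("focal", "reproduction", 2),
                        transition("other", "survival", 1)), n0 = 100)
  expect_equal(reproductive_excess(up, 1), 100)
  # k_j = 0.5 survival, N_j = 100, downstream product 4
  dn <- life_cycle(list(transition("focal", "survival", 0.5),
                        transition("other", "reproduction", 4)), n0 = 100)
  expect_equal(reproductive_excess(dn, 1), 25)
})

test_that("reproductive excess is monotone in the focal and non-focal multipliers", {
  set.seed(19)
  for (i in 1:10) {
    cyc <- random_cycle(n_trans = 4, genotypes = 1)
    j <- sample(4, 1)
    base <- reproductive_excess(cyc, j)
    bump <- function(jj, factor) {
      trans <- cyc$transitions
      k_new <- cyc$k[, jj] * factor
      trans[[jj]] <- transition(trans[[jj]]$label,
                                if (all(k_new <= 1)) "survival" else "reproduction",
                                k_new)
      life_cycle(trans, n0 = cyc$n0,
                 frequencies = stats::setNames(1, cyc$genotypes))
    }
    expect_gt(reproductive_excess(bump(j, 1.05), j), base)
    other <- setdiff(seq_len(4), j)[1]
    expect_gt(reproductive_excess(bump(other, 1.05), j), base)
  }
})

test_that("bottleneck form: expectation over paths, point mass reduces to fixed cycle", {
  cyc <- life_cycle(list(transition("rep", "reproduction", 3),
                         transition("surv", "survival", 0.5)), n0 = 60)
  # single deterministic path equal to the non-focal remainder of the cycle
  fixed <- reproductive_excess(cyc, 1, "best")
  viapath <- reproductive_excess_bottleneck(
    cyc, 1, n_bot = cyc$stage_sizes[1],
    paths = list(list(weight = 1, k = 0.5)))
  expect_identical(fixed, viapath)
  # two equiprobable paths with products {1, 3}: N_min = N_bot / 2
  two <- reproductive_excess_bottleneck(
    cyc, 1, n_bot = 100,
    paths = list(list(weight = 0.5, k = 1), list(weight = 0.5, k = 3)))
  expect_equal(two, 3 * 60 - 100 / 2)
  # N_bot = 1 with huge downstream products: RE tends to the focal output
  big <- reproductive_excess_bottleneck(
    cyc, 1, n_bot = 1, paths = list(list(weight = 1, k = c(1e6, 1e3))))
  expect_equal(big, 180, tolerance = 1e-6)
  expect_error(reproductive_excess_bottleneck(
    cyc, 1, n_bot = 10, paths = list(list(weight = 0.4, k = 1))), "sum to 1")
})

test_that("Wright-Fisher identities", {
  id0 <- wf_identities(1, 1, 500)
  expect_equal(id0$selective_deaths_per_capita, 0)
  expect_equal(id0$reproductive_excess_per_capita, 0)
  id <- wf_identities(1, 1.1, 1000)
  expect_equal(id$selective_deaths_per_capita, 0.1)
  expect_equal(id$n_min, 1000 / 1.1)
  expect_equal(id$reproductive_excess_per_capita, 1 - 1 / 1.1)
  id2 <- wf_identities(2, 2, 100)
  expect_equal(id2$selective_deaths_per_capita, 0)
  expect_equal(id2$reproductive_excess_per_capita, 1.5)
  expect_error(wf_identities(1.2, 1.1, 100), "cannot exceed")
})

test_that("per-transition selective deaths never cancel across transitions", {
  surv <- transition("surv", "survival", c(a = 0.9, b = 0.6))
  res <- selective_deaths_per_transition(surv, c(a = 100, b = 100))
  expect_equal(unname(res$per_genotype), c(0, 30))
  expect_equal(res$total, 30)
  # monomorphic: no selective deaths
  expect_equal(selective_deaths_per_transition(
    transition("t", "survival", c(a = 0.7)), c(a = 50))$total, 0)
  # antagonistic pleiotropy: each transition has its own best genotype, so
  # both contribute positive selective deaths even with static frequencies
  t1 <- transition("t1", "survival", c(a = 0.9, b = 0.45))
  t2 <- transition("t2", "reproduction", c(a = 1, b = 2))
  counts <- c(a = 100, b = 100)
  d1 <- selective_deaths_per_transition(t1, counts)$total
  d2 <- selective_deaths_per_transition(t2, counts)$total
  expect_gt(d1, 0)
  expect_gt(d2, 0)
  expect_error(selective_deaths_per_transition(t1, numeric(0)), "empty")
})
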