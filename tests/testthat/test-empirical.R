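# The empirical pipeline: survival estimation, proportion of deaths
# selective, winner's-curse adjustment, fecundity gate, reproductive excess.

test_that("survival rates pool pots and use the density-appropriate denominator", {
  tab <- worked_fixture()
  est <- estimate_survival(tab, "toy_lowdens", density = "low")
  expect_equal(est$rate, c(0.9, 0.5))
  expect_equal(est$denominator, c(100, 100))
  hi <- toy_cohort()
  est_hi <- estimate_survival(hi, "toy", density = "high")
  expect_equal(est_hi$rate, c(1, 0.5))
  expect_equal(est_hi$denominator, c(10, 10))
  expect_error(estimate_survival(tab, "nowhere", "low"), "not present")
  # a genotype with a zero denominator is excluded with a warning
  tab2 <- validate_cohort(rbind(as.data.frame(tab),
                                data.frame(genotype = "c",
                                           environment = "toy_lowdens",
                                           pot = 999, seeds_planted = 10,
                                           seedlings_retained = 0, adults = 0,
                                           seeds_produced = 0)))
  expect_warning(est3 <- estimate_survival(tab2, "toy_lowdens", "low"),
                 "zero denominator")
  expect_equal(nrow(est3), 2)
})

test_that("proportion of deaths selective matches the worked example and bounds", {
  expect_equal(proportion_selective_deaths(c(0.9, 0.5), c(100, 100)), 2 / 3)
  # all rates equal: no deaths are selective
  expect_equal(proportion_selective_deaths(c(0.4, 0.4, 0.4), c(30, 30, 30)), 0)
  # best genotype survives everything: every death was avoidable
  expect_equal(proportion_selective_deaths(c(1, 0.3, 0.6), c(50, 50, 50)), 1)
  # no deaths at all: undefined, not zero
  expect_warning(p <- proportion_selective_deaths(c(1, 1), c(10, 10)),
                 "undefined")
  expect_true(is.na(p))
  # label symmetry
  expect_equal(proportion_selective_deaths(c(0.5, 0.9), c(100, 100)), 2 / 3)
})

test_that("extreme-value adjustment is inert for single genotypes and huge samples", {
  one <- adjust_extreme_value(0.7, 1000, B = 100)
  expect_equal(one$inflation, 0)
  expect_equal(one$r_best_adjusted, 0.7)
  # with enormous per-genotype samples the estimator is consistent and the
  # correction vanishes
  set.seed(8)
  rates <- stats::rbeta(60, 2, 2)
  big <- adjust_extreme_value(rates, rep(1e5, 60), B = 200, seed = 1)
  expect_lt(big$inflation, 0.005)
  expect_equal(big$r_best_adjusted, max(rates), tolerance = 0.01)
  expect_error(adjust_extreme_value(c(0.5, 0.6), c(10, 10), B = 50),
               ">= 100")
})

test_that("adjustment collapses the winner's curse under a shared true rate", {
  # moderate scale here; the full 517 x 30 design is exercised in the
  # acceptance suite
  set.seed(21)
  G <- 200; n <- 30
  props <- replicate(12, {
    adults <- stats::rbinom(G, n, 0.6)
    adj <- adjust_extreme_value(adults / n, rep(n, G), B = 400)
    c(raw = adj$prop_raw, adj = adj$prop_adjusted)
  })
  expect_gt(mean(props["raw", ]), 0.3) # the curse is large...
  expect_lt(abs(mean(props["adj", ])), 2 * stats::sd(props["adj", ]) /
              sqrt(ncol(props))) # ...and the adjustment centres it at 0
  # determinism given a seed
  adults <- stats::rbinom(G, n, 0.6)
  a1 <- adjust_extreme_value(adults / n, rep(n, G), B = 300, seed = 99)
  a2 <- adjust_extreme_value(adults / n, rep(n, G), B = 300, seed = 99)
  expect_identical(a1, a2)
  expect_lte(a1$prop_adjusted, a1$prop_raw)
})

test_that("fecundity gate: null by construction vs a shifted genotype", {
  set.seed(4)
  base <- generate_cohort(synthetic_config(n_genotypes = 25,
                                           pots_per_genotype = 4),
                          seed = 10)$table
  env <- "madrid_highwater_highdens"
  g0 <- fecundity_gate(base, env, n_perm = 400, seed = 1)
  expect_false(g0$significant)
  expect_true(all(g0$deaths == 0))
  # shift one genotype's seed output far upward: the gate must fire and
  # charge everyone else their foregone offspring
  shifted <- base
  idx <- shifted$environment == env & shifted$genotype == "g001" &
    shifted$adults > 0
  shifted$seeds_produced[idx] <- shifted$seeds_produced[idx] * 6L
  g1 <- fecundity_gate(shifted, env, n_perm = 400, seed = 1)
  expect_true(g1$significant)
  expect_gt(g1$total_deaths, 0)
  expect_equal(unname(g1$deaths["g001"]), 0)
  # alpha = 1 disables the gate
  g2 <- fecundity_gate(base, env, alpha = 1, n_perm = 200, seed = 1)
  expect_true(g2$significant)
})

test_that("reproductive excess of the toy cycle matches the hand computation", {
  # 2 genotypes, seedling->adult survival {1.0, 0.5}, 10 seeds per survivor,
  # germination 1, one pot per genotype:
  #   adults/pot = 7.5, seeds/pot = 75, seedlings/pot = 10, r_best = 1
  # RE_seedlings = 10 - 7.5/1 = 2.5 (dispersal-independent)
  # RE_seeds at dispersal d: 75 - 7.5 / (d * 1 * 1) -> 0 at d = 0.1,
  #                                                    67.5 at d = 1
  re <- empirical_reproductive_excess(toy_cohort(), "toy", density = "high",
                                      dispersal_survival = c(0.1, 1))
  expect_equal(re$re_low[re$transition == "seeds"], 0)
  expect_equal(re$re_high[re$transition == "seeds"], 67.5)
  expect_equal(re$re_low[re$transition == "seedlings"], 2.5)
  expect_equal(re$re_high[re$transition == "seedlings"], 2.5)
  # degenerate dispersal range: zero-length RE interval
  re0 <- empirical_reproductive_excess(toy_cohort(), "toy", density = "high",
                                       dispersal_survival = c(0.5, 0.5))
  expect_equal(re0$re_low, re0$re_high)
  # doubling seed output moves the focal output k_j N_j linearly at fixed N_min
  tab2 <- toy_cohort()
  tab2$seeds_produced <- tab2$seeds_produced * 2L
  re2 <- empirical_reproductive_excess(tab2, "toy", density = "high",
                                       dispersal_survival = c(0.1, 1))
  expect_equal(re2$re_high[re2$transition == "seeds"],
               re$re_high[re$transition == "seeds"] + 75)
})

test_that("run_all produces one valid summary per environment, reproducibly", {
  sim <- generate_cohort(synthetic_config(n_genotypes = 30,
                                          pots_per_genotype = 3), seed = 2)
  cfg <- empirical_config(B = 150, n_perm = 150, seed = 11)
  res <- run_all(sim$table, cfg)
  expect_equal(length(res$problems), 0)
  s <- res$summary
  expect_equal(nrow(s), 8)
  expect_setequal(s$transition_scope, c("seed_to_adult", "seedling_to_adult"))
  expect_true(all(s$prop_selective_raw >= 0 & s$prop_selective_raw <= 1))
  expect_true(all(s$prop_selective_adjusted >= 0 &
                    s$prop_selective_adjusted <= s$prop_selective_raw))
  # per-pot seedling excess respects the design caps
  low <- s$transition_scope == "seedling_to_adult"
  expect_true(all(s$re_seedlings_high[low] <= 1))
  expect_true(all(s$re_seedlings_high[!low] <= 30))
  expect_true(all(s$re_seeds_low <= s$re_seeds_high))
  # byte-identical rerun under the same config
  res2 <- run_all(sim$table, cfg)
  expect_identical(res$summary, res2$summary)
})

test_that("benign environments show more excess seeds and fewer selective deaths", {
  sim <- generate_cohort(synthetic_config(n_genotypes = 120,
                                          pots_per_genotype = 3), seed = 6)
  res <- run_all(sim$table, empirical_config(B = 200, n_perm = 100, seed = 5))
  s <- res$summary[res$summary$transition_scope == "seed_to_adult", ]
  hw <- grepl("highwater", s$environment)
  expect_gt(mean(s$prop_selective_adjusted[!hw]),
            mean(s$prop_selective_adjusted[hw]))
  expect_gt(mean(s$re_seeds_low[hw]), mean(s$re_seeds_low[!hw]))
})
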