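# Synthetic cohort generator: emulates the statistical structure of a
# 517-genotype, 2x2x2-environment A. thaliana field design, so the whole
# empirical pipeline can be exercised and validated without external data.

#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the study design the pipeline targets: 517 homozygous
#' genotypes grown across 2 (site) x 2 (water) x 2 (density) environments; at
#' high density 30 seeds per pot with selection measured from seed to adult;
#' at low density ~10 seeds sown, thinned to a single retained seedling, with
#' selection measured from seedling to adult.
#'
#' Genotype-specific seedling-to-adult survival is drawn from a per-water
#' Beta prior: benign high-water conditions use a concentrated, high-mean
#' prior and harsh low-water conditions a diffuse, low-mean one, so that the
#' generated truth reproduces the qualitative field observation that a larger
#' share of deaths is selective under water stress. Germination is
#' genotype-independent. Per-survivor seed output is negative binomial (a
#' gamma-mixed Poisson); the default dispersion gives a coefficient of
#' variation near 0.5, plausible for plants. Setting `fecundity_shift` to a
#' named vector of per-genotype log-fold changes induces true fecundity
#' selection (default: none, matching the null the pipeline's gate tests).
#'
#' @param n_genotypes Number of genotypes (default 517).
#' @param pots_per_genotype Replicate pots per genotype per environment
#'   (default 5; a single pot would leave the low-density transition with a
#'   one-seedling denominator and no information).
#' @param seeds_per_pot_high Seeds planted per high-density pot (30).
#' @param seeds_sown_low Seeds sown per low-density pot (10).
#' @param germination Genotype-independent germination probability.
#' @param survival_prior Named list of `c(alpha, beta)` Beta parameters for
#'   true seedling-to-adult survival, keyed by water level.
#' @param fecundity_mean Mean seeds per surviving adult.
#' @param fecundity_size Negative binomial size (gamma shape) parameter.
#' @param fecundity_shift Optional named per-genotype log-scale fecundity
#'   shifts.
#' @param sites Site labels (first factor of the environment grid).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genotypes = 517,
                             pots_per_genotype = 5,
                             seeds_per_pot_high = 30,
                             seeds_sown_low = 10,
                             germination = 0.8,
                             survival_prior = list(highwater = c(30, 10),
                                                   lowwater = c(2, 3)),
                             fecundity_mean = 100,
                             fecundity_size = 4,
                             fecundity_shift = NULL,
                             sites = c("madrid", "tuebingen")) {
  check_positive(c(n_genotypes, pots_per_genotype, seeds_per_pot_high,
                   seeds_sown_low, fecundity_mean, fecundity_size),
                 "counts and fecundity parameters")
  check_prob(germination, "germination", open_left = TRUE)
  if (seeds_sown_low < 1) stop_domain("cannot thin to 1 from < 1 sown seed")
  for (w in names(survival_prior)) {
    check_positive(survival_prior[[w]], paste0("Beta parameters (", w, ")"))
  }
  structure(list(n_genotypes = n_genotypes,
                 pots_per_genotype = pots_per_genotype,
                 seeds_per_pot_high = seeds_per_pot_high,
                 seeds_sown_low = seeds_sown_low,
                 germination = germination,
                 survival_prior = survival_prior,
                 fecundity_mean = fecundity_mean,
                 fecundity_size = fecundity_size,
                 fecundity_shift = fecundity_shift,
                 sites = sites),
            class = "synthetic_config")
}

synthetic_environments <- function(config) {
  grid <- expand.grid(site = config$sites,
                      water = names(config$survival_prior),
                      density = c("highdens", "lowdens"),
                      stringsAsFactors = FALSE)
  grid$environment <- paste(grid$site, grid$water, grid$density, sep = "_")
  grid
}

# expected proportion of deaths selective given true rates and equal
# per-genotype denominators
truth_proportion <- function(rates) {
  (max(rates) - mean(rates)) / (1 - mean(rates))
}

#' Generate a synthetic cohort table with known truth
#'
#' Simulates the full design of [synthetic_config()]: per environment, each
#' genotype's true seedling-to-adult survival is drawn from the water-level
#' Beta prior; germination is binomial at a shared rate; adults are binomial
#' in the retained seedlings at the genotype rate; and per-survivor seed
#' output is negative binomial. At high density the realized seed-to-adult
#' survival (the quantity the pipeline estimates there) is germination times
#' seedling survival.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed; identical `(config, seed)` pairs generate
#'   identical tables.
#' @return A list with `table` (a validated `cohort_table`) and `truth`, a
#'   list holding the seed, per-environment true survival rates (at the
#'   transition the pipeline scores in that environment), the true proportion
#'   of deaths selective, and the true per-pot reproductive excess of the
#'   seed and seedling transitions at the configured fecundity (reported at
#'   dispersal survival 0.1 and 1).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  envs <- synthetic_environments(config)
  genotypes <- sprintf("g%03d", seq_len(config$n_genotypes))
  shift <- rep(0, config$n_genotypes)
  names(shift) <- genotypes
  if (!is.null(config$fecundity_shift)) {
    shift[names(config$fecundity_shift)] <- config$fecundity_shift
  }
  with_seed(seed, {
    tables <- list()
    truth_envs <- list()
    for (e in seq_len(nrow(envs))) {
      env <- envs$environment[e]
      prior <- config$survival_prior[[envs$water[e]]]
      u <- stats::rbeta(config$n_genotypes, prior[1], prior[2])
      g <- config$germination
      pots <- config$pots_per_genotype
      high <- envs$density[e] == "highdens"
      rows <- vector("list", config$n_genotypes)
      for (i in seq_len(config$n_genotypes)) {
        mu <- config$fecundity_mean * exp(shift[i])
        if (high) {
          sown <- config$seeds_per_pot_high
          germ <- stats::rbinom(pots, sown, g)
          adults <- stats::rbinom(pots, germ, u[i])
          retained <- germ
        } else {
          sown <- config$seeds_sown_low
          germ <- stats::rbinom(pots, sown, g)
          retained <- pmin(germ, 1L)
          adults <- stats::rbinom(pots, retained, u[i])
        }
        seeds_out <- integer(pots)
        has_adults <- adults > 0
        if (any(has_adults)) {
          seeds_out[has_adults] <- stats::rnbinom(
            sum(has_adults),
            mu = adults[has_adults] * mu,
            size = adults[has_adults] * config$fecundity_size)
        }
        rows[[i]] <- tibble::tibble(genotype = genotypes[i],
                                    environment = env,
                                    pot = seq_len(pots),
                                    seeds_planted = as.integer(sown),
                                    seedlings_retained = as.integer(retained),
                                    adults = as.integer(adults),
                                    seeds_produced = as.integer(seeds_out))
      }
      tables[[env]] <- dplyr::bind_rows(rows)
      # truth at the transition the pipeline scores in this environment
      rates <- if (high) g * u else u
      names(rates) <- genotypes
      truth_envs[[env]] <- list(
        density = if (high) "high" else "low",
        true_rates = rates,
        prop_selective = truth_proportion(rates),
        reproductive_excess = truth_reproductive_excess(config, u, g, high))
    }
    table <- validate_cohort(dplyr::bind_rows(tables))
    list(table = table,
         truth = list(seed = seed, config = config,
                      environments = truth_envs))
  })
}

# Expected per-pot reproductive excess under the true parameters, for the
# seed (focal: reproduction) and seedling (focal: establishment) transitions,
# best-genotype mode, at the two ends of the dispersal-survival range.
truth_reproductive_excess <- function(config, u, g, high,
                                      dispersal = c(0.1, 1)) {
  if (high) {
    seedlings_pp <- config$seeds_per_pot_high * g
  } else {
    seedlings_pp <- 1 - (1 - g)^config$seeds_sown_low
  }
  adults_pp <- seedlings_pp * mean(u)
  seeds_pp <- adults_pp * config$fecundity_mean
  u_best <- max(u)
  re_seeds <- seeds_pp - adults_pp / (dispersal * g * u_best)
  re_seedlings <- seedlings_pp - adults_pp / u_best
  list(seeds = re_seeds, seedlings = rep(re_seedlings, 2))
}

#' A tiny hand-checkable cohort fixture
#'
#' Two genotypes in one low-density environment, 100 single-seedling pots
#' each: genotype `a` has 90 surviving adults out of 100 and genotype `b` 50
#' of 100, and every survivor sets 100 seeds. The raw proportion of deaths
#' selective is therefore `(100*(0.9-0.9) + 100*(0.9-0.5)) /
#' (100*(1-0.9) + 100*(1-0.5)) = 40/60 = 2/3` - small enough to verify by
#' hand, and the committed reference case for the pipeline.
#'
#' @return A validated `cohort_table` (deterministic; no RNG).
#' @examples
#' tab <- worked_fixture()
#' est <- estimate_survival(tab, "toy_lowdens", density = "low")
#' proportion_selective_deaths(est$rate, est$denominator) # 2/3
#' @export
worked_fixture <- function() {
  survivors <- c(a = 90, b = 50)
  rows <- lapply(names(survivors), function(gt) {
    adult <- rep(c(1L, 0L), c(survivors[[gt]], 100L - survivors[[gt]]))
    tibble::tibble(genotype = gt, environment = "toy_lowdens",
                   pot = seq_len(100L), seeds_planted = 10L,
                   seedlings_retained = 1L, adults = adult,
                   seeds_produced = 100L * adult)
  })
  validate_cohort(dplyr::bind_rows(rows))
}
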