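# Empirical pipeline: from genotype x environment cohort tables to the
# proportion of deaths that are selective and per-transition reproductive
# excess, with an extreme-value (winner's curse) bias adjustment and a
# permutation gate on fecundity differences.

#' Per-genotype survival rates in one environment
#'
#' Pools counts across pots (sums of numerators and denominators - the
#' minimum-variance binomial estimator for equal-design replicate pots) and
#' returns each genotype's survival over the transition selection is scored
#' on: seed to adult at high density (denominator: seeds planted), seedling
#' to adult at low density (denominator: retained seedlings, so seed-stage
#' deaths are excluded by design there).
#'
#' @param table A `cohort_table`.
#' @param environment Environment id present in the table.
#' @param density `"high"` or `"low"`; inferred from the environment label
#'   when `NULL` (see [infer_density()]).
#' @return Tibble with `genotype`, `adults`, `denominator`, `rate`, sorted by
#'   genotype. Genotypes with a zero denominator are dropped with a warning.
#' @export
estimate_survival <- function(table, environment, density = NULL) {
  rows <- table[table$environment == environment, , drop = FALSE]
  if (nrow(rows) == 0) stop_domain("environment not present: ", environment)
  density <- density %||% infer_density(environment)
  if (is.na(density) || !density %in% c("high", "low")) {
    stop_domain("density for '", environment,
                "' is neither given nor encoded in the label")
  }
  denom_col <- if (density == "high") "seeds_planted" else "seedlings_retained"
  agg <- dplyr::summarise(dplyr::group_by(rows, genotype),
                          adults = sum(adults),
                          denominator = sum(.data[[denom_col]]),
                          .groups = "drop")
  zero <- agg$denominator == 0
  if (any(zero)) {
    warning(sum(zero), " genotype(s) excluded from '", environment,
            "' (zero denominator)", call. = FALSE)
    agg <- agg[!zero, , drop = FALSE]
  }
  if (nrow(agg) < 2) {
    stop_domain("need at least 2 genotypes with nonzero denominators in '",
                environment, "'")
  }
  agg$rate <- agg$adults / agg$denominator
  dplyr::arrange(agg, genotype)
}

#' Proportion of deaths that are selective
#'
#' Of all deaths observed over the scored transition, the fraction that a
#' genotype would have avoided had it been the best genotype present:
#' `sum_i d_i (r_best - r_i) / sum_i d_i (1 - r_i)`, with `d_i` the
#' denominators and `r_best` the maximum observed rate (or a bias-adjusted
#' replacement for it, in which case the value may be slightly negative -
#' callers report `max(0, .)`).
#'
#' @param rates Per-genotype survival rates.
#' @param denominators Per-genotype trial counts.
#' @param r_best Best-genotype survival; defaults to `max(rates)`.
#' @return The proportion (in `[0, 1]` when `r_best = max(rates)`), or `NA`
#'   with a warning when no deaths occurred (the quantity is undefined, not
#'   zero).
#' @examples
#' proportion_selective_deaths(c(0.9, 0.5), c(100, 100)) # 2/3
#' @export
proportion_selective_deaths <- function(rates, denominators,
                                        r_best = max(rates)) {
  if (length(rates) < 2) stop_domain("need at least 2 genotypes")
  if (length(rates) != length(denominators)) {
    stop_domain("rates and denominators must have the same length")
  }
  check_prob(rates, "rates")
  check_positive(denominators, "denominators", strict = FALSE)
  deaths <- sum(denominators * (1 - rates))
  if (deaths <= 0) {
    warning("no deaths in this environment: proportion selective undefined",
            call. = FALSE)
    return(NA_real_)
  }
  sum(denominators * (r_best - rates)) / deaths
}

#' Extreme-value (winner's curse) adjustment of the best survival rate
#'
#' The maximum of hundreds of noisy survival estimates overstates the true
#' best genotype's survival, inflating the apparent proportion of selective
#' deaths. This adjustment estimates the inflation by parametric bootstrap
#' and subtracts it from the observed maximum.
#'
#' The default (`method = "deconvolution"`) proceeds in three steps. (1) A
#' pooled-binomial homogeneity pretest: if the among-genotype chi-square is
#' consistent with one shared rate at level `alpha`, the simulated truth is
#' flat at the pooled mean. (2) Otherwise the true among-genotype variance is
#' estimated by moments (observed weighted variance minus mean binomial
#' sampling variance) and the rate profile is linearly shrunk toward the
#' pooled mean to match it. Bootstrapping from the raw estimates themselves
#' would rebuild the winner's curse into the simulated truth and underestimate
#' the inflation, defeating the adjustment; the deconvolution step is what
#' makes the null case come out near zero. (3) `B` parametric replicates are
#' drawn binomially from the shrunken profile at the observed denominators;
#' the inflation is the mean simulated maximum minus the maximum of the
#' simulated truth, and is subtracted from the observed maximum (clamped to
#' `[0, 1]`).
#'
#' The adjusted proportion is recomputed with the adjusted `r_best` and
#' returned *signed*: under a true null it is centred at zero, so it can dip
#' slightly negative; [run_all()] clamps it to `[0, prop_raw]` for reporting.
#'
#' @param rates Per-genotype survival rates (point estimates).
#' @param denominators Per-genotype trial counts.
#' @param B Number of bootstrap replicates (`>= 100`).
#' @param seed Optional seed for the bootstrap (restores the caller's RNG
#'   stream afterwards).
#' @param alpha Level of the homogeneity pretest.
#' @param method Adjustment strategy; only `"deconvolution"` is built in, but
#'   the argument names the slot where an alternative (e.g. an exact
#'   replication of some published procedure) can be registered.
#' @return List with `r_best_observed`, `r_best_adjusted`, `inflation`,
#'   `p_homogeneity`, `prop_raw`, `prop_adjusted` (signed), `B`, `method`.
#' @examples
#' est <- estimate_survival(worked_fixture(), "toy_lowdens", "low")
#' adjust_extreme_value(est$rate, est$denominator, B = 200, seed = 1)
#' @export
adjust_extreme_value <- function(rates, denominators, B = 1000, seed = NULL,
                                 alpha = 0.05, method = "deconvolution") {
  method <- match.arg(method, "deconvolution")
  if (B < 100) stop_domain("B must be >= 100")
  check_prob(rates, "rates")
  check_positive(denominators, "denominators")
  G <- length(rates)
  r_best <- max(rates)
  prop_raw <- if (G < 2) NA_real_ else suppressWarnings(
    proportion_selective_deaths(rates, denominators))
  base <- list(r_best_observed = r_best, r_best_adjusted = r_best,
               inflation = 0, p_homogeneity = NA_real_,
               prop_raw = prop_raw, prop_adjusted = prop_raw,
               B = B, method = method)
  rbar <- sum(rates * denominators) / sum(denominators)
  # degenerate cases: nothing to adjust
  if (G < 2 || is.na(prop_raw) || rbar %in% c(0, 1)) return(base)
  X2 <- sum(denominators * (rates - rbar)^2) / (rbar * (1 - rbar))
  p_hom <- stats::pchisq(X2, df = G - 1, lower.tail = FALSE)
  if (p_hom >= alpha) {
    truth <- rep(rbar, G)
  } else {
    v_obs <- sum(denominators * (rates - rbar)^2) / sum(denominators)
    v_noise <- mean(rates * (1 - rates) / denominators)
    v_true <- max(0, v_obs - v_noise)
    shrink <- if (v_obs > 0) sqrt(v_true / v_obs) else 0
    truth <- pmin(1, pmax(0, rbar + shrink * (rates - rbar)))
  }
  with_seed(seed, {
    sims <- matrix(stats::rbinom(G * B, denominators, truth),
                   nrow = G) / denominators
    inflation <- mean(apply(sims, 2, max)) - max(truth)
  })
  r_adj <- min(1, max(0, r_best - inflation))
  prop_adj <- suppressWarnings(
    proportion_selective_deaths(rates, denominators, r_best = r_adj))
  base$r_best_adjusted <- r_adj
  base$inflation <- inflation
  base$p_homogeneity <- p_hom
  base$prop_adjusted <- prop_adj
  base
}

#' Permutation gate on genotype fecundity differences
#'
#' Tests for among-genotype differences in per-survivor seed set by freely
#' permuting genotype labels across pots (with surviving adults) and
#' comparing the pot-weighted among-genotype variance of mean per-survivor
#' seed counts to its permutation distribution. If the differences are not
#' significant at `alpha`, fecundity selective deaths are set to zero;
#' otherwise they are `N_i (b_best - b_i)` with `N_i` the genotype's
#' surviving adults and `b_i` its pooled per-survivor seed count.
#'
#' @param table A `cohort_table`.
#' @param environment Environment id.
#' @param alpha Significance level of the gate (`alpha = 1` disables it:
#'   always significant).
#' @param n_perm Number of permutations (`>= 1000` recommended).
#' @param seed Optional seed (RNG stream restored afterwards).
#' @return List with `significant`, `p_value`, `fecundity` (per-genotype
#'   pooled per-survivor seed counts), `deaths` (per-genotype fecundity
#'   selective deaths; zero when the gate does not pass) and `total_deaths`.
#'   When no pot has survivors the gate is skipped with a warning.
#' @export
fecundity_gate <- function(table, environment, alpha = 0.05, n_perm = 1000,
                           seed = NULL) {
  rows <- table[table$environment == environment & table$adults > 0, ,
                drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no surviving adults in '", environment,
            "': fecundity gate skipped", call. = FALSE)
    return(list(significant = NA, p_value = NA_real_,
                fecundity = numeric(0), deaths = numeric(0),
                total_deaths = 0))
  }
  y <- rows$seeds_produced / rows$adults
  gt <- rows$genotype
  pooled <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(genotype = gt,
                                   seeds = rows$seeds_produced,
                                   adults = rows$adults), genotype),
    b = sum(seeds) / sum(adults), n_adults = sum(adults), .groups = "drop")
  stat <- function(labels) {
    means <- tapply(y, labels, mean)
    counts <- tabulate(factor(labels, levels = names(means)))
    sum(counts * (means - mean(y))^2)
  }
  if (length(unique(gt)) < 2) {
    warning("fewer than 2 genotypes with survivors in '", environment,
            "': fecundity gate skipped", call. = FALSE)
    p <- NA_real_
    significant <- NA
  } else {
    obs <- stat(gt)
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat(sample(gt)), 0)
    })
    p <- (1 + sum(perm >= obs)) / (1 + n_perm)
    significant <- p <= alpha
  }
  deaths <- if (isTRUE(significant)) {
    fecundity_selective_deaths(pooled$n_adults, pooled$b)
  } else {
    rep(0, nrow(pooled))
  }
  names(deaths) <- pooled$genotype
  b <- stats::setNames(pooled$b, pooled$genotype)
  list(significant = significant, p_value = p, fecundity = b,
       deaths = deaths, total_deaths = sum(deaths))
}

#' Per-pot reproductive excess of the seed and seedling transitions
#'
#' Builds the observed life cycle of one environment - adults set seeds
#' (reproduction), seeds survive dispersal at an assumed rate, dispersed
#' seeds germinate and establish as seedlings, seedlings survive (selectively)
#' to adulthood - and applies [reproductive_excess()] in best-genotype mode
#' to two focal transitions: seed production and seedling establishment. All
#' quantities are normalized per pot. Dispersal survival is unobserved in a
#' pot experiment, so the excess of seeds is reported over an assumed
#' `(low, high)` range (default spanning 10-fold); the seedling excess does
#' not depend on it. The seedling stage is set by the planting design (at
#' most 1 retained seedling per pot at low density, at most 30 at high), so
#' the seedling excess respects those caps structurally.
#'
#' @param table A `cohort_table`.
#' @param environment Environment id.
#' @param density `"high"`/`"low"`; inferred from the label when `NULL`.
#' @param dispersal_survival Length-2 numeric, `0 < low <= high <= 1`.
#' @param r_best Optional override for the best seedling-to-adult survival
#'   (e.g. a bias-adjusted value); defaults to the best observed.
#' @return Tibble with one row per transition (`"seeds"`, `"seedlings"`) and
#'   columns `re_low`, `re_high` (per pot, at the low and high end of the
#'   dispersal range).
#' @export
empirical_reproductive_excess <- function(table, environment, density = NULL,
                                          dispersal_survival = c(0.1, 1),
                                          r_best = NULL) {
  rows <- table[table$environment == environment, , drop = FALSE]
  if (nrow(rows) == 0) stop_domain("environment not present: ", environment)
  density <- density %||% infer_density(environment)
  if (length(dispersal_survival) != 2 ||
      dispersal_survival[1] > dispersal_survival[2]) {
    stop_domain("dispersal_survival must be (low, high) with low <= high")
  }
  check_prob(dispersal_survival, "dispersal_survival", open_left = TRUE)
  n_pots <- nrow(rows)
  adults_pp <- sum(rows$adults) / n_pots
  seeds_pp <- sum(rows$seeds_produced) / n_pots
  seedlings_pp <- sum(rows$seedlings_retained) / n_pots
  planted_pp <- sum(rows$seeds_planted) / n_pots
  if (adults_pp == 0 || seedlings_pp == 0) {
    stop_domain("environment '", environment,
                "' has no adults or no seedlings; life cycle undefined")
  }
  # seedling -> adult survival per genotype (the selective transition of the
  # cycle; at high density the scored seed->adult rate is germination times
  # this)
  per_gt <- dplyr::summarise(dplyr::group_by(rows, genotype),
                             adults = sum(adults),
                             seedlings = sum(seedlings_retained),
                             .groups = "drop")
  per_gt <- per_gt[per_gt$seedlings > 0 & per_gt$adults > 0, , drop = FALSE]
  if (nrow(per_gt) == 0) {
    stop_domain("no genotype with surviving adults in '", environment, "'")
  }
  # genotypes with zero survivors would need k = 0; they carry no weight in
  # best-genotype mode and the realized per-pot outputs already include them,
  # so they are omitted from the cycle's survival multipliers
  k_s <- pmin(1, per_gt$adults / per_gt$seedlings)
  names(k_s) <- per_gt$genotype
  if (!is.null(r_best)) k_s[which.max(k_s)] <- min(1, r_best)
  b <- seeds_pp / adults_pp           # per-survivor fecundity (nonselective)
  k_g <- seedlings_pp / planted_pp    # germination + design thinning
  freqs <- stats::setNames(rep(1 / length(k_s), length(k_s)), names(k_s))
  re_at <- function(k_d) {
    cycle <- life_cycle(list(
      transition("reproduction", "reproduction", b),
      transition("dispersal", "survival", k_d),
      transition("establishment", "survival", min(1, k_g)),
      transition("survival", "survival", k_s)),
      n0 = adults_pp, frequencies = freqs)
    c(seeds = reproductive_excess(cycle, 1, "best",
                                  realized_output = seeds_pp),
      seedlings = reproductive_excess(cycle, 3, "best",
                                      realized_output = seedlings_pp))
  }
  lo <- re_at(dispersal_survival[1])
  hi <- re_at(dispersal_survival[2])
  tibble::tibble(transition = c("seeds", "seedlings"),
                 re_low = unname(pmin(lo, hi)),
                 re_high = unname(pmax(lo, hi)))
}

#' Pipeline configuration
#'
#' @param dispersal_survival `(low, high)` assumed seed survival during
#'   dispersal; the default spans a 10-fold range.
#' @param B Bootstrap replicates for [adjust_extreme_value()].
#' @param alpha Significance level shared by the fecundity gate and the
#'   homogeneity pretest.
#' @param n_perm Permutations for [fecundity_gate()].
#' @param seed Master seed; per-environment analyses draw child seeds from it
#'   so reruns are reproducible.
#' @param density_map Optional named `"high"`/`"low"` vector by environment;
#'   inferred from labels when absent.
#' @param use_adjusted_r_best Use the bias-adjusted best survival also inside
#'   the reproductive-excess cycle (default `FALSE`: raw).
#' @return List of class `empirical_config`.
#' @export
empirical_config <- function(dispersal_survival = c(0.1, 1), B = 1000,
                             alpha = 0.05, n_perm = 1000, seed = 1,
                             density_map = NULL,
                             use_adjusted_r_best = FALSE) {
  structure(list(dispersal_survival = dispersal_survival, B = B,
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 density_map = density_map,
                 use_adjusted_r_best = use_adjusted_r_best),
            class = "empirical_config")
}

#' Run the full selective-deaths analysis on a cohort table
#'
#' For every environment in the table: estimate per-genotype survival over
#' the scored transition, compute the raw proportion of deaths that are
#' selective, adjust it for extreme-value bias, gate fecundity differences by
#' permutation, and compute per-pot reproductive excess of the seed and
#' seedling transitions over the assumed dispersal-survival range. Failures
#' in one environment are caught and reported without aborting the others.
#'
#' @param table A `cohort_table`.
#' @param config An [empirical_config()].
#' @return List with `summary` (tibble, one row per environment:
#'   `environment`, `transition_scope`, `n_genotypes`, `best_genotype` -
#'   lexicographically first among ties - `prop_selective_raw`,
#'   `prop_selective_adjusted` (clamped to `[0, raw]`), `re_seeds_low/high`,
#'   `re_seedlings_low/high`, `fecundity_significant`, `fecundity_p`),
#'   `details` (per-environment component results) and `problems` (named
#'   character vector of per-environment errors, if any).
#' @export
run_all <- function(table, config = empirical_config()) {
  stopifnot(inherits(config, "empirical_config"))
  envs <- sort(unique(table$environment))
  details <- list()
  problems <- character()
  rows <- list()
  for (i in seq_along(envs)) {
    env <- envs[i]
    res <- tryCatch({
      density <- (config$density_map %||% c())[env] %||% NA_character_
      if (is.na(density)) density <- infer_density(env)
      est <- estimate_survival(table, env, density)
      adj <- adjust_extreme_value(est$rate, est$denominator, B = config$B,
                                  seed = child_seed(config$seed, 2L * i),
                                  alpha = config$alpha)
      gate <- fecundity_gate(table, env, alpha = config$alpha,
                             n_perm = config$n_perm,
                             seed = child_seed(config$seed, 2L * i + 1L))
      re <- empirical_reproductive_excess(
        table, env, density, config$dispersal_survival,
        r_best = if (config$use_adjusted_r_best) adj$r_best_adjusted)
      best <- min(est$genotype[est$rate == max(est$rate)])
      prop_adj <- if (is.na(adj$prop_adjusted)) NA_real_ else {
        min(max(adj$prop_adjusted, 0), adj$prop_raw)
      }
      list(estimate = est, adjust = adj, gate = gate,
           reproductive_excess = re,
           summary = tibble::tibble(
             environment = env,
             transition_scope = if (density == "high") "seed_to_adult" else
               "seedling_to_adult",
             n_genotypes = nrow(est),
             best_genotype = best,
             prop_selective_raw = adj$prop_raw,
             prop_selective_adjusted = prop_adj,
             re_seeds_low = re$re_low[re$transition == "seeds"],
             re_seeds_high = re$re_high[re$transition == "seeds"],
             re_seedlings_low = re$re_low[re$transition == "seedlings"],
             re_seedlings_high = re$re_high[re$transition == "seedlings"],
             fecundity_significant = gate$significant,
             fecundity_p = gate$p_value))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      problems[env] <- conditionMessage(res)
    } else {
      details[[env]] <- res
      rows[[env]] <- res$summary
    }
  }
  list(summary = dplyr::bind_rows(rows), details = details,
       problems = problems)
}
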