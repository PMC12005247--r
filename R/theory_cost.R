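#' Parameters of a single selective sweep
#'
#' Bundles the quantities that determine the cost of one substitution: the
#' initial frequency `p0` of the beneficial allele, its selection coefficient
#' `s`, the genetic model, and (optionally) the census size `N` at the stage
#' where selection acts.
#'
#' Two models are implemented. `"haploid"` is the classical case where
#' carriers of the old allele suffer `s` extra deaths per capita, so the
#' population pays `s(1-p)N` selective deaths per generation. In
#' `"diploid_genic"` the three genotypes have fitnesses 1, 1-s, 1-2s
#' (beneficial homozygote, heterozygote, wild-type homozygote), which doubles
#' the per-capita cost to `2s(1-p)` because each individual carries two
#' alleles. Other dominance schemes (dominant, recessive, inbred) are
#' recognised but not implemented.
#'
#' @param p0 Initial allele frequency, `0 < p0 < 1`.
#' @param s Selection coefficient, `0 < s < 1`.
#' @param model `"haploid"` or `"diploid_genic"`.
#' @param N Census population size at the selected stage (`>= 1`), used when
#'   converting per-capita costs to total selective deaths.
#' @return An object of class `sweep_params`.
#' @examples
#' sweep_params(1e-4, 0.01, "diploid_genic")
#' @export
sweep_params <- function(p0, s, model = c("haploid", "diploid_genic",
                                           "diploid_dominant",
                                           "diploid_recessive", "inbred"),
                         N = NULL) {
  model <- match.arg(model)
  if (model %in% c("diploid_dominant", "diploid_recessive", "inbred")) {
    stop_domain("model '", model, "' is not implemented; ",
                "use 'haploid' or 'diploid_genic'")
  }
  check_prob(p0, "p0", open_left = TRUE, open_right = TRUE)
  check_prob(s, "s", open_left = TRUE, open_right = TRUE)
  if (!is.null(N)) check_positive(N, "N")
  structure(list(p0 = p0, s = s, model = model, N = N),
            class = "sweep_params")
}

#' @export
print.sweep_params <- function(x, ...) {
  cat("Selective sweep: p0 =", format(x$p0), ", s =", format(x$s),
      ", model =", x$model,
      if (!is.null(x$N)) paste(", N =", format(x$N)) else "", "\n")
  invisible(x)
}

# per-capita selective death rate at frequency p, by model
percapita_cost_rate <- function(p, s, model) {
  switch(model,
         haploid       = s * (1 - p),
         diploid_genic = 2 * s * (1 - p),
         stop_domain("model '", model, "' is not implemented"))
}

#' Selective deaths incurred in one generation
#'
#' The number of deaths in one generation that causally contribute to the
#' increase of a beneficial allele at frequency `p`: the `(1-p)N` individuals
#' lacking the allele each expect `s` more deaths than carriers, giving
#' `s(1-p)N`.
#'
#' @param p Current allele frequency in `[0, 1]`.
#' @param s Selection coefficient, `0 < s < 1`.
#' @param N Census size at the selected stage.
#' @return Selective deaths this generation (individuals, `>= 0`).
#' @examples
#' instantaneous_cost(0.5, 0.02, 1e4) # 100
#' @export
instantaneous_cost <- function(p, s, N) {
  check_prob(p, "p")
  check_prob(s, "s", open_left = TRUE, open_right = TRUE)
  check_positive(N, "N")
  s * (1 - p) * N
}

#' Cost of selection for one substitution
#'
#' Integrates per-capita selective deaths along the deterministic sweep
#' trajectory `dp/dt = s p (1 - p)` from `p0` to `p_end`, returning Haldane's
#' `D`: cumulative selective deaths per head of population, in units of `N`.
#' For the haploid model the integrand is `s(1-p)`, and the change of
#' variables to frequency gives `D = integral dp / p = ln(p_end/p0)`, i.e.
#' `-ln(p0)` up to terms of order `p0`; for the diploid genic model the
#' per-capita rate doubles, giving `-2 ln(p0)` (18.4 for `p0 = 1e-4`). In this
#' continuous-time parameterization the selection coefficient cancels, which
#' is why `D` is nearly independent of `s` unless `s` is close to 1.
#'
#' @param params A [sweep_params()] object.
#' @param p_end Frequency at which the sweep is deemed complete. Defaults to
#'   `1 - p0` (symmetric truncation; the neglected tail is `O(p0)`); for a
#'   sweep already past 1/2 the default is halfway to fixation,
#'   `(1 + p0) / 2`.
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return `D`, selective deaths per capita (dimensionless). Multiply by `N`
#'   for total selective deaths.
#' @examples
#' cost_per_sweep(sweep_params(1e-4, 0.01, "haploid"))       # ~9.21
#' cost_per_sweep(sweep_params(1e-4, 0.01, "diploid_genic")) # ~18.4
#' @export
cost_per_sweep <- function(params, p_end = NULL, rel_tol = 1e-8) {
  stopifnot(inherits(params, "sweep_params"))
  p0 <- params$p0
  s <- params$s
  p_end <- p_end %||% (if (p0 < 0.5) 1 - p0 else (1 + p0) / 2)
  if (p_end <= p0 || p_end >= 1) {
    stop_domain("p_end must lie in (p0, 1)")
  }
  # time integral of the per-capita rate, with dt = dp / (s p (1-p))
  integrand <- function(p) {
    percapita_cost_rate(p, s, params$model) / (s * p * (1 - p))
  }
  res <- tryCatch(
    stats::integrate(integrand, lower = p0, upper = p_end,
                     rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) {
      stop_domain("sweep cost integration failed (p0 = ", format(p0),
                  ", p_end = ", format(p_end), "): ", conditionMessage(e))
    })
  if (res$message != "OK") {
    stop_domain("sweep cost integration did not converge: ", res$message)
  }
  res$value
}

#' A set of concurrently segregating sweeps
#'
#' Describes `x` independently sweeping loci by their current frequencies
#' `p` and selection coefficients `s`. Each locus depresses mean fitness by a
#' factor `1 - d_i` with `d_i = s_i (1 - p_i)` relative to the post-sweep
#' population.
#'
#' @param p Numeric vector of current allele frequencies in `[0, 1]`.
#' @param s Numeric vector of selection coefficients (recycled if scalar).
#' @return An object of class `sweep_set` with fields `p`, `s`, `d`, and the
#'   locus count `x`.
#' @export
sweep_set <- function(p, s) {
  if (length(p) == 0) stop_domain("sweep_set needs at least one locus")
  check_prob(p, "p")
  check_prob(s, "s", open_left = TRUE, open_right = TRUE)
  s <- rep_len(s, length(p))
  structure(list(p = p, s = s, d = s * (1 - p), x = length(p)),
            class = "sweep_set")
}

#' Mean fitness relative to the post-sweep population
#'
#' With independent loci, a population mid-sweep has mean fitness lower than
#' the eventual post-sweep population by the exact factor `prod(1 - d_i)`,
#' commonly approximated by `exp(-sum d_i)`.
#'
#' @param sweeps A [sweep_set()].
#' @return A list with `exact` (the product), `approx` (the exponential
#'   approximation) and `sum_d`.
#' @examples
#' multi_locus_fitness_factor(sweep_set(p = c(0.5, 0.5), s = 0.1))
#' @export
multi_locus_fitness_factor <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  list(exact = prod(1 - sweeps$d),
       approx = exp(-sum(sweeps$d)),
       sum_d = sum(sweeps$d))
}

#' Haldane's selection intensity
#'
#' `I = ln(s_o / S)`: the log-ratio of the survival of the best genotype
#' present (`s_o`) to mean survival (`S`). Haldane's assumed long-term cap
#' was `I = 0.1`.
#'
#' @param s_o Survival probability of the best genotype, `0 < s_o <= 1`.
#' @param S Mean survival probability, `0 < S <= s_o`.
#' @return Selection intensity in nats (`>= 0`).
#' @examples
#' selection_intensity(0.9, 0.6) # log(1.5)
#' @export
selection_intensity <- function(s_o, S) {
  check_prob(s_o, "s_o", open_left = TRUE)
  check_prob(S, "S", open_left = TRUE)
  if (S > s_o) {
    stop_domain("mean survival S cannot exceed best-genotype survival s_o")
  }
  log(s_o / S)
}

#' Lag load and lead
#'
#' Both loads are normalized fitness differences. The lag load compares the
#' population mean to a (possibly hypothetical) optimal genotype,
#' `(w_opt - w_mean) / w_opt`; the lead compares it to the best genotype
#' actually present, normalized by the mean: `(w_opt - w_mean) / w_mean`.
#'
#' @param w_opt Reference (optimal or best-present) fitness, `> 0`.
#' @param w_mean Mean population fitness, `0 < w_mean <= w_opt`.
#' @return An object of class `load_summary`: list with `w_opt`, `w_mean`,
#'   `lag_load`, `lead`.
#' @examples
#' loads(1, 0.9) # lag 0.1, lead ~0.111
#' @export
loads <- function(w_opt, w_mean) {
  check_positive(w_opt, "w_opt")
  check_positive(w_mean, "w_mean")
  if (w_mean > w_opt) stop_domain("w_mean cannot exceed w_opt")
  structure(list(w_opt = w_opt, w_mean = w_mean,
                 lag_load = (w_opt - w_mean) / w_opt,
                 lead = (w_opt - w_mean) / w_mean),
            class = "load_summary")
}

#' @export
print.load_summary <- function(x, ...) {
  cat("lag load:", format(x$lag_load), "  lead:", format(x$lead), "\n")
  invisible(x)
}

#' Selective "deaths" from differential fecundity
#'
#' Foregone offspring are mathematically equivalent to deaths immediately
#' after reproduction. Each genotype `i` with `N_i` reproductive adults and
#' fecundity `b_i` incurs `N_i (b_best - b_i)` selective deaths, where
#' `b_best` is the highest fecundity among genotypes present.
#'
#' @param N_i Adult counts per genotype (`>= 0`).
#' @param b_i Fecundity per adult per genotype (`>= 0`).
#' @return Per-genotype selective deaths (same names/order as input); zero for
#'   the best genotype.
#' @examples
#' fecundity_selective_deaths(c(10, 10), c(5, 3)) # 0, 20
#' @export
fecundity_selective_deaths <- function(N_i, b_i) {
  if (length(N_i) == 0) stop_domain("empty genotype list")
  if (length(N_i) != length(b_i)) {
    stop_domain("N_i and b_i must have the same length")
  }
  check_positive(N_i, "N_i", strict = FALSE)
  check_positive(b_i, "b_i", strict = FALSE)
  out <- N_i * (max(b_i) - b_i)
  names(out) <- names(b_i) %||% names(N_i)
  out
}
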