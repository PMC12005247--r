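# Speed limits: minimum spacings between selective sweeps implied by the
# cost of selection and a finite budget of reproductive excess or intensity.

#' Haldane's spacing between sweeps
#'
#' Given a total cost per sweep of `D_total` (selective deaths in units of
#' `N`) and a sustainable cap `I_max` on selection intensity per generation,
#' sweeps must be spaced at least `n = D_total / I_max` generations apart.
#' Haldane's numbers were `D_total = 30` and `I_max = 0.1`, giving 300.
#'
#' @param cost_per_sweep Total per-sweep cost in units of `N` (`> 0`).
#' @param I_max Maximum selection intensity per generation (`> 0`).
#' @return Minimum generations between sweeps.
#' @examples
#' haldane_spacing(30, 0.1) # 300
#' @export
haldane_spacing <- function(cost_per_sweep, I_max) {
  check_positive(cost_per_sweep, "cost_per_sweep")
  check_positive(I_max, "I_max")
  cost_per_sweep / I_max
}

#' Nei/Felsenstein spacing from finite reproductive excess
#'
#' With per-adult effective fecundity `k`, the raw reproductive excess of a
#' stationary population is `(k - 1)N` per generation, and the minimum
#' spacing between sweeps starting from frequency `p0` is
#' `n = -ln(p0) / ln(k)`. For `p0 = 1e-4` and `k = 1.1` this gives 97
#' generations.
#'
#' @param p0 Initial allele frequency, `0 < p0 < 1`.
#' @param k Effective fecundity per adult; must exceed 1 or no reproductive
#'   excess is available and adaptation at constant size is impossible.
#' @return List with `generations` (`n`) and `substitutions_per_generation`
#'   (`1/n`).
#' @examples
#' nei_felsenstein_spacing(1e-4, 1.1)
#' @export
nei_felsenstein_spacing <- function(p0, k) {
  check_prob(p0, "p0", open_left = TRUE, open_right = TRUE)
  if (!is.numeric(k) || anyNA(k) || k <= 1) {
    stop_domain("k must exceed 1: with k <= 1 the population has no ",
                "reproductive excess and cannot adapt at constant size")
  }
  n <- -log(p0) / log(k)
  list(generations = n, substitutions_per_generation = 1 / n)
}

#' Haldane's original spacing from selection intensity
#'
#' `n = -ln(p0) / I` with `I = ln(W_max / W_mean)`. With `I = 0.1` and
#' `p0 = 1e-4` this is 92 generations; substituting `I = ln(k)` recovers the
#' Nei/Felsenstein spacing exactly.
#'
#' @param p0 Initial allele frequency, `0 < p0 < 1`.
#' @param I Selection intensity per generation (`> 0`).
#' @return Minimum generations between sweeps.
#' @examples
#' haldane_original_spacing(1e-4, 0.1) # ~92
#' @export
haldane_original_spacing <- function(p0, I) {
  check_prob(p0, "p0", open_left = TRUE, open_right = TRUE)
  check_positive(I, "I")
  -log(p0) / I
}

#' Effective fecundity after extrinsic mortality
#'
#' Nonselective deaths occurring at a fixed rate before selection can be
#' folded into a lower effective fecundity `k_effective = k_raw * survival`.
#' The per-generation budget for selective deaths is then
#' `k_effective - 1`; a negative budget means the population is not viable
#' even without selection.
#'
#' @param k_raw Raw fecundity per adult (`> 0`).
#' @param extrinsic_survival Probability of surviving extrinsic (nonselective)
#'   mortality, in `(0, 1]`.
#' @return List with `k_effective`, `selective_death_budget`
#'   (`k_effective - 1`) and `viable` (logical).
#' @examples
#' effective_k(2, 0.55) # k_effective 1.1
#' @export
effective_k <- function(k_raw, extrinsic_survival) {
  check_positive(k_raw, "k_raw")
  check_prob(extrinsic_survival, "extrinsic_survival", open_left = TRUE)
  ke <- k_raw * extrinsic_survival
  list(k_effective = ke,
       selective_death_budget = ke - 1,
       viable = ke >= 1)
}

#' Expected maximum of N standard normal deviates
#'
#' The expected fitness of the best genotype likely to be present, in standard
#' deviations above the mean, from the statistics of extreme values. Computed
#' by numerical integration of the exact order-statistic expectation
#' `E[max] = integral x N phi(x) Phi(x)^(N-1) dx` for `N <= 1e10`
#' (overflow-safe via log-scale normal tail probabilities), and by the Gumbel
#' asymptotic expansion above that, with location `b = qnorm(1 - 1/N)` and
#' scale `a = 1/(N phi(b))` (the two branches agree to a few 1e-3 SD at the
#' switch point). For `N = 1e6` this is about 4.9 SD.
#'
#' @param N Number of deviates (`>= 2`), up to about `1e12` and beyond.
#' @return Expected maximum in SD units; monotone increasing in `N`.
#' @examples
#' expected_extreme(2)   # 1/sqrt(pi)
#' expected_extreme(1e6) # ~4.86
#' @export
expected_extreme <- function(N) {
  if (!is.numeric(N) || anyNA(N) || N < 2) stop_domain("N must be >= 2")
  if (N <= 1e10) {
    res <- stats::integrate(
      function(x) x * N * stats::dnorm(x) *
        exp((N - 1) * stats::pnorm(x, log.p = TRUE)),
      lower = -Inf, upper = Inf, rel.tol = 1e-10)
    res$value
  } else {
    # Gumbel limit: max ~ b + a G with G standard Gumbel, E[G] = gamma
    b <- stats::qnorm(1 - 1 / N)
    a <- 1 / (N * stats::dnorm(b))
    b + 0.5772156649015329 * a
  }
}

#' Lead-based (Ewens) spacing between sweeps
#'
#' With many simultaneous sweeps, fitness variance is approximately `s/n` and
#' the best genotype present sits about `c = expected_extreme(N)` SD above the
#' mean, so the lead is `c * sqrt(s/n)`. Capping the lead at `lead_cap`
#' (Haldane's 10% applied to the lead rather than the lag load) and solving
#' gives `n = s (c / lead_cap)^2`.
#'
#' @param s Selection coefficient per sweep (`> 0`).
#' @param N Population size (`>= 2`).
#' @param lead_cap Maximum tolerable lead (`> 0`).
#' @return List with `generations`, and the extreme-value constant `c` used.
#' @examples
#' ewens_spacing(0.01, 1e6, 0.1) # n in the low twenties
#' @export
ewens_spacing <- function(s, N, lead_cap) {
  check_positive(s, "s")
  check_positive(lead_cap, "lead_cap")
  cc <- expected_extreme(N)
  list(generations = s * (cc / lead_cap)^2, c = cc)
}
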