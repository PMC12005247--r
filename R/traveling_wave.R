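# The multiple-mutations (traveling wave) regime of asexual adaptation:
# the lead q, the minimum reproductive excess q*s it implies, and the
# proportion of deaths that are selective.

#' Validate traveling-wave parameters
#'
#' @param N Population size (`>= 2`).
#' @param U Beneficial mutation rate per genome per generation, `0 < U < s`.
#' @param s Selection coefficient per mutation, `0 < s < 1` (intended small).
#' @return A list `(N, U, s)`, invisibly classed `tw_params`. Warns (does not
#'   error) when `s/U < 3`, where the model's assumptions break down.
#' @export
traveling_wave_params <- function(N, U, s) {
  if (!is.numeric(N) || anyNA(N) || N < 2) stop_domain("N must be >= 2")
  check_prob(s, "s", open_left = TRUE, open_right = TRUE)
  check_positive(U, "U")
  if (U >= s) {
    stop_domain("requires U < s (clonal-interference regime of validity)")
  }
  if (s / U < 3) {
    warning("s/U < 3: outside the regime where the multiple-mutations ",
            "model is reliable", call. = FALSE)
  }
  structure(list(N = N, U = U, s = s), class = "tw_params")
}

# Steady-state condition for the lead, in units of s. The fittest ("nose")
# class establishes at size ~1/(qs) and must grow to dominance (~N
# individuals) over the q-1 establishment intervals, each of length
# ln(s/U)/(qs), during which its advantage over the mean decays from (q-1)s
# to 0 in steps of s. Summing the growth gives
#   ln(N s) = ((q - 1)/2) ln(s/U).
# Solved by bracketed root-finding; the asymptotic form 2 ln(Ns)/ln(s/U) is
# the initializer and agrees with the root up to the O(1) term.
lead_condition <- function(q, N, U, s) {
  (q - 1) / 2 * log(s / U) - log(N * s)
}

#' Solve for the lead of an adapting asexual population
#'
#' In the multiple-mutations regime, several beneficial mutations segregate
#' concurrently and the fittest class leads the mean by `q` mutations, i.e. a
#' fitness lead of `q*s` (nose fitness `1 + qs` against a mean normalized to
#' 1). The lead determines the minimum reproductive excess the best genotype
#' needs to sustain the wave (`qs`) and the proportion of deaths that are
#' selective, `1 - 1/(1 + qs)`.
#'
#' @param N Population size.
#' @param U Beneficial mutation rate per genome per generation.
#' @param s Selection coefficient per mutation.
#' @param rel_tol Relative tolerance of the root solve.
#' @return An object of class `traveling_wave_solution`: list with `q`,
#'   `lead` (`= qs`), `min_RE` (`= qs`), `prop_selective`, `sweep_rate`, and
#'   the inputs.
#' @examples
#' solve_lead(N = 1e6, U = 1e-3, s = 0.01) # Fig-2-style defaults
#' @export
solve_lead <- function(N, U, s, rel_tol = 1e-10) {
  pars <- traveling_wave_params(N, U, s)
  if (N * s <= 1) {
    stop_domain("requires N*s > 1; increase N or s ",
                "(no established traveling wave below this)")
  }
  q0 <- 2 * log(N * s) / log(s / U) # asymptotic initializer
  lo <- max(1 + 1e-9, q0 / 4)
  hi <- max(q0 * 4, 2)
  grow <- 0
  while (lead_condition(lo, N, U, s) * lead_condition(hi, N, U, s) > 0) {
    lo <- max(1 + 1e-12, lo / 2)
    hi <- hi * 2
    grow <- grow + 1
    if (grow > 60) {
      stop_domain("no root bracketed for the lead; parameters are outside ",
                  "the model's regime (try larger s/U or N)")
    }
  }
  q <- stats::uniroot(lead_condition, c(lo, hi), N = N, U = U, s = s,
                      tol = rel_tol * max(1, q0))$root
  if (q <= 1) {
    warning("q <= 1: outside the multiple-mutations regime", call. = FALSE)
  }
  structure(list(q = q, lead = q * s, min_RE = q * s,
                 prop_selective = proportion_selective(q, s),
                 sweep_rate = sweep_rate(N, U, s),
                 N = N, U = U, s = s),
            class = "traveling_wave_solution")
}

#' @export
print.traveling_wave_solution <- function(x, ...) {
  cat(sprintf(paste0("Traveling wave (N = %.3g, U = %.3g, s = %.3g):\n",
                     "  lead q = %.4f (qs = %.4f)\n",
                     "  minimum reproductive excess = %.4f\n",
                     "  proportion of deaths selective = %.4f\n",
                     "  sweep rate = %.4g substitutions/generation\n"),
              x$N, x$U, x$s, x$q, x$lead, x$min_RE, x$prop_selective,
              x$sweep_rate))
  invisible(x)
}

#' Proportion of deaths that are selective, given the lead
#'
#' The best genotype's reproductive output in excess of replacement is all
#' lost to nonselective deaths; an average individual expects `(1 + qs)` as
#' many offspring deaths over the same interval, the excess being selective.
#' Hence the proportion of deaths that are selective is `1 - 1/(1 + qs)`.
#'
#' @param q Lead in units of `s` (`>= 0`).
#' @param s Selection coefficient (`>= 0`).
#' @return Fraction in `[0, 1)`. Note `1 - 1/(1+x) < x`: the proportion is
#'   always below the minimum reproductive excess `qs`.
#' @examples
#' proportion_selective(10, 0.01) # qs = 0.1 -> ~0.0909
#' @export
proportion_selective <- function(q, s) {
  check_positive(q, "q", strict = FALSE)
  check_positive(s, "s", strict = FALSE)
  1 - 1 / (1 + q * s)
}

#' Rate of beneficial sweeps in asexuals
#'
#' The lead-based substitution rate for de novo beneficial mutations of
#' constant effect, `2 s ln(Ns) / ln^2(s/U)` substitutions per generation.
#'
#' @param N Population size (`Ns >= 1`).
#' @param U Beneficial mutation rate (`U < s`).
#' @param s Selection coefficient.
#' @return Substitutions per generation.
#' @examples
#' sweep_rate(1e6, 1e-3, 0.01) # ~0.0347
#' @export
sweep_rate <- function(N, U, s) {
  check_positive(N, "N")
  check_positive(U, "U")
  check_positive(s, "s")
  if (s / U <= 1) stop_domain("requires s > U")
  if (N * s < 1) stop_domain("requires N*s >= 1")
  2 * s * log(N * s) / log(s / U)^2
}

#' Lead solutions over a parameter grid
#'
#' Sweeps one of `N`, `U`, `s` over a geometric grid (endpoints clipped to
#' keep `s/U >= 3`) with the other two held fixed, solving for the lead at
#' each point.
#'
#' @param param Which parameter to sweep: `"N"`, `"U"` or `"s"`.
#' @param from,to Grid endpoints (before clipping).
#' @param length_out Number of grid points.
#' @param N,U,s Values of the fixed parameters.
#' @return A tibble with columns `N`, `U`, `s`, `q`, `lead`, `min_RE`,
#'   `prop_selective`, `sweep_rate`.
#' @export
traveling_wave_grid <- function(param = c("N", "U", "s"), from, to,
                                length_out = 20, N = 1e6, U = 1e-3,
                                s = 0.01) {
  param <- match.arg(param)
  check_positive(c(from, to), "grid endpoints")
  if (param == "U") {
    to <- min(to, s / 3)
    from <- min(from, to)
  }
  if (param == "s") {
    from <- max(from, 3 * U)
    to <- max(to, from)
  }
  grid <- exp(seq(log(from), log(to), length.out = length_out))
  rows <- lapply(grid, function(v) {
    args <- list(N = N, U = U, s = s)
    args[[param]] <- v
    sol <- suppressWarnings(do.call(solve_lead, args))
    tibble::tibble(N = args$N, U = args$U, s = args$s, q = sol$q,
                   lead = sol$lead, min_RE = sol$min_RE,
                   prop_selective = sol$prop_selective,
                   sweep_rate = sol$sweep_rate)
  })
  dplyr::bind_rows(rows)
}
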