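# Generalized life-history framework: ordered transitions, N_min solvers,
# per-transition reproductive excess, bottleneck generalization, and the
# absolute-fitness Wright-Fisher identities.
#
# Stage indexing convention (documented here once, used everywhere):
#
#   stage 0          stage 1                stage T-1         stage T (= 0')
#     N_0  --[trans 1]-->  N_1  --...-->  N_{T-1} --[trans T]-->  N_T = N_0'
#
# Transitions are numbered 1..T. "Stage j" is the population *entering*
# transition j+1; transition j maps stage j-1 to stage j, multiplying the
# stage size by k_j. For a focal transition j, `N_min` refers to the minimum
# size at stage j (i.e. just after the focal transition) that still
# regenerates the stage-(j-1) size one full cycle later.

#' A single life-history transition
#'
#' One survival or reproduction step of a life cycle. `k` gives each
#' genotype's multiplier over the transition: survival requires `k <= 1`,
#' reproduction permits `k > 1`. `k` may also be a function
#' `(stage_size, frequencies) -> named multipliers` for density-regulated
#' transitions; it is resolved on the baseline trajectory when the cycle is
#' built (the counterfactuals behind `N_min` hold all non-focal transitions
#' at their baseline values).
#'
#' @param label Character label for the transition.
#' @param kind `"survival"` or `"reproduction"`.
#' @param k Named numeric vector of per-genotype multipliers (`> 0`), an
#'   unnamed scalar applying to all genotypes, or a function of
#'   `(stage_size, frequencies)` returning such a vector.
#' @return An object of class `lh_transition`.
#' @examples
#' transition("germination", "survival", 0.8)
#' transition("seed set", "reproduction", c(A = 100, B = 80))
#' @export
transition <- function(label, kind = c("survival", "reproduction"), k) {
  kind <- match.arg(kind)
  if (!is.function(k)) {
    check_positive(k, paste0("k (", label, ")"))
    if (kind == "survival" && any(k > 1)) {
      stop_domain("survival transition '", label, "' has k > 1")
    }
  }
  structure(list(label = label, kind = kind, k = k), class = "lh_transition")
}

#' An ordered life cycle
#'
#' A life cycle is an ordered list of [transition()]s together with the
#' population size `n0` entering the first transition and the genotype
#' frequencies at that point. Stage sizes and within-cycle genotype
#' frequencies are propagated forward deterministically (fractional
#' individuals allowed): over transition j, `N_j = N_{j-1} * sum_i f_i k_ij`
#' and `f_i` is reweighted by `k_ij`. Density-dependent `k` functions are
#' evaluated on this baseline trajectory and frozen.
#'
#' @param transitions List of [transition()] objects (at least one).
#' @param n0 Population size entering the first transition (`> 0`).
#' @param frequencies Named genotype frequencies at the start of the cycle
#'   (non-negative, summing to 1). Defaults to a single genotype.
#' @return An object of class `life_cycle` with resolved per-genotype
#'   multiplier matrix `k` (genotypes x transitions), `stage_sizes`
#'   (length T+1, stages 0..T) and per-stage frequencies `freqs`.
#' @examples
#' wf <- life_cycle(list(
#'   transition("birth", "reproduction", c(a = 2, b = 1.8)),
#'   transition("death", "survival", c(a = 0.5, b = 0.5))),
#'   n0 = 100, frequencies = c(a = 0.5, b = 0.5))
#' wf$stage_sizes
#' @export
life_cycle <- function(transitions, n0, frequencies = c(genotype = 1)) {
  if (length(transitions) < 1) stop_domain("need at least one transition")
  if (!all(vapply(transitions, inherits, TRUE, "lh_transition"))) {
    stop_domain("transitions must be built with transition()")
  }
  check_positive(n0, "n0")
  check_positive(frequencies, "frequencies", strict = FALSE)
  if (abs(sum(frequencies) - 1) > 1e-8) {
    stop_domain("genotype frequencies must sum to 1")
  }
  g <- names(frequencies) %||% paste0("g", seq_along(frequencies))
  names(frequencies) <- g
  T_ <- length(transitions)
  k <- matrix(NA_real_, nrow = length(g), ncol = T_,
              dimnames = list(g, vapply(transitions, `[[`, "", "label")))
  freqs <- matrix(NA_real_, nrow = length(g), ncol = T_ + 1,
                  dimnames = list(g, NULL))
  stage <- numeric(T_ + 1)
  stage[1] <- n0
  freqs[, 1] <- frequencies
  for (j in seq_len(T_)) {
    kj <- transitions[[j]]$k
    if (is.function(kj)) kj <- kj(stage[j], freqs[, j])
    if (length(kj) == 1 && is.null(names(kj))) kj <- stats::setNames(rep(kj, length(g)), g)
    if (!all(g %in% names(kj))) {
      stop_domain("transition '", transitions[[j]]$label,
                  "' lacks multipliers for some genotypes")
    }
    kj <- kj[g]
    check_positive(kj, paste0("k (", transitions[[j]]$label, ")"))
    if (transitions[[j]]$kind == "survival" && any(kj > 1)) {
      stop_domain("survival transition '", transitions[[j]]$label,
                  "' resolved to k > 1")
    }
    k[, j] <- kj
    kbar <- sum(freqs[, j] * kj)
    stage[j + 1] <- stage[j] * kbar
    freqs[, j + 1] <- freqs[, j] * kj / kbar
  }
  structure(list(transitions = transitions, n0 = n0, genotypes = g,
                 k = k, stage_sizes = stage, freqs = freqs),
            class = "life_cycle")
}

#' @export
print.life_cycle <- function(x, ...) {
  T_ <- length(x$transitions)
  cat("Life cycle with", T_, "transitions,", length(x$genotypes),
      "genotype(s)\n")
  for (j in seq_len(T_)) {
    cat(sprintf("  %d. %-12s [%s]  N %.6g -> %.6g\n", j,
                x$transitions[[j]]$label, x$transitions[[j]]$kind,
                x$stage_sizes[j], x$stage_sizes[j + 1]))
  }
  invisible(x)
}

# per-transition best-genotype multipliers (resolved per transition, not
# globally: required for antagonistic-pleiotropy accounting)
k_best <- function(cycle) apply(cycle$k, 2, max)

#' Minimum post-transition population size
#'
#' Solves for `N_min` at the stage just after the focal transition `j`: the
#' smallest size there that still regenerates the stage size entering
#' transition `j` one full cycle later, with all non-focal transitions held
#' at their baseline multipliers. With respect to the actual population,
#' `N_j_entry = N_min * sum_i f_i prod_{x != j} k_ix` (with `f_i` the genotype
#' frequencies entering the focal transition); with respect to a hypothetical
#' population of the best genotype, the frequency-weighted sum is replaced by
#' `prod_{x != j} k_best,x`, with the best genotype resolved per transition.
#'
#' @param cycle A [life_cycle()].
#' @param focal Index of the focal transition (1-based).
#' @param mode `"actual"` or `"best"`.
#' @return `N_min` at the stage following the focal transition.
#'   `solve_nmin(cycle, j, "best") <= solve_nmin(cycle, j, "actual")`, with
#'   equality for monomorphic cycles.
#' @export
solve_nmin <- function(cycle, focal, mode = c("actual", "best")) {
  stopifnot(inherits(cycle, "life_cycle"))
  mode <- match.arg(mode)
  T_ <- ncol(cycle$k)
  if (!(focal %in% seq_len(T_))) stop_domain("focal must be in 1..", T_)
  nonfocal <- setdiff(seq_len(T_), focal)
  denom <- if (mode == "best") {
    prod(k_best(cycle)[nonfocal])
  } else {
    per_genotype <- apply(cycle$k[, nonfocal, drop = FALSE], 1, prod)
    sum(cycle$freqs[, focal] * per_genotype)
  }
  if (!is.finite(denom) || denom <= 0) {
    stop_domain("non-focal multiplier product is not positive for transition ",
                focal, " ('", cycle$transitions[[focal]]$label, "')")
  }
  cycle$stage_sizes[focal] / denom
}

#' @rdname solve_nmin
#' @export
solve_nmin_actual <- function(cycle, focal) solve_nmin(cycle, focal, "actual")

#' @rdname solve_nmin
#' @export
solve_nmin_best <- function(cycle, focal) solve_nmin(cycle, focal, "best")

#' Reproductive excess of a life-history transition
#'
#' `RE_j = k_j N_j - N_min`: the realized output of the focal transition
#' minus the minimum output needed for the cycle to sustain itself
#' ([solve_nmin()]). This is the budget from which selective deaths during
#' transition `j` can be paid without shrinking the population. Under
#' `nmin_mode = "best"` the focal population is a hypothetical one in which
#' every individual carries the per-transition best genotype (so the focal
#' output uses `k_best,j`); under `"actual"` both use the realized mean
#' multiplier. May be negative (population not self-sustaining).
#'
#' @param cycle A [life_cycle()].
#' @param focal Focal transition index.
#' @param nmin_mode `"best"` (default) or `"actual"`.
#' @param realized_output Optional observed focal output `k_j N_j`
#'   (individuals), overriding the cycle's own forward simulation - used when
#'   the focal stage size is set externally (e.g. by experimental design)
#'   rather than by the modeled upstream transitions.
#' @return Reproductive excess after the focal transition (individuals).
#' @examples
#' wf <- life_cycle(list(
#'   transition("birth", "reproduction", 2),
#'   transition("death", "survival", 0.5)), n0 = 100)
#' reproductive_excess(wf, 1) # 0: exactly replacing
#' @export
reproductive_excess <- function(cycle, focal,
                                nmin_mode = c("best", "actual"),
                                realized_output = NULL) {
  nmin_mode <- match.arg(nmin_mode)
  nmin <- solve_nmin(cycle, focal, nmin_mode)
  out <- realized_output %||% {
    kj <- if (nmin_mode == "best") k_best(cycle)[[focal]] else {
      sum(cycle$freqs[, focal] * cycle$k[, focal])
    }
    kj * cycle$stage_sizes[focal]
  }
  unname(out - nmin)
}

#' Reproductive excess with a variable life cycle (bottleneck form)
#'
#' For organisms without a fixed sequence of transitions, the fixed-cycle
#' `N_min` is replaced by the minimum output of the focal transition that
#' ensures `N_bot` individuals make it through the worst bottleneck:
#' `N_min = N_bot / E[prod_x k_best,x]`, the expectation running over the
#' possible sequences of transitions between the focal transition and the
#' bottleneck. With a single path of weight 1 whose product equals the
#' non-focal best product and `N_bot` equal to the focal entry stage size,
#' this reduces exactly to [reproductive_excess()].
#'
#' @param cycle A [life_cycle()].
#' @param focal Focal transition index.
#' @param n_bot Minimum number of individuals required past the bottleneck
#'   (`>= 1`); the smallest population that reliably escapes extinction, an
#'   ecological input with no default.
#' @param paths List of paths, each a list with `weight` (probabilities
#'   summing to 1) and `k` (numeric vector of best-genotype multipliers for
#'   the stages between focal transition and bottleneck).
#' @param realized_output As in [reproductive_excess()].
#' @return Reproductive excess after the focal transition.
#' @examples
#' wf <- life_cycle(list(
#'   transition("growth", "reproduction", 100),
#'   transition("dilution", "survival", 0.01)), n0 = 1e6)
#' reproductive_excess_bottleneck(wf, 2, n_bot = 100,
#'   paths = list(list(weight = 1, k = 100)))
#' @export
reproductive_excess_bottleneck <- function(cycle, focal, n_bot, paths,
                                           realized_output = NULL) {
  stopifnot(inherits(cycle, "life_cycle"))
  check_positive(n_bot, "n_bot")
  w <- vapply(paths, function(p) p$weight, 0)
  if (abs(sum(w) - 1) > 1e-8) stop_domain("path weights must sum to 1")
  prods <- vapply(paths, function(p) prod(p$k), 0)
  eprod <- sum(w * prods)
  if (!is.finite(eprod) || eprod <= 0) {
    stop_domain("expected multiplier product over paths must be positive")
  }
  nmin <- n_bot / eprod
  out <- realized_output %||%
    (k_best(cycle)[[focal]] * cycle$stage_sizes[focal])
  unname(out - nmin)
}

#' Absolute-fitness Wright-Fisher identities
#'
#' In an absolute-fitness Wright-Fisher model where adults of genotype `i`
#' leave `k_i` offspring and die, per-capita selective deaths equal
#' `k_best - k_mean`, the minimum adult population is `N_min = N / k_best`,
#' and per-capita reproductive excess is `k_mean - 1 / k_best`.
#'
#' @param k_mean Mean absolute fitness (`> 0`).
#' @param k_best Best genotype's absolute fitness (`>= k_mean`).
#' @param N Adult population size.
#' @return List with `selective_deaths_per_capita`, `n_min`,
#'   `reproductive_excess_per_capita`.
#' @examples
#' wf_identities(1, 1.1, 1000)
#' @export
wf_identities <- function(k_mean, k_best, N) {
  check_positive(k_mean, "k_mean")
  check_positive(k_best, "k_best")
  check_positive(N, "N")
  if (k_mean > k_best) stop_domain("k_mean cannot exceed k_best")
  list(selective_deaths_per_capita = k_best - k_mean,
       n_min = N / k_best,
       reproductive_excess_per_capita = k_mean - 1 / k_best)
}

#' Selective deaths during one transition
#'
#' How many deaths (or foregone offspring) each genotype experiences during a
#' transition that it would not have experienced if replaced by the best
#' genotype at that transition: `N_i (k_best - k_i)` with `N_i` the genotype's
#' count entering the transition. The best genotype is resolved per
#' transition, so antagonistic pleiotropy across transitions produces positive
#' selective deaths at each of them - selective deaths never cancel out.
#'
#' @param trans A [transition()] with a resolved (non-function) `k`.
#' @param counts Named per-genotype counts entering the transition (`>= 0`).
#' @return List with `per_genotype` (named vector) and `total`.
#' @examples
#' selective_deaths_per_transition(
#'   transition("overwinter", "survival", c(A = 0.9, B = 0.6)),
#'   counts = c(A = 100, B = 100)) # B: 30
#' @export
selective_deaths_per_transition <- function(trans, counts) {
  stopifnot(inherits(trans, "lh_transition"))
  if (length(counts) == 0) stop_domain("empty genotype counts")
  check_positive(counts, "counts", strict = FALSE)
  k <- trans$k
  if (is.function(k)) {
    stop_domain("transition has an unresolved density-dependent k; ",
                "resolve it through life_cycle() first")
  }
  if (length(k) == 1 && is.null(names(k))) {
    k <- stats::setNames(rep(k, length(counts)), names(counts))
  }
  if (!is.null(names(counts))) k <- k[names(counts)]
  if (length(k) != length(counts) || anyNA(k)) {
    stop_domain("counts and transition multipliers do not align")
  }
  per <- counts * (max(k) - k)
  list(per_genotype = per, total = sum(per))
}

#' Forward-simulate a cycle from the stage after a focal transition
#'
#' Carries a population of `size` individuals, placed at the stage just after
#' transition `after`, through the remaining transitions of the cycle and
#' around through the completed ones, returning the size entering transition
#' `after` in the next cycle. Under `mode = "best"` every individual uses the
#' per-transition best multiplier; under `"actual"` genotypes are propagated
#' (and reweighted) individually, starting from the frequencies entering the
#' focal transition - the focal transition itself is treated as
#' genotype-neutral, matching the counterfactual behind [solve_nmin()]. By
#' construction, seeding with `solve_nmin(cycle, after, mode)` returns the
#' focal entry stage size exactly (the defining round-trip identity).
#'
#' @param cycle A [life_cycle()].
#' @param after Transition index after which `size` is measured.
#' @param size Population size at that stage.
#' @param mode `"best"` or `"actual"`.
#' @return Population size entering transition `after` one cycle later.
#' @export
simulate_from <- function(cycle, after, size, mode = c("best", "actual")) {
  mode <- match.arg(mode)
  T_ <- ncol(cycle$k)
  if (!(after %in% seq_len(T_))) stop_domain("after must be in 1..", T_)
  order_ <- c(seq_len(T_)[-seq_len(after)], seq_len(after)[-after])
  if (mode == "best") {
    return(size * prod(k_best(cycle)[order_]))
  }
  f <- cycle$freqs[, after]
  n <- size
  for (j in order_) {
    kbar <- sum(f * cycle$k[, j])
    n <- n * kbar
    f <- f * cycle$k[, j] / kbar
  }
  n
}
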