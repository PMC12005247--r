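# shared fixtures built in code

# a two-genotype high-density-style toy with survival 1.0 and 0.5,
# 10 seeds/survivor fecundity, used for hand-checked reproductive excess
toy_cohort <- function() {
  validate_cohort(tibble::tibble(
    genotype = c("a", "b"),
    environment = "toy",
    pot = c(1L, 1L),
    seeds_planted = c(10L, 10L),
    seedlings_retained = c(10L, 10L),
    adults = c(10L, 5L),
    seeds_produced = c(100L, 50L)))
}

# a small random monomorphic life cycle (survival/reproduction alternating)
random_cycle <- function(n_trans = 4, genotypes = 1) {
  kinds <- sample(c("survival", "reproduction"), n_trans, replace = TRUE)
  trans <- lapply(seq_len(n_trans), function(j) {
    k <- if (kinds[j] == "survival") {
      stats::runif(genotypes, 0.2, 1)
    } else {
      stats::runif(genotypes, 0.5, 5)
    }
    names(k) <- paste0("g", seq_len(genotypes))
    transition(paste0("t", j), kinds[j], k)
  })
  f <- stats::setNames(rep(1 / genotypes, genotypes),
                       paste0("g", seq_len(genotypes)))
  life_cycle(trans, n0 = stats::runif(1, 50, 500), frequencies = f)
}
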