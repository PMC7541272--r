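# Fixtures built in code: small instances, consistent life tables, random
# comparison pairs, and an independent term-by-term oracle for the
# decomposition equations (explicit weighted sums, no package internals).

make_instance <- function(population, deaths, width = 10, label = "inst") {
  n <- length(population)
  starts <- (seq_len(n) - 1) * width
  yll_instance(
    data.frame(
      age_start = starts,
      age_end = c(starts[-1], NA),
      population = population,
      deaths = deaths
    ),
    label = label
  )
}

# life table satisfying the consistency property: slope < 1 per year of age
make_lt <- function(n, width = 10, le0 = 80, slope = 0.8) {
  starts <- (seq_len(n) - 1) * width
  yll_lifetable(data.frame(
    age_start = starts,
    age_end = c(starts[-1], NA),
    le_years = pmax(le0 - slope * starts, 1)
  ))
}

# random valid comparison pair on a shared schedule
random_pair <- function(n_bins = 10, width = 8) {
  population0 <- runif(n_bins, 100, 10000)
  population1 <- runif(n_bins, 100, 10000)
  # death rates up to 150 per 1000, so deaths < population always
  deaths0 <- population0 * runif(n_bins, 0, 0.15)
  deaths1 <- population1 * runif(n_bins, 0, 0.15)
  list(
    baseline = make_instance(population0, deaths0, width, label = "b"),
    comparison = make_instance(population1, deaths1, width, label = "c"),
    lifetable = make_lt(n_bins, width)
  )
}

# independent oracle: every equation expanded term by term from the raw
# pw/dr/le vectors
oracle_decomposition <- function(pw0, dr0, pw1, dr1, le) {
  yll0 <- sum(pw0 * le * dr0)
  yll1 <- sum(pw1 * le * dr1)
  delta <- yll1 - yll0
  as_p <- sum(pw1 * le * dr0) - sum(pw0 * le * dr0)
  as_t <- sum(pw1 * le * dr1) - sum(pw0 * le * dr1)
  death_p <- sum(pw0 * le * dr1) - sum(pw0 * le * dr0)
  death_t <- sum(pw1 * le * dr1) - sum(pw1 * le * dr0)
  ratio_p <- sum(pw0 * dr1) / sum(pw0 * dr0)
  ratio_t <- sum(pw1 * dr1) / sum(pw1 * dr0)
  aad_p <- sum(pw0 * le * dr1) - sum(pw0 * le * dr0) * ratio_p
  aad_t <- sum(pw1 * le * dr1) - sum(pw1 * le * dr0) * ratio_t
  drate_p <- sum(pw0 * le * dr0) * ratio_p - sum(pw0 * le * dr0)
  drate_t <- sum(pw1 * le * dr0) * ratio_t - sum(pw1 * le * dr0)
  list(
    yll0 = yll0, yll1 = yll1, delta = delta,
    as_p = as_p, as_t = as_t,
    death_p = death_p, death_t = death_t,
    ratio_p = ratio_p, ratio_t = ratio_t,
    aad_p = aad_p, aad_t = aad_t,
    drate_p = drate_p, drate_t = drate_t,
    resid_p = delta - as_p - death_p,
    resid_t = delta - as_t - death_t,
    resid_closed = sum(le * (pw1 - pw0) * (dr1 - dr0))
  )
}

rates_of <- function(pair) {
  list(
    r0 = rate_schedule(pair$baseline),
    r1 = rate_schedule(pair$comparison)
  )
}
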