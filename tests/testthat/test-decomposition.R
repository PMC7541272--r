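test_that("delta_yll is the difference of the two YLL rates", {
  pair <- random_pair(n_bins = 5)
  r <- rates_of(pair)
  expect_equal(delta_yll(r$r0, r$r0, pair$lifetable), 0)
  expect_equal(
    delta_yll(r$r0, r$r1, pair$lifetable),
    yll_rate(pair$comparison, pair$lifetable) - yll_rate(pair$baseline, pair$lifetable),
    tolerance = 1e-12
  )
})

test_that("delta equals the death gradient when only death rates change", {
  i0 <- make_instance(c(400, 600), c(4, 12))
  i1 <- make_instance(c(400, 600), c(2, 18)) # same populations, new deaths
  lt <- make_lt(2)
  r0 <- rate_schedule(i0)
  r1 <- rate_schedule(i1)
  d <- delta_yll(r0, r1, lt)
  for (a in c("partial", "total")) {
    expect_equal(death_gradient(r0, r1, lt, a), d, tolerance = 1e-12)
    expect_equal(age_structure_gradient(r0, r1, lt, a), 0)
  }
  expect_equal(decomposition_residual(r0, r1, lt, "partial"), 0, tolerance = 1e-12)
})

test_that("age-structure gradient matches its hand expansion", {
  # 2 bins: pw (0.6,0.4)->(0.4,0.6), dr0=(5,20), le=(60,10)
  # partial = (-0.2)(60)(5) + (0.2)(10)(20) = -60 + 40 = -20
  i0 <- instance_from_rates(
    data.frame(age_start = c(0, 60), age_end = c(60, NA), pw = c(0.6, 0.4), dr_per_1000 = c(5, 20)),
    total_population = 10000
  )
  i1 <- instance_from_rates(
    data.frame(age_start = c(0, 60), age_end = c(60, NA), pw = c(0.4, 0.6), dr_per_1000 = c(5, 20)),
    total_population = 10000
  )
  lt <- yll_lifetable(data.frame(age_start = c(0, 60), le_years = c(60, 10)))
  r0 <- rate_schedule(i0)
  r1 <- rate_schedule(i1)
  expect_equal(age_structure_gradient(r0, r1, lt, "partial"), -20, tolerance = 1e-9)
  # dr unchanged: both approaches agree, death gradient and residual vanish
  expect_equal(age_structure_gradient(r0, r1, lt, "total"), -20, tolerance = 1e-9)
  expect_equal(death_gradient(r0, r1, lt, "partial"), 0, tolerance = 1e-12)
  expect_equal(decomposition_residual(r0, r1, lt, "total"), 0, tolerance = 1e-12)
})

test_that("single-bin death gradient is le times the rate change", {
  i0 <- make_instance(1000, 10)
  i1 <- make_instance(1000, 8)
  lt <- yll_lifetable(data.frame(age_start = 0, le_years = 50))
  r0 <- rate_schedule(i0)
  r1 <- rate_schedule(i1)
  for (a in c("partial", "total")) {
    expect_equal(death_gradient(r0, r1, lt, a), 1 * 50 * (8 - 10), tolerance = 1e-12)
  }
})

test_that("overall death-rate ratio behaves as a scaling factor", {
  pair <- random_pair(n_bins = 6)
  r <- rates_of(pair)
  expect_equal(overall_death_rate_ratio(r$r0, r$r0, "partial"), 1)
  half <- r$r0
  half$dr <- r$r0$dr * 0.5
  expect_equal(overall_death_rate_ratio(r$r0, half, "partial"), 0.5, tolerance = 1e-12)
  expect_equal(overall_death_rate_ratio(r$r0, half, "total"), 0.5, tolerance = 1e-12)
  # mixed case against direct arithmetic
  expect_equal(
    overall_death_rate_ratio(r$r0, r$r1, "total"),
    sum(r$r1$pw * r$r1$dr) / sum(r$r1$pw * r$r0$dr),
    tolerance = 1e-12
  )
  zero <- r$r0
  zero$dr <- zero$dr * 0
  expect_error(overall_death_rate_ratio(zero, r$r1, "partial"),
    class = "ylldecomp_degenerate_baseline"
  )
})

test_that("uniform rate scaling has zero age-at-death gradient", {
  set.seed(7)
  for (c_factor in c(0.25, 0.5, 1, 1.7)) {
    pair <- random_pair(n_bins = 8)
    r0 <- rate_schedule(pair$baseline)
    r1 <- r0
    r1$dr <- r0$dr * c_factor
    for (a in c("partial", "total")) {
      expect_equal(age_at_death_gradient(r0, r1, pair$lifetable, a), 0, tolerance = 1e-9)
      expect_equal(
        death_rate_gradient(r0, r1, pair$lifetable, a),
        death_gradient(r0, r1, pair$lifetable, a),
        tolerance = 1e-9
      )
    }
  }
})

test_that("delaying deaths to older ages at fixed overall rate gives a negative age-at-death gradient", {
  # same pw, same pw-weighted overall death rate; deaths move from the
  # young bin (high remaining life) to the old bin
  pw <- c(0.5, 0.5)
  dr0 <- c(20, 10)
  dr1 <- c(10, 20) # sum(pw*dr) unchanged
  le <- c(70, 20)
  df <- function(dr) {
    instance_from_rates(
      data.frame(age_start = c(0, 50), age_end = c(50, NA), pw = pw, dr_per_1000 = dr),
      total_population = 1000
    )
  }
  lt <- yll_lifetable(data.frame(age_start = c(0, 50), le_years = le))
  r0 <- rate_schedule(df(dr0))
  r1 <- rate_schedule(df(dr1))
  # hand expansion: ratio = 1, aad = sum(pw*le*dr1) - sum(pw*le*dr0)
  expected <- sum(pw * le * dr1) - sum(pw * le * dr0) # 0.5*(70*10+20*20) - 0.5*(70*20+20*10) = -250
  expect_equal(expected, -250)
  for (a in c("partial", "total")) {
    expect_equal(age_at_death_gradient(r0, r1, lt, a), -250, tolerance = 1e-9)
    expect_lt(age_at_death_gradient(r0, r1, lt, a), 0)
    expect_equal(death_rate_gradient(r0, r1, lt, a), 0, tolerance = 1e-9)
  }
})

test_that("gradients match the independent term-by-term oracle on random pairs", {
  set.seed(101)
  for (i in 1:30) {
    pair <- random_pair(n_bins = sample(3:12, 1))
    r <- rates_of(pair)
    le <- pair$lifetable$le_years
    o <- oracle_decomposition(r$r0$pw, r$r0$dr, r$r1$pw, r$r1$dr, le)
    lt <- pair$lifetable
    expect_equal(delta_yll(r$r0, r$r1, lt), o$delta, tolerance = 1e-12)
    expect_equal(age_structure_gradient(r$r0, r$r1, lt, "partial"), o$as_p, tolerance = 1e-12)
    expect_equal(age_structure_gradient(r$r0, r$r1, lt, "total"), o$as_t, tolerance = 1e-12)
    expect_equal(death_gradient(r$r0, r$r1, lt, "partial"), o$death_p, tolerance = 1e-12)
    expect_equal(death_gradient(r$r0, r$r1, lt, "total"), o$death_t, tolerance = 1e-12)
    expect_equal(age_at_death_gradient(r$r0, r$r1, lt, "partial"), o$aad_p, tolerance = 1e-12)
    expect_equal(age_at_death_gradient(r$r0, r$r1, lt, "total"), o$aad_t, tolerance = 1e-12)
    expect_equal(death_rate_gradient(r$r0, r$r1, lt, "partial"), o$drate_p, tolerance = 1e-12)
    expect_equal(death_rate_gradient(r$r0, r$r1, lt, "total"), o$drate_t, tolerance = 1e-12)
  }
})

test_that("age-at-death and death-rate gradients sum to the death gradient exactly", {
  set.seed(5)
  for (i in 1:50) {
    pair <- random_pair(n_bins = 4)
    r <- rates_of(pair)
    for (a in c("partial", "total")) {
      lhs <- age_at_death_gradient(r$r0, r$r1, pair$lifetable, a) +
        death_rate_gradient(r$r0, r$r1, pair$lifetable, a)
      expect_equal(lhs, death_gradient(r$r0, r$r1, pair$lifetable, a), tolerance = 1e-12)
    }
  }
})

test_that("partial and total residuals are antisymmetric and match the closed form", {
  set.seed(9)
  for (i in 1:50) {
    pair <- random_pair(n_bins = sample(2:10, 1))
    r <- rates_of(pair)
    res_p <- decomposition_residual(r$r0, r$r1, pair$lifetable, "partial")
    res_t <- decomposition_residual(r$r0, r$r1, pair$lifetable, "total")
    closed <- sum(pair$lifetable$le_years * (r$r1$pw - r$r0$pw) * (r$r1$dr - r$r0$dr))
    expect_equal(res_p, closed, tolerance = 1e-9)
    expect_equal(res_t, -closed, tolerance = 1e-9)
  }
})

test_that("averaging the two approaches removes the residual", {
  pair <- random_pair(n_bins = 7)
  res <- decompose_yll(pair$baseline, pair$comparison, pair$lifetable)
  expect_equal(sum(res$residue_free), res$delta_yll, tolerance = 1e-9)
  expect_equal(res$partial$residual, -res$total$residual, tolerance = 1e-9)
  expect_equal(sum(res$percent), 100, tolerance = 1e-6)
  # averaging identity: equal inputs are returned unchanged
  x <- c(age_structure = 1.5, death_rate = -2, age_at_death = 0.25)
  expect_equal(residue_free(x, x), x)
  expect_equal(
    residue_free(
      c(age_structure = -85.13, death_rate = -305.65, age_at_death = -27.83),
      c(age_structure = -34.21, death_rate = -258.45, age_at_death = -24.11)
    ),
    c(age_structure = -59.67, death_rate = -282.05, age_at_death = -25.97)
  )
})

test_that("percent contributions divide by the signed overall change", {
  expect_equal(
    unname(percent_contributions(c(a = 5, b = 0, c = 0), 5)),
    c(100, 0, 0)
  )
  pct <- percent_contributions(c(x = -2, y = 6), 4)
  expect_equal(unname(pct), c(-50, 150))
  expect_equal(sum(pct), 100)
  expect_error(percent_contributions(c(x = 1), 0), class = "ylldecomp_zero_delta")
})

test_that("adjusted baseline rates reproduce the comparison's overall death rate", {
  pair <- random_pair(n_bins = 9)
  r <- rates_of(pair)
  same <- adjusted_death_rates(r$r0, r$r0, "partial")
  expect_equal(same$dr0_adjusted, r$r0$dr)
  half <- r$r0
  half$dr <- r$r0$dr * 0.5
  expect_equal(adjusted_death_rates(r$r0, half, "partial")$dr0_adjusted, half$dr,
    tolerance = 1e-12
  )
  adj <- adjusted_death_rates(r$r0, r$r1, "partial")
  expect_equal(
    sum(r$r0$pw * adj$dr0_adjusted),
    sum(r$r0$pw * r$r1$dr),
    tolerance = 1e-12
  )
})

test_that("identical instances decompose to the all-zero result", {
  pair <- random_pair(n_bins = 6)
  res <- suppressWarnings(decompose_yll(pair$baseline, pair$baseline, pair$lifetable))
  expect_equal(res$delta_yll, 0)
  for (block in list(res$partial, res$total)) {
    expect_equal(block$age_structure, 0)
    expect_equal(block$death, 0)
    expect_equal(block$age_at_death, 0)
    expect_equal(block$death_rate, 0)
    expect_equal(block$residual, 0)
  }
  expect_equal(unname(res$residue_free), c(0, 0, 0))
  expect_true(res$zero_delta)
  expect_true(all(is.na(res$percent)))
})

test_that("swapping baseline and comparison negates the change and exchanges approaches", {
  set.seed(23)
  pair <- random_pair(n_bins = 8)
  fwd <- decompose_yll(pair$baseline, pair$comparison, pair$lifetable)
  rev <- decompose_yll(pair$comparison, pair$baseline, pair$lifetable)
  expect_equal(rev$delta_yll, -fwd$delta_yll, tolerance = 1e-12)
  for (k in c("age_structure", "death", "residual")) {
    expect_equal(rev$partial[[k]], -fwd$total[[k]], tolerance = 1e-9)
    expect_equal(rev$total[[k]], -fwd$partial[[k]], tolerance = 1e-9)
  }
  expect_equal(unname(rev$residue_free["age_structure"]),
    -unname(fwd$residue_free["age_structure"]),
    tolerance = 1e-9
  )
})

test_that("decompose_yll agrees with the oracle end to end", {
  set.seed(31)
  pair <- random_pair(n_bins = 3)
  r <- rates_of(pair)
  o <- oracle_decomposition(r$r0$pw, r$r0$dr, r$r1$pw, r$r1$dr, pair$lifetable$le_years)
  res <- decompose_yll(pair$baseline, pair$comparison, pair$lifetable)
  expect_equal(res$yll0, o$yll0, tolerance = 1e-12)
  expect_equal(res$yll1, o$yll1, tolerance = 1e-12)
  expect_equal(res$delta_yll, o$delta, tolerance = 1e-12)
  expect_equal(res$partial$age_structure, o$as_p, tolerance = 1e-12)
  expect_equal(res$partial$death_rate, o$drate_p, tolerance = 1e-12)
  expect_equal(res$partial$age_at_death, o$aad_p, tolerance = 1e-12)
  expect_equal(res$partial$residual, o$resid_p, tolerance = 1e-12)
  expect_equal(res$total$age_structure, o$as_t, tolerance = 1e-12)
  expect_equal(res$total$death_rate, o$drate_t, tolerance = 1e-12)
  expect_equal(res$total$age_at_death, o$aad_t, tolerance = 1e-12)
  expect_equal(res$total$residual, o$resid_t, tolerance = 1e-12)
  expect_equal(
    unname(res$residue_free),
    c((o$as_p + o$as_t) / 2, (o$drate_p + o$drate_t) / 2, (o$aad_p + o$aad_t) / 2),
    tolerance = 1e-12
  )
})

test_that("a deathless baseline assigns the whole death gradient to the death rate", {
  i0 <- make_instance(c(500, 500), c(0, 0))
  i1 <- make_instance(c(500, 500), c(5, 2))
  lt <- make_lt(2)
  expect_warning(
    res <- decompose_yll(i0, i1, lt),
    class = "ylldecomp_degenerate_baseline_warning"
  )
  for (block in list(res$partial, res$total)) {
    expect_equal(block$age_at_death, 0)
    expect_equal(block$death_rate, block$death, tolerance = 1e-12)
  }
  expect_true(length(res$warnings) > 0)
})

test_that("tidy and glance summarise the decomposition", {
  pair <- random_pair(n_bins = 5)
  res <- decompose_yll(pair$baseline, pair$comparison, pair$lifetable)
  td <- tidy(res)
  expect_identical(nrow(td), 12L) # 4 components x 3 approaches
  expect_setequal(unique(td$approach), c("partial", "total", "averaged"))
  avg <- td[td$approach == "averaged" & td$component != "residual", ]
  expect_equal(sum(avg$estimate), res$delta_yll, tolerance = 1e-9)
  expect_equal(sum(avg$percent), 100, tolerance = 1e-6)
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$delta_yll, res$delta_yll)
  expect_equal(gl$n_bins, 5L)
})

test_that("plots are buildable ggplot objects", {
  pair <- random_pair(n_bins = 6)
  res <- decompose_yll(pair$baseline, pair$comparison, pair$lifetable)
  p1 <- autoplot(res)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_death_rates(pair$baseline, pair$comparison)
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
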