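test_that("summary statistics follow their definitions", {
  s <- summarize_values(c(5, 5, 5))
  expect_equal(s$am, 5); expect_equal(s$gm, 5)
  expect_equal(s$median, 5); expect_equal(s$sd, 0)
  s2 <- summarize_values(c(1, 10, 100))
  expect_equal(s2$gm, 10)
  expect_equal(s2$am, 37)
  expect_equal(s2$median, 10)
  expect_equal(c(s2$min, s2$max), c(1, 100))
  # even n uses the midpoint rule
  expect_equal(summarize_values(c(1, 2, 10, 20))$median, 6)
})

test_that("censored values are counted but never enter the statistics", {
  base <- summarize_values(c(2, 4, 8))
  mixed <- summarize_values(c(2, 4, 8, 999, 0.001),
                            censored = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(mixed$n_censored, 2)
  expect_equal(mixed$n_detected, 3)
  for (f in c("am", "sd", "gm", "median", "min", "max"))
    expect_equal(mixed[[f]], base[[f]])
  expect_error(summarize_values(c(1, 2), censored = c(TRUE, TRUE)),
               class = "radecol_empty_summary_error")
  expect_error(summarize_values(c(0, 2)), class = "radecol_domain_error")
})

test_that("GM never exceeds AM on positive data, equality iff constant", {
  set.seed(5)
  for (i in 1:20) {
    v <- rlnorm(sample(3:12, 1), meanlog = runif(1, -1, 3), sdlog = runif(1, 0.1, 1.5))
    s <- summarize_values(v)
    expect_lte(s$gm, s$am + 1e-12)
  }
  expect_equal(summarize_values(rep(3.3, 4))$gm, summarize_values(rep(3.3, 4))$am)
})

test_that("relative-to-muscle percentages are per-animal ratios", {
  co <- make_small_cohort()  # heart = 50%, 75%, 25% of muscle by construction
  rel <- relative_to_muscle(co, "Cs137")
  expect_equal(unname(rel$percent[, "muscle"]), c(100, 100, 100))
  expect_equal(unname(rel$percent[, "heart"]), c(50, 75, 25))
  expect_equal(unname(rel$mean_percent["heart"]), 50)
})

test_that("relative distribution is scale-free per animal", {
  co <- make_small_cohort()
  m2 <- co$measurements
  m2$value[m2$animal_id == "A2"] <- m2$value[m2$animal_id == "A2"] * 7
  co2 <- cohort_dataset(co$animals, m2)
  expect_equal(relative_to_muscle(co2, "Cs137")$percent,
               relative_to_muscle(co, "Cs137")$percent)
})

test_that("animals without a detected muscle value are dropped with a warning", {
  a <- make_animals(2)
  m <- rbind(make_measurements("A1", "muscle", "Cs137", 10),
             make_measurements(c("A1", "A2"), "heart", "Cs137", c(5, 9)))
  co <- cohort_dataset(a, m)
  expect_warning(rel <- relative_to_muscle(co, "Cs137"), "A2")
  expect_equal(rownames(rel$percent), "A1")
  expect_error(relative_to_muscle(co, "K40"), class = "radecol_empty_result_error")
})

test_that("spearman matrix is tie-aware and matches the midrank oracle", {
  a <- make_animals(8)
  set.seed(42)
  for (rep in 1:10) {
    x <- sample(1:4, 8, replace = TRUE) + runif(8, 0, 0.01)  # forced ties
    y <- sample(1:4, 8, replace = TRUE)
    m <- rbind(make_measurements(a$animal_id, "muscle", "Cd", x, unit = "mg/kg"),
               make_measurements(a$animal_id, "liver", "Cd", y + 0.5, unit = "mg/kg"))
    co <- cohort_dataset(a, m)
    sm <- spearman_matrix(co, "Cd", c("muscle", "liver"))
    expect_equal(sm["muscle", "liver"],
                 suppressWarnings(cor(x, y + 0.5, method = "spearman")))
  }
})

test_that("spearman matrix handles monotone structure and sparse pairs", {
  a <- make_animals(5)
  x <- c(1, 3, 7, 8, 20)
  m <- rbind(make_measurements(a$animal_id, "muscle", "Cs137", x),
             make_measurements(a$animal_id, "heart", "Cs137", x^2),
             make_measurements(a$animal_id, "liver", "Cs137", rev(x)),
             make_measurements(a$animal_id[1:2], "kidney", "Cs137", c(4, 6)))
  co <- cohort_dataset(a, m)
  sm <- spearman_matrix(co, "Cs137", c("muscle", "heart", "liver", "kidney"))
  expect_equal(sm["muscle", "heart"], 1)     # monotone increasing
  expect_equal(sm["muscle", "liver"], -1)    # strictly decreasing
  expect_true(is.na(sm["muscle", "kidney"])) # < 3 complete pairs -> NA, not 0
  expect_equal(sm, t(sm))
  # invariance under a strictly monotone transform
  m2 <- m
  idx <- m2$tissue == "muscle"
  m2$value[idx] <- exp(m2$value[idx] / 10)
  sm2 <- spearman_matrix(cohort_dataset(a, m2), "Cs137",
                         c("muscle", "heart", "liver", "kidney"))
  expect_equal(sm2["muscle", "heart"], sm["muscle", "heart"])
  expect_equal(sm2["muscle", "liver"], sm["muscle", "liver"])
})

test_that("BCI residuals match manual least squares on a 4-point reference", {
  ref <- data.frame(body_length_cm = c(100, 110, 120, 130),
                    body_mass_kg = c(20, 24, 27, 33))
  # hand OLS: beta = cov(x, y) / var(x), alpha = ybar - beta * xbar
  beta <- cov(ref$body_length_cm, ref$body_mass_kg) / var(ref$body_length_cm)
  alpha <- mean(ref$body_mass_kg) - beta * mean(ref$body_length_cm)
  bci <- compute_bci(c(30, 25), c(115, 125), ref)
  expect_equal(bci, c(30, 25) - (alpha + beta * c(115, 125)))
  # an animal exactly on the fitted line scores zero
  expect_equal(compute_bci(alpha + beta * 118, 118, ref), 0)
  # reference residuals sum to zero
  resid <- compute_bci(ref$body_mass_kg, ref$body_length_cm, ref)
  expect_lt(abs(sum(resid)), 1e-9)
  # missing biometrics give a missing BCI
  expect_true(is.na(compute_bci(NA, 120, ref)))
  expect_error(compute_bci(25, 115, data.frame(body_length_cm = c(120, 120, 120),
                                               body_mass_kg = c(20, 25, 30))),
               class = "radecol_fit_error")
})
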