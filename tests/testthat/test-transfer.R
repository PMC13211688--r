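soil_t0 <- function(date = "2016-01-01") {
  data.frame(analyte = c("Cs137", "Cs137", "Cd"),
             value = c(109, 141, 0.9),
             unit = c("Bq/kg", "Bq/kg", "mg/kg"),
             basis = "dry",
             reference_date = c(date, date, NA),
             source = "fixture", stringsAsFactors = FALSE)
}

test_that("whole-organism concentrations follow the proxy-tissue rules", {
  a <- make_animals(1)
  m <- rbind(make_measurements("A1", "muscle", "Cs137", 40),
             make_measurements("A1", "bone", "Pb", 1000, unit = "ug/kg"))
  co <- cohort_dataset(a, m)
  cfg <- transfer_config()
  expect_equal(whole_organism_concentration(co, "Cs137", cfg, "A1"), 10)
  expect_equal(whole_organism_concentration(co, "Pb", cfg, "A1"), 160)
  # f = 1 proxy is the identity
  cfg1 <- transfer_config(tissue_factor = c(muscle = 1))
  expect_equal(whole_organism_concentration(co, "Cs137", cfg1, "A1"), 40)
  expect_error(whole_organism_concentration(co, "Sr", cfg, "A1"),
               class = "radecol_config_error")
})

test_that("censored-only proxies are skipped with a warning", {
  a <- make_animals(1)
  m <- make_measurements("A1", "muscle", "Cs137", 0.05, censored = TRUE)
  co <- cohort_dataset(a, m)
  expect_warning(v <- whole_organism_concentration(co, "Cs137",
                                                   transfer_config(), "A1"),
                 "censored")
  expect_true(is.na(v))
})

test_that("concentration ratio is a guarded quotient", {
  expect_equal(concentration_ratio(7, 7), 1)
  expect_equal(concentration_ratio(0, 5), 0)
  expect_equal(concentration_ratio(10.1, 125), 0.0808)
  expect_error(concentration_ratio(1, 2, "Bq/kg", "mg/kg"),
               class = "radecol_unit_error")
  expect_error(concentration_ratio(1, 0), class = "radecol_domain_error")
})

test_that("soil references decay-correct radionuclides and pass stable elements", {
  st <- soil_t0("2016-01-01")
  # stable element: value unchanged regardless of date
  expect_equal(soil_reference_for("Cd", as.Date("2030-01-01"), st)$value, 0.9)
  # two radionuclide entries at zero elapsed time: plain mean
  expect_equal(soil_reference_for("Cs137", as.Date("2016-01-01"), st)$value, 125)
  # one half-life halves a single entry
  one <- st[1, ]
  d <- as.Date("2016-01-01") + 10958          # whole days, so pick the matching T1/2
  spec <- data.frame(name = "Cs137", half_life_years = 10958 / 365.25,
                     stable_analogue = "Cs")
  expect_equal(soil_reference_for("Cs137", d, one, spec)$value, 109 / 2,
               tolerance = 1e-12)
  # radionuclide entry without reference_date is a configuration error
  bad <- st; bad$reference_date[1:2] <- NA
  expect_error(soil_reference_for("Cs137", d, bad), class = "radecol_config_error")
})

test_that("cr_table matches hand-computed per-animal ratios", {
  a <- make_animals(3, dates = rep(as.Date("2016-01-01"), 3))
  m <- make_measurements(a$animal_id, "muscle", "Cs137", c(40, 80, 120))
  co <- cohort_dataset(a, m)
  tab <- cr_table(co, "Cs137", transfer_config(), soil_t0("2016-01-01"))
  crs <- attr(tab, "per_animal")$Cs137
  # hand arithmetic: (value * 0.25) / 125
  expect_equal(unname(crs), c(10, 20, 30) / 125)
  expect_equal(tab$am, mean(crs))
  expect_equal(tab$gm, exp(mean(log(crs))))
  expect_equal(c(tab$min, tab$max), range(crs))
  expect_equal(tab$soil_value_used, 125)
  # constant values: SD = 0 and AM = GM = each CR
  mc <- make_measurements(a$animal_id, "muscle", "Cs137", rep(50, 3))
  tc <- cr_table(cohort_dataset(a, mc), "Cs137", transfer_config(),
                 soil_t0("2016-01-01"))
  expect_equal(tc$sd, 0)
  expect_equal(tc$am, tc$gm)
})

test_that("CR is invariant under simultaneous unit rescaling", {
  a <- make_animals(2, dates = rep(as.Date("2016-01-01"), 2))
  m <- make_measurements(a$animal_id, "muscle", "Cs137", c(30, 60))
  co <- cohort_dataset(a, m)
  st <- soil_t0("2016-01-01")
  t1 <- cr_table(co, "Cs137", transfer_config(), st)
  m2 <- m; m2$value <- m2$value * 1000
  st2 <- st; st2$value <- st2$value * 1000
  t2 <- cr_table(cohort_dataset(a, m2), "Cs137", transfer_config(), st2)
  expect_equal(t1$am, t2$am)
  expect_equal(t1$min, t2$min)
})

test_that("later sampling dates scale radionuclide CRs by the decay law", {
  shift_days <- 3652
  shift <- shift_days / 365.25  # years, matching the fixed-year convention
  d0 <- rep(as.Date("2016-01-01"), 2)
  a1 <- make_animals(2, dates = d0)
  a2 <- make_animals(2, dates = d0 + shift_days)
  m <- make_measurements(c("A1", "A2"), "muscle", "Cs137", c(30, 60))
  st <- soil_t0("2016-01-01")
  t1 <- cr_table(cohort_dataset(a1, m), "Cs137", transfer_config(), st)
  t2 <- cr_table(cohort_dataset(a2, m), "Cs137", transfer_config(), st)
  expect_equal(t2$am / t1$am, 2^(shift / 30.0), tolerance = 1e-9)
})

test_that("analytes with no eligible animals are omitted with a warning", {
  a <- make_animals(1)
  m <- make_measurements("A1", "muscle", "Cs137", 10)
  co <- cohort_dataset(a, m)
  expect_warning(tab <- cr_table(co, c("Cs137", "Cd"), transfer_config(),
                                 soil_t0()),
                 "no eligible animals")
  expect_equal(tab$analyte, "Cs137")
})
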