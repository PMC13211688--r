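# fixtures built in code; no files on disk

make_animals <- function(n = 3, dates = as.Date("2016-01-01") + seq_len(n)) {
  data.frame(animal_id = paste0("A", seq_len(n)),
             sampling_date = dates,
             latitude = 44 + seq_len(n) / 10,
             longitude = 15 + seq_len(n) / 10,
             region = rep(c("North", "Central", "South"), length.out = n),
             age_years = seq_len(n) / 2,
             sex = rep(c("female", "male"), length.out = n),
             body_mass_kg = 20 + 2 * seq_len(n),
             body_length_cm = 110 + 3 * seq_len(n),
             stringsAsFactors = FALSE)
}

make_measurements <- function(animal_ids, tissue, analyte, values,
                              unit = "Bq/kg", basis = "dry",
                              censored = rep(FALSE, length(values))) {
  data.frame(animal_id = animal_ids, tissue = tissue, analyte = analyte,
             value = values, unit = unit, basis = basis, censored = censored,
             stringsAsFactors = FALSE)
}

# three animals with muscle + heart Cs137 whose ratios are known by hand
make_small_cohort <- function() {
  a <- make_animals(3)
  m <- rbind(
    make_measurements(a$animal_id, "muscle", "Cs137", c(10, 20, 40)),
    make_measurements(a$animal_id, "heart", "Cs137", c(5, 15, 10)))
  cohort_dataset(a, m)
}
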