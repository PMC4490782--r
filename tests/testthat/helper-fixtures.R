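# Tiny hand-built fixtures for the deterministic modules.

# A minimal claims bundle for one or more subjects, defaulting to full
# enrollment over the study period and one dementia visit on day 300.
make_bundle <- function(pharmacy = NULL, medical = NULL, enrollment = NULL,
                        death = NULL, subjects = c("A"),
                        birth_year = 1930L,
                        config = study_config()) {
  empty_ph <- data.table(subject_id = character(0), dispense_day = integer(0),
                         days_supply = integer(0), drug_class = character(0))
  empty_md <- data.table(subject_id = character(0), service_day = integer(0),
                         primary_dx = character(0), setting = character(0))
  empty_de <- data.table(subject_id = character(0), death_day = integer(0))
  if (is.null(enrollment)) {
    enrollment <- data.table(subject_id = subjects, start_month = 0L,
                             end_month = day_to_month(config$study_end_day,
                                                      config$month_length_days))
  }
  if (!"birth_year" %in% names(enrollment)) {
    by_ <- birth_year
    enrollment <- as.data.table(enrollment)
    enrollment[, `:=`(birth_year = by_, sex = "F")]
  }
  claims_bundle(
    pharmacy = if (is.null(pharmacy)) empty_ph else as.data.table(pharmacy),
    medical = if (is.null(medical)) empty_md else as.data.table(medical),
    enrollment = enrollment,
    death = if (is.null(death)) empty_de else as.data.table(death),
    code_map = default_code_map(),
    config = config
  )
}

md_row <- function(subject_id, day, dx = "DEM01", setting = "outpatient") {
  data.table(subject_id = subject_id, service_day = as.integer(day),
             primary_dx = dx, setting = setting)
}

ph_row <- function(subject_id, day, supply = 30L, class = "ACHEI") {
  data.table(subject_id = subject_id, dispense_day = as.integer(day),
             days_supply = as.integer(supply), drug_class = class)
}

# a small simulated scenario shared by several structural tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_bundle(preset("gi_effect", n_subjects = 600,
                                       seed = 424242))
    }
    cache
  }
})
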