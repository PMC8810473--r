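test_that("packaged base cases reproduce every parameter table cell", {
  shared_transitions <- list(
    perioperative_death = c(0.035, 0.007),
    concurrent_distant_given_local = c(0.056, 0.011),
    concurrent_local_given_distant = c(0.17, 0.034),
    distant_after_local_3y = c(0.11, 0.023),
    mortality_local_salvaged_5y = c(0.50, 0.10),
    mortality_local_unsalvaged_5y = c(0.70, 0.14),
    mortality_distant_5y = c(0.80, 0.16),
    mortality_local_and_distant_5y = c(0.80, 0.16)
  )
  per_arm <- list(
    local_recurrence_2y = list(WW = c(0.19, 0.04), TME = c(0.016, 0.003)),
    local_recurrence_5y = list(WW = c(0.24, 0.05), TME = c(0.010, 0.002)),
    salvage_given_local = list(WW = c(0.94, 0.19), TME = c(0.59, 0.12)),
    distant_recurrence_5y = list(WW = c(0.10, 0.02), TME = c(0.079, 0.016))
  )
  shared_utilities <- list(
    initial_ww = c(0.80, 0.16), initial_postop = c(0.110, 0.022),
    salvage_tme_disutility_state = c(0.69, 0.14),
    local_recurrence = c(0.67, 0.13), distant_recurrence = c(0.70, 0.14),
    local_and_distant = c(0.48, 0.096)
  )
  shared_costs <- list(
    adjuvant_chemo_per_cycle = c(1890.00, 378.00),
    ostomy_care_monthly = c(93.25, 18.65),
    office_visit = c(25.95, 5.19), rectal_exam = c(9.01, 1.80),
    flex_sig = c(58.74, 11.75), cea_test = c(23.41, 4.68),
    colonoscopy = c(194.97, 38.99),
    ct_abd_pelvis = c(323.99, 64.80), ct_chest = c(161.09, 32.22),
    mri_pelvis = c(405.08, 81.02),
    restaging_local = c(2100.00, 420.00), restaging_distant = c(1200.00, 240.00),
    reirradiation_course = c(19800.00, 3960.00),
    palliative_capecitabine_per_cycle = c(510.00, 102.00),
    palliative_mfolfox6_per_cycle = c(850.00, 170.00),
    death_perioperative = c(11295.38, 2259.08),
    death_cancer = c(11295.38, 2259.08),
    death_noncancer = c(11295.38, 2259.08)
  )
  audit <- function(spec, section, expected) {
    for (nm in names(expected)) {
      p <- spec[[section]][[nm]]
      expect_equal(c(p$mean, p$sd), unname(expected[[nm]]),
                   info = paste(spec$comparison, section, nm))
    }
  }
  for (spec in list(apr_spec(), lar_spec())) {
    audit(spec, "transitions", shared_transitions)
    audit(spec, "utilities", shared_utilities)
    audit(spec, "costs", shared_costs)
    for (nm in names(per_arm)) {
      for (arm in c("WW", "TME")) {
        p <- spec$transitions[[nm]][[arm]]
        expect_equal(c(p$mean, p$sd), unname(per_arm[[nm]][[arm]]),
                     info = paste(spec$comparison, nm, arm))
      }
    }
    expect_identical(spec$utilities$death$mean, 0)
    expect_identical(spec$utilities$death$family, "fixed")
    # validation passes, flagging only the documented non-monotone TME inputs
    expect_warning(validate_spec(spec), "non-monotone")
  }
  apr <- apr_spec()
  expect_equal(c(apr$costs$surgery_apr$mean, apr$costs$surgery_apr$sd),
               c(22015.72, 4403.14))
  expect_equal(c(apr$utilities$longterm_apr$mean, apr$utilities$longterm_apr$sd),
               c(0.750, 0.15))
  expect_equal(c(apr$costs$colonoscopy_stoma$mean, apr$costs$colonoscopy_stoma$sd),
               c(164.34, 32.87))
  lar <- lar_spec()
  expect_equal(c(lar$costs$surgery_lar$mean, lar$costs$surgery_lar$sd),
               c(34662.98, 6932.60))
  expect_equal(c(lar$costs$ostomy_takedown$mean, lar$costs$ostomy_takedown$sd),
               c(906.02, 181.20))
  expect_equal(lar$utilities$longterm_lar_with_ostomy$mean, 0.70)
  expect_equal(lar$utilities$longterm_lar_without_ostomy$mean, 0.78)
  expect_equal(surgery_type(apr), "APR")
  expect_equal(surgery_type(lar), "LAR")
})

test_that("a missing sd is filled as 20% of the mean at load", {
  path <- system.file("extdata", "base_case_ww_vs_apr.yaml", package = "wwcea")
  raw <- yaml::read_yaml(path)
  raw$transitions$perioperative_death$sd <- NULL
  raw$costs$office_visit$sd <- NULL
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, tmp)
  spec <- suppressWarnings(load_spec(tmp))
  expect_equal(spec$transitions$perioperative_death$sd, 0.007)
  expect_equal(spec$costs$office_visit$sd, 0.20 * 25.95)
})

test_that("validation rejects out-of-range and incomplete configs by name", {
  path <- system.file("extdata", "base_case_ww_vs_apr.yaml", package = "wwcea")
  edit_and_load <- function(mutate) {
    raw <- yaml::read_yaml(path)
    raw <- mutate(raw)
    tmp <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    yaml::write_yaml(raw, tmp)
    suppressWarnings(load_spec(tmp))
  }
  expect_error(
    edit_and_load(function(r) { r$transitions$local_recurrence_2y$WW$mean <- 1.5; r }),
    "local_recurrence_2y.WW")
  expect_error(
    edit_and_load(function(r) { r$utilities$initial_ww$mean <- -0.2; r }),
    "initial_ww")
  expect_error(
    edit_and_load(function(r) { r$costs$surgery_apr$mean <- -10; r }),
    "surgery_apr")
  expect_error(
    edit_and_load(function(r) { r$transitions$perioperative_death <- NULL; r }),
    "perioperative_death")
  expect_error(
    edit_and_load(function(r) { r$comparison <- "WW_vs_TAE"; r }),
    "comparison")
  expect_error(
    edit_and_load(function(r) { r$surveillance$WW$pet_scan <- c(12); r }),
    "pet_scan")
  expect_error(base_case_spec("WW_vs_NOTHING"))
})

test_that("specs serialize to YAML and round-trip exactly", {
  for (spec in list(apr_spec(), lar_spec())) {
    tmp <- withr::local_tempfile(fileext = ".yaml")
    write_spec(spec, tmp)
    back <- suppressWarnings(load_spec(tmp))
    for (field in c("comparison", "timeline", "transitions", "utilities",
                    "costs", "surveillance", "life_table")) {
      expect_equal(back[[field]], spec[[field]], info = field)
    }
  }
})

test_that("parameters are addressable by dotted path", {
  spec <- apr_spec()
  expect_equal(get_param(spec, "transitions.local_recurrence_2y.WW")$mean, 0.19)
  expect_equal(get_param(spec, "costs.surgery_apr")$mean, 22015.72)
  s2 <- suppressWarnings(set_param(spec, "transitions.local_recurrence_2y.WW", 0.5))
  expect_equal(get_param(s2, "transitions.local_recurrence_2y.WW")$mean, 0.5)
  expect_equal(get_param(s2, "transitions.local_recurrence_2y.WW")$sd, 0.04)
  expect_equal(get_param(spec, "transitions.local_recurrence_2y.WW")$mean, 0.19)
  s3 <- set_param(spec, "natural_mortality_monthly", 0.01)
  expect_equal(s3$overrides$natural_mortality_monthly, 0.01)
  expect_error(set_param(spec, "transitions.not_a_parameter", 0.5), "unknown")
  expect_error(set_param(spec, "transitions.local_recurrence_2y.WW", 1.5), "\\[0, 1\\]")
})

test_that("the packaged life table is valid and loads by reference", {
  lt <- apr_spec()$life_table
  expect_true(all(lt$annual_death_probability >= 0 & lt$annual_death_probability <= 1))
  expect_true(all(diff(lt$annual_death_probability[lt$age >= 18]) >= 0))
  expect_true(all(65:70 %in% lt$age))
})
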