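test_that("minimum constraints are apomorphy-gated with a dating envelope", {
  res <- min_constraint(hominin_record())
  expect_true(res$valid)
  expect_equal(res$min_ma, 6.5)  # younger endpoint: cannot overstate a minimum
  expect_equal(res$envelope, c(younger = 6.5, older = 7.5))

  # no apomorphy-documented occurrence: explicit no-minimum, no fallback
  occ <- as.data.frame(hominin_occurrences())
  occ$apomorphy <- FALSE
  none <- quietly(min_constraint(lineage_record(occ, extant = TRUE)))
  expect_false(none$valid)
  expect_true(is.na(none$min_ma))

  # the older of two apomorphy occurrences governs
  occ2 <- as.data.frame(hominin_occurrences())
  occ2$apomorphy <- c(FALSE, TRUE, TRUE, FALSE)
  two <- min_constraint(lineage_record(occ2, extant = TRUE))
  expect_equal(two$envelope, c(younger = 5.7, older = 6.0))
})

test_that("taphonomic controls older than the FAD set the soft maximum", {
  # Clypeaster-style epochs: focal FAD in the Middle Eocene (~41 Ma mid),
  # other irregular echinoids known from the Lower Eocene and Paleocene
  focal <- lineage_record(occurrences(
    "Clypeaster", "clypeaster", c("L1", "L2"), horizon_id = c("h1", "h2"),
    age_older_ma = c(47.8, 38.0), age_younger_ma = c(41.2, 33.9),
    region = "Tethys"), extant = TRUE)
  controls <- control_occurrences(
    control_taxon = c("irregular_echinoid_A", "irregular_echinoid_B",
                      "younger_control"),
    age_older_ma = c(56.0, 66.0, 30.0),   # Lower Eocene base, Paleocene base
    age_younger_ma = c(47.8, 56.0, 23.0),
    region = "Tethys")
  res <- taphonomic_max(focal, controls)
  expect_true(res$valid)
  expect_equal(res$soft_max_ma, 56.0)    # base of the Lower Eocene
  expect_equal(res$strict_max_ma, 66.0)  # stricter: base of the Paleocene
  expect_equal(res$n_controls, 2L)

  # controls only younger than the FAD: explicit no-maximum
  young <- control_occurrences("c", 30, 23, region = "Tethys")
  expect_false(quietly(taphonomic_max(focal, young))$valid)

  # k = 2 policy with a single qualifying horizon: no maximum, warning logged
  one <- control_occurrences("c", 56, 47.8, region = "Tethys")
  expect_false(quietly(taphonomic_max(focal, one, k = 2))$valid)

  # region filter: out-of-region controls never qualify
  away <- control_occurrences("c", 60, 50, region = "Caribbean")
  expect_false(quietly(taphonomic_max(focal, away))$valid)
  expect_true(taphonomic_max(focal, away, same_region = FALSE)$valid)
})

test_that("successive-outgroup FADs pass through with validation", {
  focal <- hominin_record()
  expect_equal(outgroup_fad_max(focal, 90), 90)
  expect_error(outgroup_fad_max(focal, 5), "younger than the focal")
  degenerate <- lineage_record(occurrences("x", "x", "L1",
                                           age_older_ma = 15,
                                           age_younger_ma = 15),
                               extant = TRUE)
  expect_warning(out <- outgroup_fad_max(degenerate, 15), "degenerate")
  expect_equal(out, 15)
})

test_that("coalescence adjustment subtracts within bounds", {
  expect_equal(coalescence_adjust(10, 2), 8)
  expect_equal(coalescence_adjust(7, 0), 7)
  expect_equal(coalescence_adjust(2, 2), 0)
  expect_error(coalescence_adjust(2, 3), "exceeds")
})

test_that("apomorphy-lag widening is additive and monotone in duration", {
  expect_equal(apomorphy_lag_bound(10, 2.3), 12.3)  # mammal-like duration
  expect_equal(apomorphy_lag_bound(10, 15), 25)     # cycad-like duration
  expect_equal(apomorphy_lag_bound(10, 0), 10)
  durations <- c(0, 1, 2.3, 5, 15)
  widened <- vapply(durations, apomorphy_lag_bound,
                    numeric(1), soft_max_on_first_apomorphy = 10)
  expect_true(all(diff(widened) > 0))
})

test_that("Q metric and expected fossil species are exact ratios/products", {
  expect_equal(round(q_metric(698, 537), 2), 0.77)
  expect_equal(q_metric(50, 50), 1)
  expect_equal(q_metric(50, 0), 0)
  expect_error(q_metric(10, 11), "exceeds")

  expect_equal(expected_fossil_species(5500, 0.01, 26), 1430)
  expect_equal(expected_fossil_species(5500, 0.01, 26, rounding = "hundred"),
               1400)
  expect_equal(expected_fossil_species(5500, 1 / 5500, 26), 26)
  expect_equal(expected_fossil_species(5500, 0, 26), 0)
})

test_that("bracket assembly composes candidates without averaging", {
  rec <- hominin_record(extant = FALSE)
  mn <- min_constraint(rec)
  ci_env <- ci_record(rec, 0.95)$envelope
  br <- assemble_bracket("hominin_chimp_split", mn,
                         soft_max_candidates = c(
                           ci = unname(ci_env["older"]),
                           taphonomic = 10.0),
                         point_estimate = unbiased_origin(rec))
  expect_s3_class(br, "node_bracket")
  expect_equal(br$min_ma, 6.5)
  expect_equal(round(br$final[["max"]], 1), 12.8)   # least restrictive
  expect_equal(br$selected_method, "ci")
  expect_equal(nrow(br$soft_max), 2L)               # both reported
  # user-selected method wins over least-restrictive
  br2 <- assemble_bracket("node", mn,
                          soft_max_candidates = c(ci = 12.8, taphonomic = 10),
                          select = "taphonomic")
  expect_equal(br2$final[["max"]], 10)

  # min-only bracket: open-ended and flagged
  open <- quietly(assemble_bracket("lonely", mn))
  expect_true(open$open_ended)
  expect_true(is.na(open$final[["max"]]))

  # inconsistency is a hard error
  expect_error(assemble_bracket("bad", mn,
                                soft_max_candidates = c(ci = 5)),
               "exceeds")
  # and so is assembling without a valid minimum
  expect_error(assemble_bracket("nomin",
                                list(valid = FALSE, min_ma = NA_real_)),
               "valid minimum")
})

test_that("lag widening inside assembly shifts every candidate", {
  mn <- list(min_ma = 6.5, envelope = c(younger = 6.5, older = 7.5),
             valid = TRUE)
  br <- assemble_bracket("node", mn,
                         soft_max_candidates = c(ci = 12.8, taphonomic = 10),
                         mean_species_duration = 2.3)
  expect_equal(sort(br$soft_max$value_ma), c(12.3, 15.1))
  expect_equal(br$final[["max"]], 15.1)
  expect_true(any(grepl("apomorphy lag", br$adjustments)))
})
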