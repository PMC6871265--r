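test_that("extant-basis confidence bound matches its closed form and limits", {
  # sand-dollar worked example: FAD 4.0 Ma, 10 localities
  expect_equal(ci_extant(4.0, 10, 0.95)$T_C, 4.0 * 0.05^(-1 / 10))
  expect_equal(round(ci_extant(4.0, 10, 0.95)$T_C, 2), 5.40)
  # zero confidence returns the FAD itself
  expect_equal(ci_extant(7.7, 3, 0)$T_C, 7.7)
  # a single locality at 95%: 20-fold extension
  expect_equal(ci_extant(10, 1, 0.95)$T_C, 200)
  expect_error(ci_extant(10, 1, 1), "C")
  expect_error(ci_extant(10, 0, 0.5), "n")
})

test_that("range-basis bound reproduces the hominin envelope to 1 d.p.", {
  expect_equal(round(ci_range(7.5, 3.1, 4, 0.95)$T_C, 1), 12.8)
  expect_equal(round(ci_range(6.5, 2.1, 4, 0.95)$T_C, 1), 10.1)
  # hand-derived: R[(1-C)^(-1/(n-1)) - 1] + FAD with n=2, C=0.5 doubles R
  expect_equal(ci_range(10, 1, 2, 0.5)$T_C, 11.0)
  expect_error(ci_range(10, 1, 1, 0.5), "n")
  expect_error(ci_range(10, 0, 4, 0.5), "R")
})

test_that("record interface selects the basis from the extant flag", {
  rec <- hominin_record(extant = FALSE)
  res <- ci_record(rec, 0.95)
  expect_equal(res$basis, "range")
  expect_equal(round(unname(res$envelope["older"]), 1), 12.8)
  expect_equal(round(unname(res$envelope["younger"]), 1), 10.1)
  # override to the extant basis
  expect_equal(ci_record(rec, 0.95, basis = "extant")$basis, "extant")
})

test_that("unbiased and ML-corrected point estimates agree where they must", {
  rec <- hominin_record(extant = FALSE)
  est <- unbiased_origin(rec, envelope = TRUE)
  env <- attr(est, "envelope")
  expect_equal(round(unname(env["older"]), 1), 8.5)
  expect_equal(round(unname(env["younger"]), 1), 7.2)

  # extant case: FAD + FAD/n, equal to the finite-sample ML correction
  ages <- seq(4, 0.4, length.out = 10)
  ext <- lineage_record(occurrences("t", "l", paste0("L", 1:10),
                                    age_older_ma = ages,
                                    age_younger_ma = ages),
                        extant = TRUE)
  expect_equal(ext$n, 10L)
  expect_equal(unbiased_origin(ext), 4.4)
  expect_equal(ml_corrected_origin(4, 10), 4.4)
  expect_equal(ml_corrected_origin(7, 7), 8.0)
  # large-n limit collapses to the FAD
  expect_equal(ml_corrected_origin(4, 1e9), 4, tolerance = 1e-8)
})

test_that("extant unbiased gap matches a uniform-find simulation oracle", {
  set.seed(101)
  n <- 10; T_true <- 100; reps <- 20000
  fads <- apply(matrix(runif(reps * n, 0, T_true), reps), 1, max)
  # mean true gap vs mean estimated gap FAD/n
  expect_equal(mean(T_true - fads), mean(fads / n), tolerance = 0.02)
})

test_that("T_C is monotone in C and R, anti-monotone in n", {
  Cs <- c(0.1, 0.5, 0.8, 0.9, 0.95, 0.99)
  bounds <- vapply(Cs, function(C) ci_extant(5, 4, C)$T_C, numeric(1))
  expect_true(all(diff(bounds) > 0))
  ns <- 2:12
  bn <- vapply(ns, function(n) ci_extant(5, n, 0.95)$T_C, numeric(1))
  expect_true(all(diff(bn) < 0))
  Rs <- seq(0.5, 5, by = 0.5)
  br <- vapply(Rs, function(R) ci_range(5, R, 4, 0.95)$T_C, numeric(1))
  expect_true(all(diff(br) > 0))
  expect_true(all(bounds >= 5) && all(bn >= 5))
})

test_that("identity transform leaves the CI unchanged", {
  rec <- hominin_record(extant = FALSE)
  idmap <- data.frame(age_ma = c(0, 20), axis = c(0, 20))
  expect_equal(ci_transformed(rec, 0.95, mapping = idmap)$T_C,
               ci_record(rec, 0.95)$T_C)
  rec2 <- hominin_record(extant = TRUE)
  expect_equal(ci_transformed(rec2, 0.95, mapping = idmap)$T_C,
               ci_extant(rec2$fad_ma, rec2$n, 0.95)$T_C)
})

test_that("thickness transform deepens the bound when old units are thick", {
  # toy stack: ages 0-4 Ma span axis 0-4 (1 unit/Myr), but the 4-5 Ma
  # formation is condensed in time yet half the section: axis 4-12
  rec <- lineage_record(occurrences(
    taxon_id = "t", lineage_id = "l", locality_id = paste0("L", 1:4),
    horizon_id = paste0("h", 1:4),
    age_older_ma = c(4, 3, 2, 1), age_younger_ma = c(4, 3, 2, 1),
    axis_position = c(4, 3, 2, 1)), extant = TRUE)
  mapping <- data.frame(age_ma = c(0, 4, 5), axis = c(0, 4, 12))
  res <- ci_transformed(rec, 0.95, mapping = mapping)
  plain <- ci_extant(4, 4, 0.95)$T_C
  # hand computation on the piecewise map: axis bound 4*20^(1/4) = 8.459,
  # inverse map: 4 + (8.459-4)/8 Myr = 4.557 Ma < 8.459 Ma... the bound in
  # *axis* units is the same, but mapped back it reflects the thick unit
  axis_bound <- 4 * 0.05^(-1 / 4)
  expect_equal(res$axis_bound, axis_bound)
  expect_equal(res$T_C, 4 + (axis_bound - 4) / 8)
  # direction when the OLD unit is thick per Myr: bound in Ma shrinks;
  # conversely a condensed old unit (thin axis per Myr) deepens the bound
  mapping2 <- data.frame(age_ma = c(0, 4, 5), axis = c(0, 4, 4.5))
  res2 <- ci_transformed(rec, 0.95, mapping = mapping2)
  expect_equal(res2$T_C, 4 + (axis_bound - 4) / 0.5)
  expect_gt(res2$T_C, plain)
  expect_error(ci_transformed(rec, 0.95,
                              mapping = data.frame(age_ma = c(0, 1, 2),
                                                   axis = c(0, 2, 1))),
               "monotone")
})

test_that("nonuniform-recovery CI reduces to the constant-rate bound", {
  flat <- recovery_curve(c(0, 500), 1)
  for (n in c(1L, 3L, 7L)) {
    expect_equal(ci_nonuniform(4.0, flat, 0.95, n = n)$T_C,
                 ci_extant(4.0, n, 0.95)$T_C, tolerance = 1e-9)
  }
  # rate constant but != 1 must make no difference (relative rates)
  flat2 <- recovery_curve(c(0, 500), 0.25)
  expect_equal(ci_nonuniform(4.0, flat2, 0.95, n = 5)$T_C,
               ci_extant(4.0, 5, 0.95)$T_C, tolerance = 1e-9)
})

test_that("nonuniform CI matches a bisection oracle on a step curve", {
  curve <- recovery_curve(c(0, 50, 300), c(1, 0.2))
  FAD <- 40; n <- 5L; C <- 0.95
  # independent oracle: brute-force bisection on (G(FAD)/G(T))^n = 1 - C
  # with G assembled by hand from the two segments
  G <- function(t) ifelse(t <= 50, t, 50 + 0.2 * (t - 50))
  lo <- FAD; hi <- 300
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if ((G(FAD) / G(mid))^n > 1 - C) lo <- mid else hi <- mid
  }
  expect_equal(ci_nonuniform(FAD, curve, C, n = n)$T_C, (lo + hi) / 2,
               tolerance = 1e-7)
  # bound is strictly deeper than under constant recovery
  expect_gt(ci_nonuniform(FAD, curve, C, n = n)$T_C,
            ci_extant(FAD, n, C)$T_C)
})

test_that("insufficient recovery potential reports unbounded, not an error", {
  curve <- recovery_curve(c(0, 50, 60), c(1, 0.01))
  res <- quietly(ci_nonuniform(40, curve, 0.95, n = 2L))
  expect_true(res$unbounded)
  expect_true(is.na(res$T_C))
})

test_that("range-basis nonuniform CI reduces to ci_range on a flat curve", {
  rec <- hominin_record(extant = FALSE)
  flat <- recovery_curve(c(0, 500), 1)
  expect_equal(ci_nonuniform(rec, flat, 0.95)$T_C,
               ci_record(rec, 0.95)$T_C, tolerance = 1e-9)
})
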