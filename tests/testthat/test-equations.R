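test_that("energy conversion uses the thermochemical calorie and round-trips", {
  expect_equal(convert_energy(4184, "kJ_per_day", "kcal_per_day"), 1000)
  expect_equal(convert_energy(1, "MJ_per_day", "kcal_per_day"), 1000 / 4.184)
  expect_equal(convert_energy(0, "MJ_per_day", "kJ_per_day"), 0)
  expect_error(convert_energy(1, "cal_per_day", "kcal_per_day"), "unknown energy unit")
  set.seed(42)
  units <- c("kcal_per_day", "kJ_per_day", "MJ_per_day")
  for (i in 1:20) {
    x <- stats::runif(1, 0, 5000)
    from <- sample(units, 1); to <- sample(units, 1)
    expect_equal(convert_energy(convert_energy(x, from, to), to, from), x)
  }
})

test_that("the registry holds the 14 published equations as printed", {
  reg <- ree_equations()
  expect_length(reg, 14)
  expect_setequal(names(reg),
                  c("who", "schofield", "iom", "kim", "henry", "molnar",
                    "muller_a", "muller_b", "derumeaux_burel", "schmelzle",
                    "tverskaya", "lazzer_a", "lazzer_b", "new_ffm"))
  expect_identical(reg$lazzer_a$native_unit, "kJ_per_day")
  expect_true("height_m" %in% names(reg$lazzer_a$variants[[1]]$coef))
  expect_equal(reg$tverskaya$sex_code, c(male = 1, female = 0))
  expect_equal(reg$molnar$sex_code, c(male = 0, female = 1))
  expect_equal(reg$muller_a$sex_code, c(male = 0, female = 1))
  expect_equal(reg$new_ffm$variants[[1]]$coef,
               c(intercept = 505.412, fat_free_mass = 24.383))
  # registry is a fresh copy each call: mutation does not stick
  reg$who$variants[[1]]$coef["weight"] <- 999
  expect_equal(ree_equations()$who$variants[[1]]$coef[["weight"]], 22.7)
  # variants partition (sex, age): no overlaps within an equation
  for (spec in reg) {
    for (sx in c("male", "female")) {
      vs <- Filter(function(v) v$sex %in% c("all", sx), spec$variants)
      los <- sort(vapply(vs, function(v) v$age_lo, numeric(1)))
      his <- sort(vapply(vs, function(v) v$age_hi, numeric(1)))
      if (length(vs) > 1) expect_true(all(utils::head(his, -1) <= utils::tail(los, -1) + 1e-12))
    }
  }
})

test_that("every equation matches its hand-computed fixture points to 0.01 kcal/d", {
  fixture <- utils::read.csv(test_path("fixtures", "equation_points.csv"),
                             stringsAsFactors = FALSE)
  reg <- ree_equations()
  expect_setequal(unique(fixture$equation_id), names(reg))
  for (i in seq_len(nrow(fixture))) {
    row <- fixture[i, ]
    pred <- predict_ree(reg[[row$equation_id]], list(
      sex = row$sex, age = row$age, weight = row$weight, height = row$height,
      fat_mass = row$fat_mass, fat_free_mass = row$fat_free_mass))
    # fixture values are frozen at 4 decimals; the acceptance band is 0.01
    expect_lt(abs(pred$predicted_ree - row$expected_kcal_d), 0.01,
              label = sprintf("|%s [%s] - expected|", row$equation_id,
                              row$arithmetic))
  }
})

test_that("spec worked examples evaluate exactly", {
  reg <- ree_equations()
  expect_equal(predict_ree(reg$new_ffm, list(sex = "female", age = 12,
                                             fat_free_mass = 41.6))$predicted_ree,
               1519.7448, tolerance = 1e-6)
  expect_equal(predict_ree(reg$who, list(sex = "male", age = 12,
                                         weight = 60))$predicted_ree, 1755.0)
  expect_equal(predict_ree(reg$schmelzle, list(sex = "female", age = 10,
                                               weight = 50, height = 150))$predicted_ree,
               1300.0)
  expect_equal(predict_ree(reg$molnar, list(sex = "female", age = 12, weight = 50,
                                            height = 150))$predicted_ree,
               5260.3 / 4.184, tolerance = 1e-6)
})

test_that("age dispatch is total, unambiguous, and splits child/adolescent at 10", {
  reg <- ree_equations()
  # under-10 male uses the child variants of WHO/Schofield/Henry
  sub8 <- list(sex = "male", age = 8, weight = 30, height = 130)
  expect_equal(predict_ree(reg$who, sub8)$predicted_ree, 22.7 * 30 + 495)
  expect_equal(predict_ree(reg$henry, sub8)$predicted_ree,
               15.1 * 30 + 0.742 * 130 + 306)
  # age exactly 10 goes to the adolescent bracket
  sub10 <- list(sex = "male", age = 10, weight = 35, height = 140)
  expect_equal(predict_ree(reg$who, sub10)$predicted_ree, 18.4 * 35 + 651)
  # totality: every (sex, age) in [3,18] yields exactly one finite prediction
  for (spec in reg) {
    for (sx in c("male", "female")) {
      for (age in seq(3, 18, by = 0.5)) {
        p <- predict_ree(spec, list(sex = sx, age = age, weight = 40,
                                    height = 145, fat_mass = 10,
                                    fat_free_mass = 30))
        expect_true(is.finite(p$predicted_ree))
      }
    }
  }
})

test_that("out-of-stated-range subjects are evaluated and flagged; strict mode refuses", {
  reg <- ree_equations()
  sub17 <- list(sex = "male", age = 17, weight = 70, height = 175,
                fat_mass = 15, fat_free_mass = 55)
  p <- predict_ree(reg$kim, sub17)
  expect_true(p$out_of_stated_range)
  expect_equal(p$predicted_ree, 632.4 + 15.66 * 17 + 9.53 * 70)
  expect_false(predict_ree(reg$iom, sub17)$out_of_stated_range)
  expect_true(predict_ree(reg$schmelzle, sub17)$out_of_stated_range)
  expect_error(predict_ree(reg$kim, sub17, strict_age_range = TRUE),
               "outside the stated range")
})

test_that("missing required fields give named inapplicability errors", {
  reg <- ree_equations()
  expect_error(predict_ree(reg$new_ffm, list(sex = "male", age = 12, weight = 40)),
               "fat_free_mass")
  expect_error(predict_ree(reg$schofield, list(sex = "male", age = 12, weight = 40)),
               "height")
})

test_that("predict_all scores all pairs and records inapplicable ones", {
  co <- tiny_cohort()
  preds <- predict_all(co)
  expect_equal(nrow(preds), nrow(co) * 14)
  expect_true(all(is.na(preds$inapplicable_reason)))
  # drop FFM: the five body-composition equations become inapplicable
  co2 <- co
  co2$fat_free_mass[1] <- NA
  preds2 <- predict_all(co2)
  bad <- preds2[preds2$id == "a" & !is.na(preds2$inapplicable_reason), ]
  expect_setequal(bad$equation_id,
                  c("muller_b", "derumeaux_burel", "tverskaya", "lazzer_b",
                    "new_ffm"))
  ok <- preds2[preds2$id == "a" & is.na(preds2$inapplicable_reason), ]
  expect_equal(nrow(ok), 9)
  expect_error(predict_all(co[0, ]), "empty")
  expect_error(predict_all(co, "harris_benedict"), "unknown equation")
})

test_that("predictions are strictly positive over the plausible pediatric box", {
  reg <- ree_equations()
  set.seed(7)
  for (i in 1:200) {
    sub <- list(sex = sample(c("male", "female"), 1),
                age = stats::runif(1, 6, 18),
                weight = stats::runif(1, 15, 120),
                height = stats::runif(1, 100, 195),
                fat_free_mass = stats::runif(1, 10, 90),
                fat_mass = stats::runif(1, 1, 60))
    for (spec in reg) {
      expect_gt(predict_ree(spec, sub)$predicted_ree, 0)
    }
  }
})
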