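test_that("recall decomposition follows mass proportions and is additive", {
  comp <- tibble::tibble(food_id = "F1", commodity_id = c("A", "B"),
                         fraction = c(0.4, 0.6))
  rec <- tibble::tibble(subject_id = "S1", food_id = "F1", grams_consumed = 100)
  out <- decompose_recalls(rec, comp)
  expect_equal(out$mass_g[match(c("A", "B"), out$commodity_id)], c(40, 60))

  # splitting a record into parts changes nothing
  rec2 <- tibble::tibble(subject_id = "S1", food_id = c("F1", "F1"),
                         grams_consumed = c(50, 50))
  expect_equal(decompose_recalls(rec2, comp), out)

  # empty input, unknown food
  empty <- decompose_recalls(rec[0, ], comp)
  expect_equal(nrow(empty), 0L)
  rec_bad <- tibble::tibble(subject_id = "S1", food_id = "NOPE",
                            grams_consumed = 10)
  expect_error(decompose_recalls(rec_bad, comp), "NOPE",
               class = "fructuric_lookup_error")
})

test_that("fructose fraction resolution uses direct values or family ratios", {
  ref <- hand_nutrients()
  apple <- resolve_fructose_fraction(ref[ref$commodity_id == "APPLE", ], ref)
  expect_equal(apple$fraction, 0.059)
  expect_equal(apple$provenance, "direct")

  juice <- resolve_fructose_fraction(ref[ref$commodity_id == "APPLE_JUICE", ], ref)
  expect_equal(juice$fraction, (11.0 / 100) * (5.9 / 13.8), tolerance = 1e-12)
  expect_equal(juice$provenance, "ratio_imputed")

  # worked ratio example: carb 10, family fructose 2.25 / carb 11.54
  ref2 <- tibble::tibble(
    commodity_id = c("OJ", "OR"), fructose_per_100g = c(NA, 2.25),
    carb_per_100g = c(10, 11.54), family_id = c("OR", NA)
  )
  oj <- resolve_fructose_fraction(ref2[1, ], ref2)
  expect_equal(oj$fraction, 0.10 * (2.25 / 11.54), tolerance = 1e-12)
  expect_equal(round(oj$fraction, 4), 0.0195)

  # zero-carbohydrate family member cannot donate a ratio
  ref3 <- ref2
  ref3$carb_per_100g[2] <- 0
  expect_error(resolve_fructose_fraction(ref3[1, ], ref3),
               class = "fructuric_lookup_error")
  # no direct value and no family link
  ref4 <- ref2
  ref4$family_id[1] <- NA
  expect_error(resolve_fructose_fraction(ref4[1, ], ref4),
               class = "fructuric_lookup_error")
})

test_that("corn sweetener partition weights components by disappearance shares", {
  mix <- hand_mix()
  expect_equal(partition_corn_sweetener(100, mix), 44.3)
  expect_equal(partition_corn_sweetener(0, mix), 0)
  one <- sweetener_mix(1, 0, 0)
  expect_equal(partition_corn_sweetener(10, one), 5.5)
  expect_error(sweetener_mix(0.5, 0.4, 0.2), class = "fructuric_config_error")
  expect_error(partition_corn_sweetener(-1, mix),
               class = "fructuric_domain_error")
})

test_that("bound fructose is half of added sucrose", {
  expect_equal(added_bound_fructose(20), 10)
  expect_equal(added_bound_fructose(0), 0)
  expect_equal(added_bound_fructose(99.86), 49.93)
  expect_error(added_bound_fructose(-1), class = "fructuric_domain_error")
})

test_that("intake components match a hand-computed spreadsheet oracle to 1e-9", {
  out <- estimate_intakes(hand_recalls(), hand_composition(), hand_nutrients(),
                          hand_mix(), hand_energy())
  s1 <- out[out$subject_id == "S1", ]
  # hand arithmetic: 200 g juice drink -> 100 g apple juice + 12 g corn
  # sweetener; 100 g pie -> 30 g apple + 25 g wheat + 15 g cane sugar
  nat <- 100 * (0.11 * 5.9 / 13.8) + 30 * 0.059
  addunb <- 12 * (0.5 * 0.55 + 0.4 * 0.42)
  bound <- 0.5 * (15 * 1.0)
  expect_equal(s1$natural_unbound_g, nat, tolerance = 1e-9)
  expect_equal(s1$added_unbound_g, addunb, tolerance = 1e-9)
  expect_equal(s1$added_bound_g, bound, tolerance = 1e-9)
  expect_equal(s1$all_added_g, addunb + bound, tolerance = 1e-9)
  expect_equal(s1$total_g, nat + addunb + bound, tolerance = 1e-9)
  expect_equal(s1$total_pct_energy, 100 * 4 * (nat + addunb + bound) / 2000,
               tolerance = 1e-9)
  # subject eating only bread: no fructose from any component
  s2 <- out[out$subject_id == "S2", ]
  expect_equal(s2$total_g, 0)
  expect_equal(s2$all_added_g, 0)
  # audit records provenance per commodity
  audit <- attr(out, "audit")
  expect_equal(audit$provenance[audit$commodity_id == "APPLE_JUICE"],
               "ratio_imputed")
  expect_equal(audit$provenance[audit$commodity_id == "APPLE"], "direct")
})

test_that("pure added-sugar and pure-fruit diets obey the component rules", {
  ref <- hand_nutrients()
  comp <- tibble::tibble(food_id = c("SUGAR_FOOD", "FRUIT_FOOD"),
                         commodity_id = c("SUGAR_CB", "APPLE"),
                         fraction = c(1, 1))
  en <- tibble::tibble(subject_id = c("A", "B"), energy_kcal = 2000)
  # 100 g of a pure-sucrose added sugar: all bound, half the mass
  rec <- tibble::tibble(subject_id = "A", food_id = "SUGAR_FOOD",
                        grams_consumed = 100, reliable = TRUE)
  out <- estimate_intakes(rec, comp, ref, hand_mix(), en[1, ])
  expect_equal(out$natural_unbound_g, 0)
  expect_equal(out$added_unbound_g, 0)
  expect_equal(out$added_bound_g, 50)
  expect_equal(out$total_g, 50)
  # fruit only: everything natural
  rec2 <- tibble::tibble(subject_id = "B", food_id = "FRUIT_FOOD",
                         grams_consumed = 250, reliable = TRUE)
  out2 <- estimate_intakes(rec2, comp, ref, hand_mix(), en[2, ])
  expect_equal(out2$all_added_g, 0)
  expect_equal(out2$total_g, out2$natural_unbound_g)
  expect_equal(out2$natural_unbound_g, 250 * 0.059, tolerance = 1e-12)
})

test_that("intake estimation is monotone in grams and additive over records", {
  base <- hand_recalls()
  out0 <- estimate_intakes(base, hand_composition(), hand_nutrients(),
                           hand_mix(), hand_energy())
  # split every record in two
  split_rec <- dplyr::bind_rows(
    dplyr::mutate(base, grams_consumed = grams_consumed * 0.3),
    dplyr::mutate(base, grams_consumed = grams_consumed * 0.7)
  )
  out_split <- estimate_intakes(split_rec, hand_composition(), hand_nutrients(),
                                hand_mix(), hand_energy())
  comp_cols <- c("natural_unbound_g", "added_unbound_g", "added_bound_g",
                 "all_added_g", "total_g")
  expect_equal(out_split[comp_cols], out0[comp_cols], tolerance = 1e-12)

  # increasing any food's grams weakly increases every component
  for (i in seq_len(nrow(base))) {
    up <- base
    up$grams_consumed[i] <- up$grams_consumed[i] + 50
    out_up <- estimate_intakes(up, hand_composition(), hand_nutrients(),
                               hand_mix(), hand_energy())
    for (v in comp_cols) {
      expect_true(all(out_up[[v]] >= out0[[v]] - 1e-12))
    }
  }
})

test_that("zero-energy subjects get flagged undefined percent-energy", {
  en <- tibble::tibble(subject_id = c("S1", "S2"), energy_kcal = c(0, 1800))
  out <- estimate_intakes(hand_recalls(), hand_composition(), hand_nutrients(),
                          hand_mix(), en)
  expect_true(out$energy_flag[out$subject_id == "S1"])
  expect_true(is.na(out$total_pct_energy[out$subject_id == "S1"]))
  expect_false(out$energy_flag[out$subject_id == "S2"])
})

test_that("natural bound fructose underestimate clamps and scales correctly", {
  expect_equal(round(natural_bound_underestimate(135.91, 99.86, 14.49, 0.2653), 2),
               2.86)
  expect_equal(natural_bound_underestimate(100, 100, 0, 0.2653), 0)
  expect_equal(natural_bound_underestimate(50, 20, 10, 0.5), 5.0)
  # negative remainder clamps rather than going negative
  expect_equal(natural_bound_underestimate(50, 60, 10, 0.5), 0)
  expect_error(natural_bound_underestimate(50, 20, 10, 1.2),
               class = "fructuric_domain_error")
})
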