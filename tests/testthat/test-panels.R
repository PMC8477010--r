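# A toy GSEA record table emulating the study's panel results: ASD-up
# sets negatively enriched, ASD-risk (down-in-ASD) sets positively
# enriched -> a reverse-ASD profile.
toy_records <- function(nes, q, sets = names(nes)) {
  data.frame(set = sets, size = 50, es = sign(nes) * 0.5, nes = nes,
             pval = 0.01, fdr_q = q, significant = q < 0.05,
             stringsAsFactors = FALSE)
}

toy_panel <- panel_spec(
  c("DEG_Up", "CoExp_Up", "DEG_Down", "SFARI_all", "FMRP"),
  c("up_in_ASD", "up_in_ASD", "down_in_ASD", "down_in_ASD", "down_in_ASD"))

test_that("pattern classification mirrors the panel direction logic", {
  rec <- toy_records(nes = c(DEG_Up = -2.1, CoExp_Up = -1.8,
                             DEG_Down = 0.3, SFARI_all = 2.5, FMRP = 1.9),
                     q = c(0.01, 0.02, 0.8, 0.001, 0.03))
  call <- classify_pattern(rec, toy_panel, group = "Veh-K/W")
  expect_equal(call$label, "reverse-ASD")
  expect_equal(call$n_reverse, 4)
  expect_equal(call$n_like, 0)
  expect_equal(call$strength, 2.1 + 1.8 + 2.5 + 1.9)
  expect_equal(call$sets$concordance[call$sets$set_name == "DEG_Down"],
               "null")

  # nothing significant -> indeterminate
  none <- classify_pattern(toy_records(
    nes = c(DEG_Up = -2, CoExp_Up = -2, DEG_Down = 1, SFARI_all = 1,
            FMRP = 1), q = rep(0.2, 5)), toy_panel)
  expect_equal(none$label, "indeterminate")
  expect_equal(none$strength, 0)

  # flipping every NES converts reverse-ASD to ASD-like, equal strength
  flipped <- rec
  flipped$nes <- -rec$nes
  anti <- classify_pattern(flipped, toy_panel)
  expect_equal(anti$label, "ASD-like")
  expect_equal(anti$strength, -call$strength)
  expect_equal(anti$n_like, call$n_reverse)

  # invariant to record ordering
  perm <- classify_pattern(rec[c(4, 2, 5, 1, 3), ], toy_panel)
  expect_equal(perm$sets, call$sets)
  expect_equal(perm$label, call$label)

  # panel sets missing from the records are warned about, counted null
  expect_warning(part <- classify_pattern(rec[1:3, ], toy_panel),
                 "missing")
  expect_equal(part$n_reverse, 2)
  expect_error(classify_pattern(rec[0, ], toy_panel), "no panel set")
})

test_that("pattern comparison detects weakening and strengthening", {
  a <- classify_pattern(toy_records(
    nes = c(DEG_Up = -2.1, CoExp_Up = -1.8, DEG_Down = 0.3,
            SFARI_all = 2.5, FMRP = 1.9),
    q = c(0.01, 0.02, 0.8, 0.001, 0.03)), toy_panel)
  expect_equal(compare_patterns(a, a)$verdict, "unchanged")

  # one significant risk set lost, every |NES| reduced -> weakened
  b <- classify_pattern(toy_records(
    nes = c(DEG_Up = -1.2, CoExp_Up = -1.1, DEG_Down = 0.2,
            SFARI_all = 1.4, FMRP = 1.0),
    q = c(0.03, 0.04, 0.9, 0.3, 0.04)), toy_panel)
  cmp <- compare_patterns(a, b)
  expect_equal(cmp$verdict, "weakened")
  expect_equal(cmp$n_concordant_a, 4)
  expect_equal(cmp$n_concordant_b, 3)
  expect_true(all(cmp$deltas$d_nes[c(1, 2)] > 0))  # negative NES shrank
  expect_equal(compare_patterns(b, a)$verdict, "strengthened")

  other <- panel_spec("X", "up_in_ASD")
  c2 <- classify_pattern(toy_records(nes = c(X = -2), q = 0.01), other)
  expect_error(compare_patterns(a, c2), "different panels")
})

test_that("panel specs and pattern calls serialize faithfully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_spec(toy_panel, path)
  expect_equal(as.data.frame(read_panel_spec(path)),
               as.data.frame(toy_panel))
  expect_error(panel_spec(c("a", "a"), rep("up_in_ASD", 2)), "duplicate")
  expect_error(panel_spec("a", "sideways"), "expected_direction")

  call <- classify_pattern(toy_records(
    nes = c(DEG_Up = -2.1, CoExp_Up = -1.8, DEG_Down = 0.3,
            SFARI_all = 2.5, FMRP = 1.9),
    q = c(0.01, 0.02, 0.8, 0.001, 0.03)), toy_panel, group = "Veh-K/W")
  jpath <- withr::local_tempfile(fileext = ".json")
  write_pattern_call(call, jpath)
  parsed <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(parsed$label, "reverse-ASD")
  expect_equal(parsed$strength, call$strength)
  expect_equal(nrow(parsed$sets), 5)
})
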