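small_mimetic <- function(composition, seed, co_entry_prob = 0, ...) {
  mimetic_spec(composition, diameter_range_um = c(100, 150),
               image_shape = c(200L, 200L), co_entry_prob = co_entry_prob,
               seed = seed, ...)
}

test_that("a clean stream of positives sorts with yield and accuracy one", {
  frames <- generate_mimetic(small_mimetic(c(CLASS1_RED_HOMOG = 8), seed = 1,
                                           noise_sigma = 0,
                                           label_jitter_sd = 0))
  rep <- run_sort(frames, criteria_preset("TEST1_CLASS1"), "CLASS1_RED_HOMOG")
  expect_identical(rep$yield, 1)
  expect_identical(rep$accuracy, 1)
  expect_identical(rep$true_positives, 8L)
})

test_that("clean-limit yield and accuracy reach one for every preset", {
  cases <- list(
    list(preset = "TEST1_CLASS1", pos = "CLASS1_RED_HOMOG",
         mix = c(CLASS1_RED_HOMOG = 4, CLASS2_GREEN_HOMOG = 4, UNLABELED = 3)),
    list(preset = "TEST2_CLASS2", pos = "CLASS2_GREEN_HOMOG",
         mix = c(CLASS2_GREEN_HOMOG = 4, CLASS1_RED_HOMOG = 4, UNLABELED = 3)),
    list(preset = "TEST3_CLASS3", pos = "CLASS3_DUAL_HOMOG",
         mix = c(CLASS3_DUAL_HOMOG = 4, CLASS2_GREEN_HOMOG = 4, UNLABELED = 3)),
    list(preset = "TEST4_CLASS6", pos = "CLASS6_RED_NARROW_HALO",
         mix = c(CLASS6_RED_NARROW_HALO = 4, CLASS4_RED_BROAD_HALO = 3,
                 CLASS7_GREEN_BROAD_HALO = 3, UNLABELED = 3)),
    list(preset = "TEST5_CLASS5", pos = "CLASS5_RED_MEDIUM_HALO",
         mix = c(CLASS5_RED_MEDIUM_HALO = 4, CLASS4_RED_BROAD_HALO = 3,
                 CLASS7_GREEN_BROAD_HALO = 3, UNLABELED = 3)))
  for (cs in cases) {
    frames <- generate_mimetic(small_mimetic(cs$mix, seed = 77,
                                             noise_sigma = 0,
                                             label_jitter_sd = 0))
    rep <- run_sort(frames, criteria_preset(cs$preset), cs$pos)
    expect_identical(rep$yield, 1)
    expect_identical(rep$accuracy, 1)
  }
})

test_that("conservation identities hold on every run", {
  frames <- generate_mimetic(small_mimetic(
    c(CLASS1_RED_HOMOG = 5, CLASS2_GREEN_HOMOG = 5, UNLABELED = 4), seed = 5))
  rep <- run_sort(frames, criteria_preset("TEST1_CLASS1"), "CLASS1_RED_HOMOG")
  expect_identical(rep$true_positives + rep$false_positives,
                   rep$total_collected)
  expect_identical(rep$true_positives + rep$false_negatives,
                   rep$positives_fed)
  n_beads <- sum(vapply(frames, function(f) length(f$truth_classes), 1L))
  expect_identical(rep$true_positives + rep$false_positives +
                     rep$false_negatives + rep$true_negatives, n_beads)
})

test_that("a stream without positives reports NA yield", {
  frames <- generate_mimetic(small_mimetic(c(CLASS2_GREEN_HOMOG = 4), seed = 3))
  rep <- run_sort(frames, criteria_preset("TEST1_CLASS1"), "CLASS1_RED_HOMOG")
  expect_true(is.na(rep$yield))
  expect_identical(rep$total_collected, 0L)
  expect_identical(rep$accuracy, 1)   # vacuous: nothing collected
})

test_that("valve traces follow the canonical flowchart sequences", {
  frames <- generate_mimetic(small_mimetic(
    c(CLASS1_RED_HOMOG = 3, CLASS2_GREEN_HOMOG = 3, UNLABELED = 2), seed = 7))
  rep <- run_sort(frames, criteria_preset("TEST1_CLASS1"), "CLASS1_RED_HOMOG")
  expect_true(all(rep$outcomes$valve_trace %in%
                    c("load", "load trap route_positive",
                      "load trap route_negative")))
  expect_true(all(rep$outcomes$routed_to[rep$outcomes$decision == "positive"]
                  == "positive"))
  # undetected frames never leave the load state
  expect_true(all(rep$outcomes$valve_trace[rep$outcomes$decision == "absent"]
                  == "load"))
  # the four valve configurations
  expect_identical(unname(valve_state("load")["imaging"]), "open")
  expect_identical(unname(valve_state("trap")["imaging"]), "closed")
  expect_identical(unname(valve_state("route_positive")["negative_outlet"]),
                   "closed")
  expect_identical(unname(valve_state("route_negative")["positive_outlet"]),
                   "closed")
})

test_that("co-entered beads of different classes are routed jointly", {
  frames <- generate_mimetic(small_mimetic(
    c(CLASS1_RED_HOMOG = 3, CLASS2_GREEN_HOMOG = 3),
    seed = 13, co_entry_prob = 1,
  ))
  rep <- run_sort(frames, criteria_preset("TEST1_CLASS1"), "CLASS1_RED_HOMOG")
  mixed <- grepl("CLASS1_RED_HOMOG", rep$outcomes$truth_classes) &
    grepl("CLASS2_GREEN_HOMOG", rep$outcomes$truth_classes)
  # 3 + 3 beads paired up must yield at least one mixed pair (odd counts)
  expect_true(any(mixed))
  # every mixed frame necessarily mis-routes one of its two beads
  expect_gt(rep$false_positives + rep$false_negatives, 0)
})

test_that("single-bead mode assigns sequential wells and pauses", {
  frames <- generate_mimetic(small_mimetic(c(CLASS1_RED_HOMOG = 3), seed = 17))
  rep <- run_sort(frames, criteria_preset("TEST1_CLASS1"), "CLASS1_RED_HOMOG",
                  mode = "single")
  pos <- rep$outcomes[rep$outcomes$routed_to == "positive", ]
  expect_identical(pos$well, c("A1", "A2", "A3"))
  expect_true(all(pos$pause))
  # bulk mode emits no pause events or wells
  repb <- run_sort(frames, criteria_preset("TEST1_CLASS1"), "CLASS1_RED_HOMOG")
  expect_false(any(repb$outcomes$pause))
  expect_true(all(is.na(repb$outcomes$well)))
})

test_that("the 97th positive wraps the well plate with a warning", {
  expect_identical(well_for_positive(1), "A1")
  expect_identical(well_for_positive(13), "B1")
  expect_identical(well_for_positive(96), "H12")
  expect_warning(w <- well_for_positive(97), "wraps")
  expect_identical(w, "A1")
})
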