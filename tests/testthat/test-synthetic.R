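test_that("rendered frames stay in the 12-bit integer range", {
  for (id in c("CLASS1_RED_HOMOG", "CLASS5_RED_MEDIUM_HALO", "UNLABELED")) {
    fr <- quick_render(id, seed = 3)
    for (ch in c("red", "green")) {
      expect_type(fr$image[[ch]], "integer")
      expect_gte(min(fr$image[[ch]]), 0)
      expect_lte(max(fr$image[[ch]]), 4095)
    }
  }
})

test_that("unlabeled beads carry only background signal", {
  fr <- quick_render("UNLABELED", seed = 5)
  disk <- fr$truth_masks[[1]]
  expect_lt(oracle_percentile(fr$image$red[disk] / 4095, 99), 0.1)
  expect_lt(oracle_percentile(fr$image$green[disk] / 4095, 99), 0.1)
})

test_that("homogeneous red bead metrics clear the red/green thresholds", {
  m <- quick_metrics("CLASS1_RED_HOMOG", seed = 7)
  expect_gt(m$p90_er, 0.5)
  expect_lt(m$p90_eg, 0.2)
})

test_that("narrow-halo bead is strongly inhomogeneous in red", {
  m <- quick_metrics("CLASS6_RED_NARROW_HALO", diameter_um = 150, seed = 7)
  expect_gt(m$alpha_er, 0.15)
  expect_gt(m$alpha_er - m$alpha_eg, 0)
})

test_that("halo classes are brighter in the shell than in the core (noise-free)", {
  for (id in c("CLASS4_RED_BROAD_HALO", "CLASS5_RED_MEDIUM_HALO",
               "CLASS6_RED_NARROW_HALO")) {
    spec <- default_class_spec(id)
    fr <- quick_render(id, diameter_um = 150, seed = 2, noise_sigma = 0,
                       label_jitter_sd = 0)
    disk <- fr$truth_masks[[1]]
    center <- c(100.5, 100.5)
    r <- 75
    shell <- disk & !disk_mask(c(200L, 200L), center, (1 - spec$halo_penetration) * r)
    core <- disk & !shell
    red <- fr$image$red / 4095
    expect_gt(mean(red[shell]) - mean(red[core]), 0.01)
  }
})

test_that("truth disk area matches the analytic disk", {
  for (d in c(60, 120, 190)) {
    fr <- quick_render("CLASS1_RED_HOMOG", diameter_um = d, seed = 1)
    expect_equal(sum(fr$truth_masks[[1]]), pi * (d / 2)^2,
                 tolerance = 0.05)
  }
})

test_that("rendering validates diameter against pixel scale and field", {
  spec <- default_class_spec("CLASS1_RED_HOMOG")
  expect_error(render_bead(spec, diameter_um = -5), "positive")
  expect_error(render_bead(spec, diameter_um = 10), "20 pixels")
  expect_error(render_bead(spec, diameter_um = 400, image_shape = c(350, 350)),
               "field of view")
})

test_that("mimetic stream has exact composition and one bead per frame", {
  spec <- mimetic_spec(c(CLASS1_RED_HOMOG = 18, CLASS2_GREEN_HOMOG = 20,
                         UNLABELED = 20),
                       diameter_range_um = c(100, 150),
                       image_shape = c(200L, 200L), seed = 11)
  frames <- generate_mimetic(spec)
  expect_length(frames, 58)
  expect_true(all(vapply(frames, function(f) length(f$truth_classes), 1L) == 1))
  counts <- table(vapply(frames, function(f) f$truth_classes, ""))
  expect_equal(unname(counts[c("CLASS1_RED_HOMOG", "CLASS2_GREEN_HOMOG",
                               "UNLABELED")]),
               c(18L, 20L, 20L), ignore_attr = TRUE)
  # masks stay inside the frame
  expect_true(all(vapply(frames, function(f) {
    all(dim(f$truth_masks[[1]]) == c(200L, 200L))
  }, TRUE)))
})

test_that("identical seeds replay bit-identical mimetic streams", {
  spec <- mimetic_spec(c(CLASS3_DUAL_HOMOG = 3, CLASS6_RED_NARROW_HALO = 3),
                       diameter_range_um = c(100, 140),
                       image_shape = c(180L, 180L), seed = 42)
  a <- generate_mimetic(spec)
  b <- generate_mimetic(spec)
  expect_identical(a, b)
})

test_that("co-entry probability one pairs beads up", {
  spec <- mimetic_spec(c(CLASS1_RED_HOMOG = 4, CLASS2_GREEN_HOMOG = 4),
                       diameter_range_um = c(100, 120),
                       image_shape = c(260L, 260L),
                       co_entry_prob = 1, seed = 9)
  frames <- generate_mimetic(spec)
  expect_length(frames, 4)
  expect_true(all(vapply(frames, function(f) length(f$truth_masks), 1L) == 2))
  expect_true(all(vapply(frames, function(f) {
    length(f$truth_masks) == length(f$truth_classes)
  }, TRUE)))
})

test_that("empty compositions are rejected", {
  expect_error(mimetic_spec(c(CLASS1_RED_HOMOG = 0)), "at least one bead")
})
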