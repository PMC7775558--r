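# flat synapse: PM along y = 0 over [-500, 500], AZ over [-200, 200];
# a vesicle with centre (x, d + r) has edge distance d to the PM

test_that("vesicle pool rules: docked, active zone, periactive, cytoplasmic", {
  mem <- flat_membranes()
  r <- 20
  p <- make_profile(
    mem$pm, mem$az,
    circle_rec("synaptic_vesicle", 0, 10 + r, r),     # pm 10, az 10
    circle_rec("synaptic_vesicle", 380, 10 + r, r),   # pm 10, az > 30
    circle_rec("synaptic_vesicle", 0, r, r),          # touching: docked
    circle_rec("synaptic_vesicle", 0, 200 + r, r))    # deep cytoplasm
  cls <- classify_vesicles(p, threshold = 30)
  expect_equal(cls$pool, c("active_zone", "periactive", "docked",
                           "cytoplasmic"))
  expect_equal(cls$dist_pm, c(10, 10, 0, 200), tolerance = 1e-9)
  expect_true(cls$docked[3])
  expect_equal(cls$dist_az[2], sqrt(180^2 + 30^2) - r, tolerance = 1e-9)
})

test_that("manual docked/tethered annotations override geometry and are
           tallied for QC", {
  mem <- flat_membranes()
  p <- make_profile(
    mem$pm, mem$az,
    circle_rec("docked_vesicle", 0, 8 + 20, 20),    # annotated docked, 8 nm off
    circle_rec("tethered_vesicle", 50, 20, 20),     # annotated tethered, touching
    circle_rec("docked_vesicle", -30, 20, 20))      # docked and touching
  cls <- classify_vesicles(p)
  expect_equal(cls$docked, c(TRUE, FALSE, TRUE))
  rep <- tether_override_report(cls)
  expect_equal(rep$docked_but_apart, 1L)
  expect_equal(rep$tethered_but_touching, 1L)
  expect_equal(rep$total_disagreements, 2L)

  # reordering records does not change the tallies
  p2 <- make_profile(mem$pm, mem$az,
                     circle_rec("docked_vesicle", -30, 20, 20),
                     circle_rec("docked_vesicle", 0, 28, 20),
                     circle_rec("tethered_vesicle", 50, 20, 20))
  rep2 <- tether_override_report(classify_vesicles(p2))
  expect_equal(rep2$total_disagreements, rep$total_disagreements)

  consistent <- make_profile(mem$pm, mem$az,
                             circle_rec("docked_vesicle", 0, 20, 20))
  expect_equal(tether_override_report(
    classify_vesicles(consistent))$total_disagreements, 0L)
})

test_that("uncategorized vesicles are docked geometrically; errors without
           membranes", {
  mem <- flat_membranes()
  p <- make_profile(mem$pm, mem$az,
                    circle_rec("synaptic_vesicle", 0, 15, 20))
  expect_true(classify_vesicles(p)$docked)
  expect_error(classify_vesicles(make_profile(mem$pm,
                                              circle_rec("synaptic_vesicle",
                                                         0, 30, 20))),
               "no active zone")
  expect_error(classify_vesicles(make_profile(mem$pm, mem$pm, mem$az)),
               "exactly one plasma membrane")
})

test_that("pit location: two AZ crossings or both endpoints within 5 nm", {
  mem <- flat_membranes()
  arch_x <- seq(-30, 30, by = 1)
  over <- cbind(arch_x, 10 - 0.03 * arch_x^2)  # crosses AZ (y=0) twice
  p <- make_profile(mem$pm, mem$az,
                    line_rec("pit", over),
                    line_rec("pit", cbind(arch_x + 400, 3 + 0.02 * arch_x^2)))
  loc <- classify_pits(p)
  expect_equal(loc$location, c("inside_az", "outside_az"))
  expect_gte(loc$n_az_intersections[1], 2L)

  # endpoints at 3 and 4 nm from the AZ, no crossing -> inside
  xx <- seq(-30, 30, by = 1)
  bump <- cbind(xx, -((3 + 4) / 2 + (4 - 3) / 60 * xx +
                        25 * cos(pi * xx / 60)))
  bump[1, 2] <- -3; bump[nrow(bump), 2] <- -4
  p2 <- make_profile(mem$pm, mem$az, line_rec("pit", bump))
  loc2 <- classify_pits(p2)
  expect_equal(loc2$n_az_intersections, 0L)
  expect_equal(loc2$location, "inside_az")
})

test_that("pools partition the vesicles and grow monotonically with the
           threshold", {
  g <- generate_dataset(synth_config(n_profiles = 4, seed = 21,
                                     n_vesicles = 30L),
                        tempfile())
  for (pr in g$profiles) {
    c30 <- classify_vesicles(pr, threshold = 30)
    tab <- table(factor(c30$pool, levels = c("docked", "active_zone",
                                             "periactive", "cytoplasmic")))
    expect_equal(sum(tab), nrow(c30))
    c50 <- classify_vesicles(pr, threshold = 50)
    expect_gte(sum(c50$zone == "active_zone"), sum(c30$zone == "active_zone"))
  }
})
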