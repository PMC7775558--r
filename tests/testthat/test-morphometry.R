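# helper: profile with vesicles at prescribed edge distances to the AZ/PM
# (flat synapse, vesicle centre (x, d + r) -> edge distance d) and
# prescribed diameters
distance_profile <- function(dists, diam = 40, id = "p1",
                             xs = seq(-150, 150, length.out = max(1,
                                                                  length(dists)))) {
  mem <- flat_membranes()
  ves <- mapply(function(d, x, dm) circle_rec("synaptic_vesicle", x,
                                              d + dm / 2, dm / 2),
                dists, xs[seq_along(dists)],
                rep_len(diam, length(dists)), SIMPLIFY = FALSE)
  do.call(make_profile, c(list(mem$pm, mem$az), ves,
                          list(image_id = id)))
}

cfg <- analysis_config(pixel_size = 1)

test_that("profile summaries count what is annotated", {
  s <- summarize_profile(distance_profile(c(10, 50, 120)), cfg)
  expect_equal(nrow(s$vesicles), 3L)
  expect_equal(unname(s$counts["synaptic_vesicle"]), 3L)
  expect_equal(sum(s$pool_counts), 3)
  expect_equal(s$az_lengths, 400)

  # no vesicles: zero counts, empty lists, still a valid summary
  mem <- flat_membranes()
  s0 <- summarize_profile(make_profile(mem$pm, mem$az), cfg)
  expect_equal(nrow(s0$vesicles), 0L)
  expect_equal(sum(s0$pool_counts), 0)

  # duplicating one vesicle record increments exactly one count
  p1 <- distance_profile(c(10, 50))
  p2 <- distance_profile(c(10, 50, 50))
  d <- summarize_profile(p2, cfg)$counts - summarize_profile(p1, cfg)$counts
  expect_equal(sum(d), 1)
})

test_that("diameter statistics report both aggregation orders", {
  s1 <- summarize_profile(distance_profile(100, diam = 30, id = "a"), cfg)
  s2 <- summarize_profile(distance_profile(c(100, 120), diam = 50,
                                           id = "b"), cfg)
  ds <- diameter_stats(list(s1, s2))
  expect_equal(ds$pooled$mean, (30 + 50 + 50) / 3, tolerance = 1e-12)
  expect_equal(ds$per_profile$mean, 40)
  expect_equal(ds$pooled$n, 3L)

  # pooled mean == count-weighted mean of profile means
  counts <- c(1, 2)
  means <- c(30, 50)
  expect_equal(ds$pooled$mean, sum(counts * means) / sum(counts))

  # equal diameters: SEM 0 in both orders
  se <- diameter_stats(list(
    summarize_profile(distance_profile(c(10, 20), diam = 40, id = "c"), cfg),
    summarize_profile(distance_profile(c(30, 40), diam = 40, id = "d"), cfg)))
  expect_equal(se$pooled$mean, 40)
  expect_equal(se$pooled$sem, 0)
  expect_equal(se$per_profile$sem, 0)

  expect_error(diameter_stats(list(summarize_profile(
    make_profile(flat_membranes()$pm, flat_membranes()$az), cfg))),
    "no vesicles")
})

test_that("distance binning is half-open and normalized rows sum to one", {
  s <- summarize_profile(distance_profile(c(0, 49.9, 50)), cfg)
  dd <- distance_distribution(list(s), reference = "pm", bin_width = 50)
  expect_equal(unname(dd$counts[1, ]), c(2, 1))
  expect_equal(sum(dd$normalized[1, ]), 1, tolerance = 1e-9)
  # single profile: mean of normalized rows equals the pooled normalization
  expect_equal(unname(dd$mean_normalized), unname(dd$pooled_normalized),
               tolerance = 1e-12)
  expect_error(distance_distribution(list(s), bin_width = 0), "bin_width")
})

test_that("profiles without a dense projection are excluded with a warning", {
  s1 <- summarize_profile(distance_profile(c(10, 60), id = "nodp"), cfg)
  g <- generate_profile(synth_config(n_profiles = 1, seed = 5,
                                     n_vesicles = 6L,
                                     dense_projection = TRUE))
  s2 <- summarize_profile(g$profile, cfg)
  expect_warning(
    dd <- distance_distribution(list(s1, s2), reference = "dense_projection"),
    "lack a dense projection")
  expect_equal(dd$n_profiles, 1L)
})

test_that("pooled normalization recovers known bin proportions", {
  probs <- c(0.5, 0.3, 0.2)
  set.seed(404)
  n <- 2000
  d <- (sample.int(3, n, replace = TRUE, prob = probs) - 1) * 50 +
    runif(n, 0, 49.5)
  ss <- lapply(split(d, rep(1:4, length.out = n)), function(di)
    summarize_profile(distance_profile(di,
                                       xs = runif(length(di), -180, 180),
                                       id = paste0("p", di[1])), cfg))
  dd <- distance_distribution(ss, reference = "pm", bin_width = 50)
  tol <- 3 * sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(dd$pooled_normalized[1:3] - probs) < tol))
  expect_true(all(abs(rowSums(dd$normalized) - 1) < 1e-9))
})

test_that("dataset summary reports nested pools, medians and docked
           fraction", {
  mem <- flat_membranes()
  profs <- lapply(1:5, function(i) {
    n_docked <- if (i == 1) 9L else 0L
    ves <- c(
      lapply(seq_len(n_docked), function(j)
        circle_rec("docked_vesicle", j * 30 - 150, 20, 20)),
      lapply(seq_len(20L - n_docked), function(j)
        circle_rec("synaptic_vesicle", j * 15 - 160, 120, 20)))
    do.call(make_profile, c(list(mem$pm, mem$az), ves,
                            list(image_id = paste0("p", i))))
  })
  ss <- lapply(profs, summarize_profile, config = cfg)
  summ <- dataset_summary(ss, cfg)
  expect_equal(summ$total_vesicles, 100L)
  expect_equal(sum(vapply(ss, function(s) sum(s$vesicles$docked),
                          integer(1))), 9L)
  expect_equal(summ$docked_fraction, 0.09)
  expect_equal(summ$vesicles_per_profile$median, 20)
  # medians invariant to profile ordering
  summ_rev <- dataset_summary(rev(ss), cfg)
  expect_equal(summ_rev$vesicles_per_profile$median,
               summ$vesicles_per_profile$median)
  expect_equal(summ_rev$az_length$median, summ$az_length$median)
  # conservation: pools sum to the total
  expect_equal(sum(summ$pool_counts), summ$total_vesicles)
})
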