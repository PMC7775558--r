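test_that("point-to-polyline distance uses segment projection", {
  expect_equal(point_polyline_distance(c(0, 5), rbind(c(0, 0), c(10, 0))), 5)
  expect_equal(point_polyline_distance(c(10, 0),
                                       rbind(c(0, 0), c(10, 0), c(10, 8))), 0)
  # off the end of a segment: distance to the nearest vertex
  expect_equal(point_polyline_distance(c(13, 4), rbind(c(0, 0), c(10, 0))), 5)
  expect_warning(
    d <- point_polyline_distance(c(3, 4), matrix(c(0, 0), ncol = 2)),
    "single-point")
  expect_equal(d, 5)
})

test_that("segment projection refines vertex-only distance and matches the
           dense-resampling oracle", {
  set.seed(101)
  for (i in 1:25) {
    line <- cbind(cumsum(runif(6, 5, 30)), runif(6, 0, 50))
    p <- c(runif(1, 0, 150), runif(1, -30, 80))
    d_seg <- point_polyline_distance(p, line)
    d_vert <- point_polyline_distance(p, line, vertex_only = TRUE)
    expect_lte(d_seg, d_vert + 1e-12)
    expect_lt(abs(d_seg - brute_point_distance(p, line)), 0.01)
  }
})

test_that("vesicle edge distance subtracts the radius and floors at zero", {
  line <- rbind(c(-50, 0), c(50, 0))
  expect_equal(vesicle_edge_distance(c(0, 25), 20, line), 5)
  expect_equal(vesicle_edge_distance(c(0, 15), 20, line), 0)
  # rigid translation of vesicle + membrane together changes nothing
  shift <- c(123.4, -56.7)
  expect_equal(vesicle_edge_distance(c(0, 25) + shift, 20,
                                     sweep(line, 2, -shift)),
               5, tolerance = 1e-9)
})

test_that("contour-to-polyline distance handles touch, clearance and the
           resampling oracle", {
  line <- rbind(c(-50, 0), c(50, 0))
  sq_touch <- rbind(c(-1, 0), c(1, 0), c(1, 2), c(-1, 2))
  expect_equal(contour_polyline_distance(sq_touch, line), 0)
  # side-2 square centred 10 above the line: nearest edge at 9
  sq <- rbind(c(-1, 9), c(1, 9), c(1, 11), c(-1, 11))
  expect_equal(contour_polyline_distance(sq, line), 9)
  set.seed(77)
  for (i in 1:10) {
    ang <- sort(runif(8, 0, 2 * pi))
    r <- runif(8, 5, 15)
    cont <- cbind(30 + r * cos(ang), 25 + r * sin(ang))
    d <- contour_polyline_distance(cont, line)
    ring <- rbind(cont, cont[1, ])
    brute <- min(apply(resample_polyline(ring, 0.01), 1, function(q)
      brute_point_distance(q, line, spacing = 0.01)))
    expect_lt(abs(d - brute), 0.01)
  }
})

test_that("lengths and areas follow the shoelace / arc-length formulas", {
  expect_equal(polyline_length(rbind(c(0, 0), c(3, 4))), 5)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(contour_area(sq), 1)
  expect_equal(polyline_length(sq, closed = TRUE), 4)
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  poly <- cbind(7 * cos(th), 7 * sin(th))
  expect_lt(abs(contour_area(poly) - pi * 49) / (pi * 49), 0.001)
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_warning(contour_area(bow), "self-intersecting")
})

test_that("pit metrics match analytic shapes and scale homogeneously", {
  tri <- pit_metrics(rbind(c(0, 0), c(10, 10), c(20, 0)))
  expect_equal(tri$base_width, 20)
  expect_equal(tri$depth, 10)
  expect_equal(tri$fwhm_diameter, 10)
  expect_equal(tri$arc_length, 2 * sqrt(200))

  r <- 50
  phi <- seq(0, pi, by = pi / 180)
  semi <- pit_metrics(cbind(r * cos(phi), -r * sin(phi)))
  expect_equal(semi$depth, r, tolerance = 1e-6)
  expect_equal(semi$base_width, 2 * r)
  expect_equal(semi$fwhm_diameter, r * sqrt(3), tolerance = 1e-3)
  expect_equal(semi$arc_length, pi * r, tolerance = 1e-4)

  k <- 3.7
  tri_k <- pit_metrics(k * rbind(c(0, 0), c(10, 10), c(20, 0)))
  expect_equal(unlist(tri_k), k * unlist(tri), tolerance = 1e-12)

  # pit metrics are rotation invariant (FWHM is chord-parallel, not axis-parallel)
  a <- 0.83
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  semi_rot <- pit_metrics(cbind(r * cos(phi), -r * sin(phi)) %*% R)
  expect_equal(unlist(semi_rot), unlist(semi), tolerance = 1e-9)

  expect_error(pit_metrics(rbind(c(0, 0), c(5, 0), c(10, 0))), "flat pit")
})

test_that("polyline intersection counting is transversal with deduplication", {
  x1 <- rbind(c(0, 0), c(10, 10))
  x2 <- rbind(c(0, 10), c(10, 0))
  expect_equal(polyline_intersections(x1, x2)$count, 1L)
  arch <- cbind(seq(-10, 10, by = 0.5),
                5 - 0.05 * seq(-10, 10, by = 0.5)^2)
  chord <- rbind(c(-20, 0), c(20, 0))
  expect_equal(polyline_intersections(arch, chord)$count, 2L)
  far <- rbind(c(100, 100), c(120, 100))
  expect_equal(polyline_intersections(x1, far)$count, 0L)
  # crossing exactly at a shared vertex of two segments is counted once
  vee <- rbind(c(-5, 5), c(0, 0), c(5, 5))
  horiz <- rbind(c(-10, 0), c(10, 0))
  expect_equal(polyline_intersections(vee, horiz)$count, 1L)
})

test_that("distances are invariant under rigid motion and homogeneous under
           scaling", {
  set.seed(5)
  line <- cbind(cumsum(runif(5, 2, 20)), runif(5, 0, 30))
  p <- c(20, 40)
  d0 <- point_polyline_distance(p, line)
  a <- 1.1
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  t <- c(-30, 12)
  expect_equal(point_polyline_distance(drop(p %*% R) + t,
                                       sweep(line %*% R, 2, -t)),
               d0, tolerance = 1e-9)
  expect_equal(point_polyline_distance(2.5 * p, 2.5 * line), 2.5 * d0,
               tolerance = 1e-9)
})
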