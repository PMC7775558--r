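write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("record layout parses: circles and traces, comma or whitespace", {
  f <- write_lines_tmp(c(
    "1\tsynaptic vesicle\t\t120.5\t88.0\t19.8",
    "7\tplasma membrane\t512.3\t10,20,30\t40,41,44\t"))
  p <- read_annotation(f)
  expect_s3_class(p, "synapse_profile")
  expect_length(p$records, 2L)
  v <- p$records[[1]]
  expect_equal(v$geometry, "circle")
  expect_equal(c(v$x, v$y, v$radius), c(120.5, 88.0, 19.8))
  expect_true(is.na(v$measure))
  m <- p$records[[2]]
  expect_equal(m$class, "plasma_membrane")
  expect_equal(m$x, c(10, 20, 30))
  expect_equal(m$y, c(40, 41, 44))
  expect_equal(m$measure, 512.3)
  expect_equal(p$dialect, "comma")

  fw <- write_lines_tmp("7\tplasma membrane\t512.3\t10 20 30\t40 41 44")
  pw <- read_annotation(fw)
  expect_equal(pw$records[[1]]$x, c(10, 20, 30))
  expect_equal(pw$dialect, "whitespace")
})

test_that("name matching is case/whitespace tolerant, alias-extensible, and
           unknown names are preserved with a warning", {
  expect_equal(match_structure_class(c("Synaptic Vesicles", "  endosome ",
                                       "Ferritin+ multivesicular bodies")),
               c("synaptic_vesicle", "endosome", "ferritin_mvb"))
  expect_equal(match_structure_class("mitochondria",
                                     aliases = c(mitochondria = "ferritin_mvb")),
               "ferritin_mvb")
  f <- write_lines_tmp("1\tmystery organelle\t\t5\t5\t2")
  expect_warning(p <- read_annotation(f), "unrecognised")
  expect_equal(p$records[[1]]$class, "unknown")
  expect_length(p$records, 1L)  # preserved, not dropped
})

test_that("malformed lines raise errors naming the line", {
  expect_error(read_annotation(write_lines_tmp(
    c("7\tplasma membrane\t1\t1,2,3\t4,5\t"))), "line 1.*x-coordinates")
  expect_error(read_annotation(write_lines_tmp(
    c("7\tplasma membrane\t1\t1,2\t3,4\t",
      "1\tsynaptic vesicle\t\tabc\t4\t2"))), "line 2")
  expect_error(read_annotation(write_lines_tmp(
    "1\tsynaptic vesicle\t\t1\t2\t3\textra")), "too many fields")
  expect_error(read_annotation(write_lines_tmp(
    "1\tsynaptic vesicle\t\t1\t2\t-4")), "positive radius")
  f <- tempfile(); writeLines(character(0), f)
  expect_error(read_annotation(f), "empty")
})

test_that("write/read round trip reproduces profiles", {
  g <- generate_profile(synth_config(n_profiles = 1, seed = 3,
                                     n_vesicles = 8L))
  f <- tempfile(fileext = ".txt")
  write_annotation(g$profile, f)
  p2 <- read_annotation(f, pixel_size = g$profile$pixel_size)
  expect_length(p2$records, length(g$profile$records))
  for (i in seq_along(p2$records)) {
    a <- g$profile$records[[i]]; b <- p2$records[[i]]
    expect_equal(b$class, a$class)
    expect_equal(b$tool, a$tool)
    expect_equal(b$x, a$x, tolerance = 1e-6)
    expect_equal(b$y, a$y, tolerance = 1e-6)
    if (!is.na(a$radius)) expect_equal(b$radius, a$radius, tolerance = 1e-6)
  }
  empty <- make_profile(pixel_size = 1)
  expect_error(write_annotation(empty, tempfile()), "no records")
})

test_that("dataset validation reports the membrane contract per file", {
  mem <- flat_membranes(spacing = 50)
  ok <- tempfile(fileext = ".txt")
  write_annotation(make_profile(mem$pm, mem$az,
                                circle_rec("synaptic_vesicle", 0, 30, 20)),
                   ok)
  no_pm <- tempfile(fileext = ".txt")
  write_annotation(make_profile(mem$az), no_pm)
  two_pm <- tempfile(fileext = ".txt")
  write_annotation(make_profile(mem$pm, mem$pm, mem$az), two_pm)
  no_az <- tempfile(fileext = ".txt")
  write_annotation(make_profile(mem$pm), no_az)
  broken <- write_lines_tmp("7\tplasma membrane\t1\tzz\t4\t")

  rep <- check_dataset(c(ok, no_pm, two_pm, no_az, broken))
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$issue[rep$file == basename(no_pm)],
               "missing_plasma_membrane")
  expect_equal(rep$issue[rep$file == basename(two_pm)],
               "multiple_plasma_membranes")
  expect_true("missing_active_zone" %in% rep$issue[rep$file ==
                                                     basename(no_az)])
  expect_equal(rep$issue[rep$file == basename(broken)], "parse_failure")
  expect_false(basename(ok) %in% rep$file)

  # valid set -> empty report; the check is pure (identical on repeat)
  expect_equal(nrow(check_dataset(ok)), 0L)
  expect_identical(check_dataset(c(ok, no_pm)), check_dataset(c(ok, no_pm)))

  jf <- tempfile(fileext = ".json")
  export_validation(rep, jf)
  expect_false(jsonlite::read_json(jf)$analyzable)
})
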