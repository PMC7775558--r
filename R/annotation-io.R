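# Reading, validating and writing the per-image annotation text format.
#
# Each micrograph's annotations live in one tab-separated text file, one line
# per traced structure, in ROI-manager order:
#
#   tool<TAB>name<TAB>length-or-area<TAB>x(s)<TAB>y(s)<TAB>radius
#
# tool is the ImageJ/Fiji tool number (1 straight line -> circle, 3 freehand
# selection -> closed contour, 7 freehand line -> open polyline); the
# length/area field is empty for circles; x(s)/y(s) are single numbers for
# circles and coordinate lists for traces; radius is present only for circles.
# All coordinates are ImageJ pixel coordinates (origin top-left, y downward,
# 0-based). Scaling to nm happens once, at analysis time.

#' Controlled vocabulary of annotated structures
#'
#' The structure classes recognised by the analysis, with the annotation hot
#' key, the ImageJ tool used to trace them and the implied geometry kind:
#' circular structures (vesicles, particles) are recorded with the straight
#' line tool as centre + radius, irregular closed organelles (endosomes,
#' multivesicular bodies) with the freehand selection tool as closed contours,
#' and open membranes (plasma membrane, active zone, pits, dense projection)
#' with the freehand line tool as open polylines.
#'
#' @return A data.frame with columns `class`, `label`, `hotkey`, `tool`,
#'   `geometry`.
#' @export
structure_vocabulary <- function() {
  v <- rbind(
    c("synaptic_vesicle",             "synaptic vesicle",                    "1",  1),
    c("tethered_vesicle",             "tethered synaptic vesicle",           "2",  1),
    c("docked_vesicle",               "docked synaptic vesicle",             "3",  1),
    c("dense_core_vesicle",           "dense core vesicle",                  "4",  1),
    c("docked_dense_core_vesicle",    "docked dense core vesicle",           "5",  1),
    c("large_vesicle",                "large vesicle",                       "6",  1),
    c("clathrin_coated_pit",          "clathrin coated pit",                 "7",  7),
    c("clathrin_coated_vesicle",      "clathrin coated vesicle",             "8",  1),
    c("active_zone",                  "active zone membrane",                "9",  7),
    c("plasma_membrane",              "plasma membrane",                     "0",  7),
    c("endosome",                     "endosome",                            "n0", 3),
    c("ferritin_synaptic_vesicle",    "ferritin synaptic vesicle",           "n1", 1),
    c("ferritin_tethered_vesicle",    "ferritin tethered synaptic vesicle",  "n2", 1),
    c("ferritin_docked_vesicle",      "ferritin docked synaptic vesicle",    "n3", 1),
    c("ferritin_large_vesicle",       "ferritin large vesicle",              "n4", 1),
    c("ferritin_clathrin_coated_vesicle", "ferritin clathrin coated vesicle", "n5", 1),
    c("ferritin_pit",                 "ferritin pit",                        "n6", 7),
    c("ferritin_mvb",                 "ferritin multivesicular body",        "n7", 3),
    c("ferritin_endosome",            "ferritin endosome",                   "n8", 3),
    c("ferritin_endosome_bud",        "ferritin bud on endosome",            "n9", 7),
    c("pit",                          "pit",                                 "u",  7),
    c("multivesicular_body",          "multivesicular body",                 "m",  3),
    c("particle",                     "particle",                            "p",  1),
    c("synaptic_ribbon",              "synaptic ribbon",                     "r",  7),
    c("dense_projection",             "dense projection",                    "d",  7),
    c("endosome_bud",                 "bud on endosome",                     "j",  7)
  )
  data.frame(class = v[, 1L], label = v[, 2L], hotkey = v[, 3L],
             tool = as.integer(v[, 4L]),
             geometry = c("circle", "open_polyline",
                          "closed_contour")[match(as.integer(v[, 4L]),
                                                  c(1L, 7L, 3L))],
             stringsAsFactors = FALSE)
}

# normalise a structure name for vocabulary matching: case, punctuation and
# whitespace insensitive
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[+_\\-]", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  x
}

# singular form of the trailing word ("bodies" -> "body", "pits" -> "pit")
singularize <- function(x) sub("([^s])s$", "\\1", sub("ies$", "y", x))

#' Map structure names to the controlled vocabulary
#'
#' Matching is case-insensitive and whitespace/punctuation-normalised against
#' both the display labels and the class identifiers, singular or plural. An
#' alias map extends the vocabulary for datasets that reuse hot keys for other
#' organelles (e.g. mitochondria recorded under a ferritin-organelle key).
#' Unknown names map to `"unknown"` and are preserved, not dropped.
#'
#' @param names Character vector of structure names as found in a file.
#' @param aliases Optional named character vector, `alias = class`.
#' @return Character vector of class identifiers (or `"unknown"`).
#' @export
match_structure_class <- function(names, aliases = NULL) {
  voc <- structure_vocabulary()
  keys <- c(normalize_name(voc$label), normalize_name(gsub("_", " ", voc$class)))
  vals <- c(voc$class, voc$class)
  if (!is.null(aliases)) {
    stopifnot(!is.null(names(aliases)))
    keys <- c(normalize_name(names(aliases)), keys)
    vals <- c(unname(aliases), vals)
  }
  nn <- normalize_name(names)
  idx <- match(nn, keys)
  miss <- is.na(idx)
  idx[miss] <- match(singularize(nn[miss]), keys)
  out <- vals[idx]
  out[is.na(out)] <- "unknown"
  out
}

geometry_for <- function(class, tool) {
  voc <- structure_vocabulary()
  g <- voc$geometry[match(class, voc$class)]
  fallback <- c("circle", "open_polyline", "closed_contour")[
    match(tool, c(1L, 7L, 3L))]
  ifelse(is.na(g), fallback, g)
}

split_coords <- function(field, sep) {
  if (sep == "comma") {
    parts <- strsplit(field, ",", fixed = TRUE)[[1L]]
  } else {
    parts <- strsplit(trimws(field), "\\s+")[[1L]]
  }
  suppressWarnings(as.numeric(trimws(parts)))
}

#' Read one annotation file
#'
#' Parses a tab-separated per-image annotation file into a profile object.
#' One structure record is produced per non-empty line, in file order. The
#' coordinate-list delimiter inside the x and y fields (comma or whitespace)
#' is auto-detected per file and recorded in the returned object's dialect.
#' Unknown structure names are kept with class `"unknown"` and a warning.
#' Malformed lines (non-numeric coordinates, mismatched x/y counts, bad field
#' counts) raise an error naming the line.
#'
#' @param path Path to the annotation text file.
#' @param pixel_size Pixel size in nm/pixel, attached for analysis (the file
#'   itself stores pixel units). May be `NA` at parse time.
#' @param dialect Coordinate delimiter, `"comma"` or `"whitespace"`;
#'   `NULL` to auto-detect.
#' @param aliases Optional alias map for [match_structure_class()].
#' @return A `synapse_profile` object: list with `image_id`, `records`
#'   (list of structure records), `pixel_size`, `dialect`.
#' @export
read_annotation <- function(path, pixel_size = NA_real_, dialect = NULL,
                            aliases = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw))
  if (!any(keep)) stop("empty annotation file: ", path, call. = FALSE)
  lines <- raw[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (is.null(dialect)) {
    dialect <- if (any(vapply(fields, function(f)
      length(f) >= 4L && grepl(",", f[4L], fixed = TRUE), logical(1L))))
      "comma" else "whitespace"
  }
  dialect <- match.arg(dialect, c("comma", "whitespace"))
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    # a trailing tab yields a legitimate empty 6th field
    if (length(f) < 4L) {
      stop(sprintf("%s line %d: expected >= 4 tab-separated fields, got %d",
                   basename(path), line_no[i], length(f)), call. = FALSE)
    }
    if (length(f) > 6L) {
      stop(sprintf("%s line %d: too many fields (%d); expected at most 6",
                   basename(path), line_no[i], length(f)), call. = FALSE)
    }
    tool <- suppressWarnings(as.integer(f[1L]))
    if (is.na(tool)) {
      stop(sprintf("%s line %d: non-integer tool number '%s'",
                   basename(path), line_no[i], f[1L]), call. = FALSE)
    }
    name <- trimws(f[2L])
    measure <- if (length(f) >= 3L && nzchar(trimws(f[3L]))) {
      m <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(m)) stop(sprintf("%s line %d: non-numeric length/area '%s'",
                                 basename(path), line_no[i], f[3L]),
                         call. = FALSE)
      m
    } else NA_real_
    xs <- split_coords(f[4L], dialect)
    ys <- if (length(f) >= 5L) split_coords(f[5L], dialect) else numeric(0L)
    if (length(xs) == 0L || length(ys) == 0L || anyNA(xs) || anyNA(ys)) {
      stop(sprintf("%s line %d: non-numeric coordinate field",
                   basename(path), line_no[i]), call. = FALSE)
    }
    if (length(xs) != length(ys)) {
      stop(sprintf("%s line %d: %d x-coordinates but %d y-coordinates",
                   basename(path), line_no[i], length(xs), length(ys)),
           call. = FALSE)
    }
    radius <- if (length(f) >= 6L && nzchar(trimws(f[6L]))) {
      r <- suppressWarnings(as.numeric(f[6L]))
      if (is.na(r)) stop(sprintf("%s line %d: non-numeric radius '%s'",
                                 basename(path), line_no[i], f[6L]),
                         call. = FALSE)
      r
    } else NA_real_
    cls <- match_structure_class(name, aliases)
    geom <- geometry_for(cls, tool)
    if (is.na(geom)) {
      stop(sprintf("%s line %d: unknown tool number %d",
                   basename(path), line_no[i], tool), call. = FALSE)
    }
    if (geom == "circle") {
      if (length(xs) != 1L) {
        stop(sprintf("%s line %d: circle record must have one coordinate pair",
                     basename(path), line_no[i]), call. = FALSE)
      }
      if (is.na(radius) || radius <= 0) {
        stop(sprintf("%s line %d: circle record needs a positive radius",
                     basename(path), line_no[i]), call. = FALSE)
      }
    } else {
      if (length(xs) < 2L) {
        stop(sprintf("%s line %d: trace record needs >= 2 coordinate pairs",
                     basename(path), line_no[i]), call. = FALSE)
      }
      if (!is.na(radius)) {
        stop(sprintf("%s line %d: trace record must not carry a radius",
                     basename(path), line_no[i]), call. = FALSE)
      }
    }
    records[[i]] <- structure(
      list(tool = tool, name = name, class = cls, geometry = geom,
           measure = measure, x = xs, y = ys, radius = radius),
      class = "structure_record")
  }
  unknown <- vapply(records, function(r) r$class == "unknown", logical(1L))
  if (any(unknown)) {
    warning(sprintf("%s: %d record(s) with unrecognised structure name (%s)",
                    basename(path), sum(unknown),
                    paste(unique(vapply(records[unknown], `[[`, "", "name")),
                          collapse = ", ")), call. = FALSE)
  }
  structure(list(image_id = tools::file_path_sans_ext(basename(path)),
                 records = records, pixel_size = pixel_size,
                 dialect = dialect),
            class = "synapse_profile")
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.10g", x))
}

#' Write one annotation file
#'
#' Serialises a profile back to the tab-separated annotation format, in record
#' order, with comma-separated coordinate lists. `read_annotation()` of the
#' result reproduces the profile (coordinates to at least 6 significant
#' digits).
#'
#' @param profile A `synapse_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(profile, path) {
  stopifnot(inherits(profile, "synapse_profile"))
  if (length(profile$records) == 0L) {
    stop("profile has no records; nothing to export", call. = FALSE)
  }
  lines <- vapply(profile$records, function(r) {
    paste(c(r$tool, r$name, fmt_num(r$measure),
            paste(fmt_num(r$x), collapse = ","),
            paste(fmt_num(r$y), collapse = ","),
            fmt_num(r$radius)), collapse = "\t")
  }, character(1L))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Validate a set of annotation files
#'
#' Checks that every file parses and contains the essential membranes: exactly
#' one plasma membrane and at least one active zone per image. Problems are
#' reported, never raised, so a whole dataset can be screened in one pass; an
#' empty report means the dataset is analyzable. The check is pure: it never
#' modifies the files and repeated calls return identical reports.
#'
#' @param paths Character vector of annotation file paths (>= 1).
#' @param aliases Optional alias map for [match_structure_class()].
#' @return A data.frame of class `validation_report` with columns `file`,
#'   `issue` (one of `parse_failure`, `missing_plasma_membrane`,
#'   `multiple_plasma_membranes`, `missing_active_zone`), `message`.
#' @export
check_dataset <- function(paths, aliases = NULL) {
  stopifnot(length(paths) >= 1L)
  rows <- list()
  add <- function(file, issue, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, issue = issue, message = message,
      stringsAsFactors = FALSE)
  }
  for (p in paths) {
    prof <- tryCatch(
      suppressWarnings(read_annotation(p, aliases = aliases)),
      error = function(e) e)
    if (inherits(prof, "error")) {
      add(basename(p), "parse_failure", conditionMessage(prof))
      next
    }
    classes <- vapply(prof$records, `[[`, "", "class")
    n_pm <- sum(classes == "plasma_membrane")
    n_az <- sum(classes == "active_zone")
    if (n_pm == 0L) {
      add(basename(p), "missing_plasma_membrane",
          "no plasma membrane annotated")
    } else if (n_pm > 1L) {
      add(basename(p), "multiple_plasma_membranes",
          sprintf("%d plasma membranes annotated; exactly one expected", n_pm))
    }
    if (n_az == 0L) {
      add(basename(p), "missing_active_zone", "no active zone annotated")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0L), issue = character(0L),
               message = character(0L), stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Export a validation report as JSON
#'
#' @param report A `validation_report` from [check_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_validation <- function(report, path) {
  jsonlite::write_json(
    list(analyzable = nrow(report) == 0L,
         n_issues = nrow(report),
         issues = as.data.frame(unclass(report), stringsAsFactors = FALSE)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("dataset valid: all essential structures annotated\n")
  } else {
    cat(sprintf("%d issue(s) found:\n", nrow(x)))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %s: [%s] %s\n", x$file[i], x$issue[i], x$message[i]))
    }
  }
  invisible(x)
}

#' @export
print.synapse_profile <- function(x, ...) {
  classes <- vapply(x$records, `[[`, "", "class")
  cat(sprintf("synapse profile '%s': %d records (pixel size %s nm/px)\n",
              x$image_id, length(x$records),
              ifelse(is.na(x$pixel_size), "unset", format(x$pixel_size))))
  print(table(classes))
  invisible(x)
}

#' Convert a profile's records to nm-scaled geometry
#'
#' Applies the nm-per-pixel scaling exactly once, returning each record's
#' coordinates (and radius) in nm. Used internally by all analysis steps.
#'
#' @param profile A `synapse_profile` with a finite `pixel_size`.
#' @return The profile with an additional `nm` element per record: list with
#'   `xy` (matrix) and `radius`.
#' @keywords internal
#' @noRd
scale_profile <- function(profile) {
  px <- profile$pixel_size
  if (!is.numeric(px) || is.na(px) || px <= 0) {
    stop("profile '", profile$image_id,
         "': pixel_size (nm/pixel) must be set before analysis",
         call. = FALSE)
  }
  profile$records <- lapply(profile$records, function(r) {
    r$nm <- list(xy = cbind(r$x, r$y) * px,
                 radius = if (is.na(r$radius)) NA_real_ else r$radius * px)
    r
  })
  profile
}

records_of_class <- function(profile, classes) {
  keep <- vapply(profile$records, function(r) r$class %in% classes,
                 logical(1L))
  profile$records[keep]
}

#' Structure classes treated as vesicles
#'
#' Circle-geometry classes that enter vesicle counts, diameters and pool
#' classification. Gold/ferritin particles are excluded: they are markers,
#' not organelles.
#'
#' @return Character vector of class identifiers.
#' @export
vesicle_classes <- function() {
  voc <- structure_vocabulary()
  setdiff(voc$class[voc$geometry == "circle"], "particle")
}

pit_classes <- function() c("pit", "clathrin_coated_pit", "ferritin_pit")

endosome_classes <- function() {
  c("endosome", "ferritin_endosome", "multivesicular_body", "ferritin_mvb")
}
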