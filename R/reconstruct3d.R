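# Serial-section assembly: per-synapse aggregates over ordered slices and
# 3D coordinate export.
#
# Each profile is one thin section; its slice index times the section
# thickness (default 33 nm) gives the z-coordinate of everything in it.
# Structures spanning adjacent sections are NOT linked automatically --
# overcounting across sections must be re-evaluated manually -- but adjacent
# large organelles whose x,y contours overlap are flagged for review.

#' Build a serial-section stack
#'
#' @param profiles List of `synapse_profile` objects, one per section.
#' @param slice_index Integer vector of section numbers (same length as
#'   `profiles`); must be unique and strictly increasing within a synapse.
#' @param synapse_id Grouping vector (default: one synapse).
#' @param section_thickness Section thickness in nm (default 33).
#' @return Object of class `serial_stack`.
#' @export
serial_stack <- function(profiles, slice_index,
                         synapse_id = rep("synapse_1", length(profiles)),
                         section_thickness = 33) {
  stopifnot(length(profiles) == length(slice_index),
            length(profiles) == length(synapse_id),
            section_thickness > 0, length(profiles) >= 1L)
  slice_index <- as.integer(slice_index)
  for (syn in unique(synapse_id)) {
    s <- slice_index[synapse_id == syn]
    if (anyDuplicated(s)) {
      stop("duplicate slice indices in synapse '", syn, "'", call. = FALSE)
    }
  }
  ord <- order(synapse_id, slice_index)
  structure(list(profiles = profiles[ord], slice_index = slice_index[ord],
                 synapse_id = synapse_id[ord],
                 section_thickness = section_thickness),
            class = "serial_stack")
}

#' @export
print.serial_stack <- function(x, ...) {
  cat(sprintf("serial stack: %d sections, %d synapse(s), %g nm/section\n",
              length(x$profiles), length(unique(x$synapse_id)),
              x$section_thickness))
  invisible(x)
}

#' Aggregate serial sections into per-synapse totals
#'
#' Sums structure counts over a synapse's sections (additive and
#' order-independent) and computes the per-synapse docked fraction. The
#' per-profile table can optionally be restricted to sections containing a
#' dense projection, the convention for reporting per-profile numbers at en
#' passant synapses. Endosomes/MVBs in adjacent sections whose x,y contours
#' overlap are counted in full but flagged (`overcount_flags`) for manual
#' review, since one organelle may span several sections.
#'
#' @param stack A `serial_stack`.
#' @param config An [analysis_config()].
#' @param require_dense_projection Restrict the per-profile table to sections
#'   with an annotated dense projection.
#' @return List of class `synapse_aggregate` with `per_profile` (data.frame),
#'   `per_synapse` (data.frame), `summaries`, `overcount_flags`.
#' @export
aggregate_synapse <- function(stack, config,
                              require_dense_projection = FALSE) {
  stopifnot(inherits(stack, "serial_stack"),
            inherits(config, "analysis_config"))
  summaries <- lapply(stack$profiles, summarize_profile, config = config)
  per_profile <- data.frame(
    synapse_id = stack$synapse_id,
    slice_index = stack$slice_index,
    image_id = vapply(summaries, `[[`, "", "image_id"),
    n_vesicles = vapply(summaries, function(s) nrow(s$vesicles), integer(1L)),
    n_docked = vapply(summaries, function(s) sum(s$vesicles$docked),
                      integer(1L)),
    n_near_az = vapply(summaries, function(s)
      sum((s$vesicles$dist_pm <= config$zone_threshold &
             s$vesicles$dist_az <= config$zone_threshold) |
            s$vesicles$docked), integer(1L)),
    n_endosomes = vapply(summaries, function(s) nrow(s$endosomes),
                         integer(1L)),
    has_dense_projection = vapply(summaries, `[[`, logical(1L),
                                  "has_dense_projection"),
    stringsAsFactors = FALSE)
  pp <- per_profile
  if (require_dense_projection) pp <- pp[pp$has_dense_projection, ]
  per_synapse <- do.call(rbind, lapply(split(seq_along(summaries),
                                             stack$synapse_id), function(ix) {
    tot <- sum(per_profile$n_vesicles[ix])
    dk <- sum(per_profile$n_docked[ix])
    data.frame(synapse_id = stack$synapse_id[ix[1L]],
               n_sections = length(ix),
               total_vesicles = tot,
               total_docked = dk,
               total_near_az = sum(per_profile$n_near_az[ix]),
               docked_fraction = if (tot > 0) dk / tot else NA_real_,
               total_endosomes = sum(per_profile$n_endosomes[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_synapse) <- NULL
  structure(list(per_profile = pp, per_synapse = per_synapse,
                 summaries = summaries,
                 overcount_flags = overcount_flags(stack, summaries)),
            class = "synapse_aggregate")
}

# flag large closed organelles in adjacent sections whose x,y contours
# overlap (candidate multi-section structures)
overcount_flags <- function(stack, summaries) {
  flags <- list()
  for (syn in unique(stack$synapse_id)) {
    ix <- which(stack$synapse_id == syn)
    ix <- ix[order(stack$slice_index[ix])]
    if (length(ix) < 2L) next
    for (k in seq_len(length(ix) - 1L)) {
      i <- ix[k]; j <- ix[k + 1L]
      if (stack$slice_index[j] - stack$slice_index[i] != 1L) next
      ca <- contours_nm(stack$profiles[[i]])
      cb <- contours_nm(stack$profiles[[j]])
      for (a in seq_along(ca)) {
        for (b in seq_along(cb)) {
          d <- contour_polyline_distance(ca[[a]], cb[[b]], closed_b = TRUE)
          if (d == 0) {
            flags[[length(flags) + 1L]] <- data.frame(
              synapse_id = syn,
              slice_a = stack$slice_index[i], slice_b = stack$slice_index[j],
              record_a = names(ca)[a], record_b = names(cb)[b],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(synapse_id = character(0L), slice_a = integer(0L),
               slice_b = integer(0L), record_a = character(0L),
               record_b = character(0L), stringsAsFactors = FALSE)
}

contours_nm <- function(profile) {
  profile <- scale_profile(profile)
  idx <- which(vapply(profile$records, function(r)
    r$class %in% endosome_classes(), logical(1L)))
  out <- lapply(idx, function(i) profile$records[[i]]$nm$xy)
  names(out) <- as.character(idx)
  out
}

#' Export 3D coordinates of a serial stack
#'
#' Writes every structure's coordinates with z = slice_index *
#' section_thickness, in nm. CSV: one row per vertex (circles contribute one
#' row carrying the radius for downstream sphere rendering); re-importing the
#' CSV reproduces the coordinates. OBJ: Wavefront vertices grouped per
#' structure class; the y-axis is negated on OBJ export (image y grows
#' downward, model y grows up) so renders come out right-handed, as noted in
#' the file header.
#'
#' @param stack A `serial_stack`.
#' @param path Output file path.
#' @param format `"csv"` or `"obj"`.
#' @return `path`, invisibly.
#' @export
export_coordinates <- function(stack, path, format = c("csv", "obj")) {
  stopifnot(inherits(stack, "serial_stack"))
  format <- match.arg(format)
  if (length(stack$profiles) == 0L) stop("empty stack", call. = FALSE)
  rows <- list()
  for (i in seq_along(stack$profiles)) {
    prof <- scale_profile(stack$profiles[[i]])
    z <- stack$slice_index[i] * stack$section_thickness
    for (j in seq_along(prof$records)) {
      r <- prof$records[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        synapse_id = stack$synapse_id[i],
        slice_index = stack$slice_index[i],
        record = j, class = r$class,
        vertex = seq_len(nrow(r$nm$xy)),
        x_nm = r$nm$xy[, 1L], y_nm = r$nm$xy[, 2L], z_nm = z,
        radius_nm = if (r$geometry == "circle") r$nm$radius else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c("# 3D coordinate export (units: nm)",
                 "# y axis negated relative to image coordinates",
                 "# (image y grows downward; model y grows up)",
                 sprintf("# section thickness: %g nm",
                         stack$section_thickness)), con)
    for (grp in split(tab, paste(tab$synapse_id, tab$slice_index,
                                 tab$record, sep = "_"))) {
      writeLines(sprintf("g %s_%s", grp$class[1L],
                         paste(grp$synapse_id[1L], grp$slice_index[1L],
                               grp$record[1L], sep = "_")), con)
      writeLines(sprintf("v %.6g %.6g %.6g",
                         grp$x_nm, -grp$y_nm, grp$z_nm), con)
    }
  }
  invisible(path)
}
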