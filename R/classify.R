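# Assignment of structures to location categories relative to the plasma
# membrane, active zone(s) and dense projection.
#
# Pool rules: a vesicle with edge distance 0 to the plasma membrane is
# docked. A vesicle within the threshold T (default 30 nm) of the plasma
# membrane AND within T of an active zone belongs to the active-zone pool;
# within T of the plasma membrane but farther than T from every active zone,
# to the periactive pool; otherwise it is cytoplasmic. Manual docked /
# tethered annotations take precedence over the geometric rule (the
# annotator saw contact or tethers that the trace cannot encode); geometric
# docking applies to uncategorized vesicles.

manual_pool_for <- function(class) {
  ifelse(class %in% c("docked_vesicle", "docked_dense_core_vesicle",
                      "ferritin_docked_vesicle"), "docked",
  ifelse(class %in% c("tethered_vesicle", "ferritin_tethered_vesicle"),
         "tethered", "uncategorized"))
}

# extract membrane traces (nm) from a scaled profile
membranes_nm <- function(profile) {
  list(pm  = lapply(records_of_class(profile, "plasma_membrane"),
                    function(r) r$nm$xy),
       az  = lapply(records_of_class(profile, "active_zone"),
                    function(r) r$nm$xy),
       dp  = lapply(records_of_class(profile,
                                     c("dense_projection", "synaptic_ribbon")),
                    function(r) r$nm$xy))
}

min_dist_to <- function(fun) {
  function(traces, ...) {
    if (length(traces) == 0L) return(NA_real_)
    min(vapply(traces, function(tr) fun(tr, ...), numeric(1L)))
  }
}

#' Classify vesicles into docked / zone pools
#'
#' Computes, for every vesicle-class record of a profile, the edge distances
#' to the plasma membrane, the nearest active zone, and (when annotated) the
#' dense projection, then assigns the docked flag and the zone per the pool
#' rules. Distances are minimum edge distances: centre-to-trace minus radius,
#' floored at zero. Manual docked/tethered classes override the geometric
#' docking rule; disagreements are flagged for QC rather than corrected.
#'
#' @param profile A `synapse_profile` with `pixel_size` set.
#' @param threshold Zone threshold T in nm (default 30).
#' @param docking_tol Edge distance at or below which an uncategorized
#'   vesicle counts as geometrically docked, in nm (default 0, i.e. contact).
#' @param vertex_only Measure distances to trace vertices only (legacy
#'   cross-validation mode) instead of continuous segment projection.
#' @return A data.frame of class `zone_classification`, one row per vesicle:
#'   `record` (index in the profile), `class`, `manual_pool`, `diameter_nm`,
#'   `dist_pm`, `dist_az`, `dist_dp`, `docked`, `geometric_docked`, `zone`,
#'   `pool` (partition label: docked / active_zone / periactive /
#'   cytoplasmic).
#' @export
classify_vesicles <- function(profile, threshold = 30, docking_tol = 0,
                              vertex_only = FALSE) {
  stopifnot(inherits(profile, "synapse_profile"), threshold > 0,
            docking_tol >= 0)
  profile <- scale_profile(profile)
  mem <- membranes_nm(profile)
  if (length(mem$pm) != 1L) {
    stop("profile '", profile$image_id, "': exactly one plasma membrane ",
         "required (found ", length(mem$pm), ")", call. = FALSE)
  }
  if (length(mem$az) == 0L) {
    stop("profile '", profile$image_id, "': no active zone annotated",
         call. = FALSE)
  }
  idx <- which(vapply(profile$records, function(r)
    r$class %in% vesicle_classes(), logical(1L)))
  n <- length(idx)
  edge_min <- min_dist_to(function(tr, center, radius)
    vesicle_edge_distance(center, radius, tr, vertex_only = vertex_only))
  out <- data.frame(record = idx,
                    class = character(n), manual_pool = character(n),
                    diameter_nm = numeric(n),
                    dist_pm = numeric(n), dist_az = numeric(n),
                    dist_dp = numeric(n),
                    docked = logical(n), geometric_docked = logical(n),
                    zone = character(n), pool = character(n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    r <- profile$records[[idx[k]]]
    center <- r$nm$xy[1L, ]
    radius <- r$nm$radius
    d_pm <- edge_min(mem$pm, center, radius)
    d_az <- edge_min(mem$az, center, radius)
    d_dp <- edge_min(mem$dp, center, radius)
    manual <- manual_pool_for(r$class)
    geo_docked <- d_pm <= docking_tol
    docked <- if (manual == "docked") TRUE
              else if (manual == "tethered") FALSE
              else geo_docked
    zone <- if (d_pm <= threshold && d_az <= threshold) "active_zone"
            else if (d_pm <= threshold) "periactive"
            else "cytoplasmic"
    out$class[k] <- r$class
    out$manual_pool[k] <- manual
    out$diameter_nm[k] <- 2 * radius
    out$dist_pm[k] <- d_pm
    out$dist_az[k] <- d_az
    out$dist_dp[k] <- d_dp
    out$docked[k] <- docked
    out$geometric_docked[k] <- geo_docked
    out$zone[k] <- zone
    out$pool[k] <- if (docked) "docked" else zone
  }
  attr(out, "threshold") <- threshold
  attr(out, "docking_tol") <- docking_tol
  attr(out, "image_id") <- profile$image_id
  class(out) <- c("zone_classification", "data.frame")
  out
}

#' Locate pits relative to the active zone
#'
#' A pit lies within the active zone when its trace overlaps the traced
#' active-zone membrane at two or more points, or when both of its endpoints
#' are within `endpoint_tol` (default 5 nm) of the active-zone membrane (the
#' entire pit then sits in the active zone). Otherwise it is outside the
#' active zone (periactive, typically endocytic). With several active zones,
#' a pit is inside if any one of them satisfies the rule.
#'
#' @param profile A `synapse_profile` with `pixel_size` set.
#' @param endpoint_tol Endpoint-to-active-zone tolerance in nm (default 5).
#' @return A data.frame, one row per pit record: `record`, `class`,
#'   `location` (`inside_az` / `outside_az`), `n_az_intersections`,
#'   `endpoint_dist_1`, `endpoint_dist_2` (nm), plus the pit shape metrics
#'   `depth`, `base_width`, `fwhm_diameter`, `arc_length` (nm).
#' @export
classify_pits <- function(profile, endpoint_tol = 5) {
  stopifnot(inherits(profile, "synapse_profile"), endpoint_tol >= 0)
  profile <- scale_profile(profile)
  mem <- membranes_nm(profile)
  if (length(mem$az) == 0L) {
    stop("profile '", profile$image_id, "': no active zone annotated",
         call. = FALSE)
  }
  idx <- which(vapply(profile$records, function(r)
    r$class %in% pit_classes(), logical(1L)))
  rows <- lapply(idx, function(i) {
    xy <- profile$records[[i]]$nm$xy
    e1 <- xy[1L, ]; e2 <- xy[nrow(xy), ]
    n_int <- 0L
    d1 <- Inf; d2 <- Inf
    for (az in mem$az) {
      n_int <- max(n_int, polyline_intersections(xy, az)$count)
      d1 <- min(d1, point_polyline_distance(e1, az))
      d2 <- min(d2, point_polyline_distance(e2, az))
    }
    inside <- FALSE
    for (az in mem$az) {
      k <- polyline_intersections(xy, az)$count
      a1 <- point_polyline_distance(e1, az)
      a2 <- point_polyline_distance(e2, az)
      if (k >= 2L || (a1 <= endpoint_tol && a2 <= endpoint_tol)) {
        inside <- TRUE
        break
      }
    }
    pm <- tryCatch(pit_metrics(xy), error = function(e) NULL)
    data.frame(record = i, class = profile$records[[i]]$class,
               location = if (inside) "inside_az" else "outside_az",
               n_az_intersections = n_int,
               endpoint_dist_1 = d1, endpoint_dist_2 = d2,
               depth = if (is.null(pm)) NA_real_ else pm$depth,
               base_width = if (is.null(pm)) NA_real_ else pm$base_width,
               fwhm_diameter = if (is.null(pm)) NA_real_ else pm$fwhm_diameter,
               arc_length = if (is.null(pm)) NA_real_ else pm$arc_length,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record = integer(0L), class = character(0L),
               location = character(0L), n_az_intersections = integer(0L),
               endpoint_dist_1 = numeric(0L), endpoint_dist_2 = numeric(0L),
               depth = numeric(0L), base_width = numeric(0L),
               fwhm_diameter = numeric(0L), arc_length = numeric(0L),
               stringsAsFactors = FALSE)
  attr(out, "image_id") <- profile$image_id
  out
}

#' Tally disagreements between manual and geometric docking
#'
#' Tethered and docked vesicles are manual calls (tethers are invisible to
#' the coordinate trace), so the analysis trusts the annotation; this report
#' quantifies where annotation and geometry disagree, for quality control:
#' vesicles annotated docked whose traced edge distance exceeds the docking
#' tolerance, and vesicles annotated tethered that geometrically touch the
#' membrane.
#'
#' @param classification A `zone_classification` from [classify_vesicles()].
#' @return A list with counts `docked_but_apart`, `tethered_but_touching`,
#'   `total_disagreements`, and the offending row indices.
#' @export
tether_override_report <- function(classification) {
  stopifnot(inherits(classification, "zone_classification"))
  tol <- attr(classification, "docking_tol")
  a <- which(classification$manual_pool == "docked" &
               classification$dist_pm > tol)
  b <- which(classification$manual_pool == "tethered" &
               classification$geometric_docked)
  list(docked_but_apart = length(a),
       tethered_but_touching = length(b),
       total_disagreements = length(a) + length(b),
       rows = sort(c(a, b)))
}
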