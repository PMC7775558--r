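# Per-profile and per-dataset statistics: sizes, counts, distance
# distributions and binned normalized abundances.

#' Analysis configuration
#'
#' One configuration object carries every tunable parameter of the analysis
#' and is echoed into every output for provenance.
#'
#' @param pixel_size Pixel size in nm/pixel (required; images should be
#'   acquired at ~1 nm/pixel or better).
#' @param bin_width Bin width for distance distributions, nm (default 50).
#' @param zone_threshold Zone threshold T, nm (default 30).
#' @param pit_endpoint_tol Pit endpoint tolerance for the inside-active-zone
#'   rule, nm (default 5).
#' @param docking_tol Docking tolerance after edge-distance flooring, nm
#'   (default 0).
#' @param section_thickness Serial-section thickness, nm (default 33).
#' @param vertex_only Legacy vertex-wise distance mode (default FALSE).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(pixel_size, bin_width = 50, zone_threshold = 30,
                            pit_endpoint_tol = 5, docking_tol = 0,
                            section_thickness = 33, vertex_only = FALSE) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0, bin_width > 0,
            zone_threshold > 0, pit_endpoint_tol >= 0, docking_tol >= 0,
            section_thickness > 0)
  structure(list(pixel_size = pixel_size, bin_width = bin_width,
                 zone_threshold = zone_threshold,
                 pit_endpoint_tol = pit_endpoint_tol,
                 docking_tol = docking_tol,
                 section_thickness = section_thickness,
                 vertex_only = isTRUE(vertex_only)),
            class = "analysis_config")
}

#' Summarize one synaptic profile
#'
#' Runs the full geometry and classification pass over one profile: vesicle
#' pools and distances, pit metrics and locations, endosome/MVB sizes and
#' distances, and membrane lengths, all in nm.
#'
#' @param profile A `synapse_profile`.
#' @param config An [analysis_config()]; its `pixel_size` is applied to the
#'   profile if the profile has none.
#' @return An object of class `profile_summary`: list with `image_id`,
#'   `counts` (named vector per structure class), `vesicles`
#'   (zone classification data.frame), `pits`, `endosomes`, `az_lengths`,
#'   `pm_length`, `has_dense_projection`, `pool_counts`.
#' @export
summarize_profile <- function(profile, config) {
  stopifnot(inherits(profile, "synapse_profile"),
            inherits(config, "analysis_config"))
  if (is.na(profile$pixel_size)) profile$pixel_size <- config$pixel_size
  scaled <- scale_profile(profile)
  classes <- vapply(scaled$records, `[[`, "", "class")
  counts <- table(factor(classes, levels = c(structure_vocabulary()$class,
                                             "unknown")))
  vesicles <- classify_vesicles(profile, threshold = config$zone_threshold,
                                docking_tol = config$docking_tol,
                                vertex_only = config$vertex_only)
  pits <- classify_pits(profile, endpoint_tol = config$pit_endpoint_tol)
  mem <- membranes_nm(scaled)
  endo_idx <- which(classes %in% endosome_classes())
  endosomes <- do.call(rbind, c(list(
    data.frame(record = integer(0L), class = character(0L),
               area_nm2 = numeric(0L), perimeter_nm = numeric(0L),
               dist_pm = numeric(0L), dist_az = numeric(0L),
               stringsAsFactors = FALSE)),
    lapply(endo_idx, function(i) {
      xy <- scaled$records[[i]]$nm$xy
      data.frame(record = i, class = classes[i],
                 area_nm2 = contour_area(xy),
                 perimeter_nm = polyline_length(xy, closed = TRUE),
                 dist_pm = if (length(mem$pm))
                   min(vapply(mem$pm, function(tr)
                     contour_polyline_distance(xy, tr), numeric(1L)))
                 else NA_real_,
                 dist_az = if (length(mem$az))
                   min(vapply(mem$az, function(tr)
                     contour_polyline_distance(xy, tr), numeric(1L)))
                 else NA_real_,
                 stringsAsFactors = FALSE)
    })))
  pools <- c(docked = 0, active_zone = 0, periactive = 0, cytoplasmic = 0)
  tab <- table(vesicles$pool)
  pools[names(tab)] <- tab
  structure(list(
    image_id = profile$image_id,
    counts = counts,
    vesicles = vesicles,
    pits = pits,
    endosomes = endosomes,
    az_lengths = vapply(mem$az, polyline_length, numeric(1L)),
    pm_length = if (length(mem$pm)) polyline_length(mem$pm[[1L]]) else NA_real_,
    has_dense_projection = length(mem$dp) > 0L,
    pool_counts = pools,
    config = config), class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("profile '%s': %d vesicles (%d docked), %d pit(s), %d endosome(s)\n",
              x$image_id, nrow(x$vesicles), sum(x$vesicles$docked),
              nrow(x$pits), nrow(x$endosomes)))
  cat(sprintf("  active zone length %s nm\n",
              paste(sprintf("%.0f", x$az_lengths), collapse = " + ")))
  invisible(x)
}

#' Vesicle diameter statistics, pooled and per-profile
#'
#' Two aggregation orders are reported: the pooled mean over every vesicle in
#' the dataset, and the mean of per-profile means (which weights each synapse
#' equally and better represents the population average). SEM = SD/sqrt(n)
#' with n the number of vesicles (pooled) or of profiles (mean of means).
#'
#' @param summaries List of `profile_summary` objects.
#' @return List with `pooled` (mean, sem, median, n), `per_profile`
#'   (mean of means, sem over profiles, median of means, n profiles).
#' @export
diameter_stats <- function(summaries) {
  diam <- lapply(summaries, function(s) s$vesicles$diameter_nm)
  all_d <- unlist(diam)
  if (length(all_d) == 0L) stop("no vesicles in dataset", call. = FALSE)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  means <- vapply(diam[lengths(diam) > 0L], mean, numeric(1L))
  list(pooled = list(mean = mean(all_d), sem = sem(all_d),
                     median = stats::median(all_d), n = length(all_d)),
       per_profile = list(mean = mean(means), sem = sem(means),
                          median = stats::median(means), n = length(means)))
}

# distribution-free 95% CI of the median (binomial rank method)
median_ci <- function(x, conf = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_))
  if (n == 1L) return(c(x, x))
  alpha <- (1 - conf) / 2
  lo <- stats::qbinom(alpha, n, 0.5)
  lo <- max(1L, lo)
  hi <- min(n, n - lo + 1L)
  c(x[lo], x[hi])
}

#' Binned distance distribution with normalized abundance
#'
#' Bins the edge distances of vesicles to a reference membrane (plasma
#' membrane, active zone or dense projection) into half-open bins
#' `[k*w, (k+1)*w)`. Reports the per-profile count matrix, the mean count per
#' bin, each profile's normalized abundance (counts divided by the profile
#' total, so each row sums to 1), their across-profile mean, and the pooled
#' normalization (all distances combined, then normalized). Profiles lacking
#' the reference (no dense projection annotated) are excluded with a warning.
#'
#' @param summaries List of `profile_summary` objects.
#' @param reference `"pm"`, `"az"` or `"dense_projection"`.
#' @param bin_width Bin width in nm (> 0).
#' @return Object of class `distance_distribution`: list with `bin_width`,
#'   `breaks`, `counts` (profile x bin matrix), `mean_per_bin`,
#'   `normalized` (per-profile rows summing to 1), `mean_normalized`,
#'   `pooled_normalized`.
#' @export
distance_distribution <- function(summaries, reference = c("az", "pm",
                                                           "dense_projection"),
                                  bin_width = 50) {
  reference <- match.arg(reference)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  col <- switch(reference, pm = "dist_pm", az = "dist_az",
                dense_projection = "dist_dp")
  dists <- lapply(summaries, function(s) {
    d <- s$vesicles[[col]]
    d[is.finite(d)]
  })
  names(dists) <- vapply(summaries, `[[`, "", "image_id")
  if (reference == "dense_projection") {
    lacking <- !vapply(summaries, `[[`, logical(1L), "has_dense_projection")
    if (any(lacking)) {
      warning(sprintf("%d profile(s) lack a dense projection and are excluded: %s",
                      sum(lacking), paste(names(dists)[lacking],
                                          collapse = ", ")), call. = FALSE)
      dists <- dists[!lacking]
    }
  }
  all_d <- unlist(dists)
  n_bins <- max(1L, floor(max(all_d, 0) / bin_width) + 1L)
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  bin_of <- function(d) pmin(floor(d / bin_width) + 1L, n_bins)
  counts <- t(vapply(dists, function(d) {
    tabulate(bin_of(d), nbins = n_bins)
  }, integer(n_bins)))
  if (n_bins == 1L) counts <- matrix(counts, ncol = 1L,
                                     dimnames = list(names(dists), NULL))
  colnames(counts) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1L])
  totals <- rowSums(counts)
  normalized <- counts / ifelse(totals > 0, totals, NA_real_)
  pooled <- colSums(counts) / sum(counts)
  structure(list(bin_width = bin_width, breaks = breaks, counts = counts,
                 mean_per_bin = colMeans(counts),
                 normalized = normalized,
                 mean_normalized = colMeans(normalized, na.rm = TRUE),
                 pooled_normalized = pooled,
                 reference = reference,
                 n_profiles = nrow(counts)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance distribution to %s: %d profiles, %d bins of %g nm\n",
              x$reference, x$n_profiles, length(x$breaks) - 1L, x$bin_width))
  print(round(rbind(mean_count = x$mean_per_bin,
                    pooled_normalized = x$pooled_normalized), 4))
  invisible(x)
}

#' Dataset-level summary statistics
#'
#' Pools the per-profile summaries of one condition into the headline
#' statistics: diameter means (both aggregation orders, mean +/- SEM),
#' per-profile vesicle counts (median with distribution-free 95% CI), the
#' nested near-membrane pools (vesicles within T of the active zone,
#' including docked ones, and the docked/tethered counts), active-zone
#' lengths, and the docked fraction (total docked / total vesicles).
#'
#' @param summaries List of `profile_summary` objects (>= 1).
#' @param config The [analysis_config()] used.
#' @return Object of class `dataset_summary`.
#' @export
dataset_summary <- function(summaries, config) {
  stopifnot(length(summaries) >= 1L)
  per_count <- vapply(summaries, function(s) nrow(s$vesicles), integer(1L))
  T <- config$zone_threshold
  near_az <- vapply(summaries, function(s)
    sum(s$vesicles$dist_pm <= T & s$vesicles$dist_az <= T |
          s$vesicles$docked), integer(1L))
  docked <- vapply(summaries, function(s) sum(s$vesicles$docked), integer(1L))
  tethered <- vapply(summaries, function(s)
    sum(s$vesicles$manual_pool == "tethered"), integer(1L))
  pools <- Reduce(`+`, lapply(summaries, `[[`, "pool_counts"))
  az_len <- unlist(lapply(summaries, `[[`, "az_lengths"))
  pits <- do.call(rbind, lapply(summaries, `[[`, "pits"))
  total_ves <- sum(per_count)
  structure(list(
    n_profiles = length(summaries),
    diameters = diameter_stats(summaries),
    vesicles_per_profile = list(median = stats::median(per_count),
                                ci95 = median_ci(per_count),
                                mean = mean(per_count), values = per_count),
    near_az_per_profile = list(median = stats::median(near_az),
                               ci95 = median_ci(near_az),
                               mean = mean(near_az), values = near_az),
    docked_per_profile = list(median = stats::median(docked),
                              ci95 = median_ci(docked),
                              mean = mean(docked), values = docked),
    tethered_per_profile = list(mean = mean(tethered), values = tethered),
    pool_counts = pools,
    az_length = list(median = stats::median(az_len), ci95 = median_ci(az_len),
                     mean = mean(az_len), values = az_len),
    docked_fraction = sum(docked) / total_ves,
    total_vesicles = total_ves,
    pits = list(n = if (is.null(pits)) 0L else nrow(pits),
                n_inside_az = if (is.null(pits)) 0L else
                  sum(pits$location == "inside_az")),
    config = config), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  d <- x$diameters
  cat(sprintf("dataset: %d profiles, %d vesicles\n",
              x$n_profiles, x$total_vesicles))
  cat(sprintf("  diameter: pooled %.1f +/- %.1f nm; mean of means %.1f +/- %.1f nm\n",
              d$pooled$mean, d$pooled$sem,
              d$per_profile$mean, d$per_profile$sem))
  cat(sprintf("  vesicles/profile: median %g (95%% CI %g-%g)\n",
              x$vesicles_per_profile$median,
              x$vesicles_per_profile$ci95[1L], x$vesicles_per_profile$ci95[2L]))
  cat(sprintf("  within %g nm of AZ: mean %.1f; docked: mean %.1f (fraction %.3f)\n",
              x$config$zone_threshold, x$near_az_per_profile$mean,
              x$docked_per_profile$mean, x$docked_fraction))
  cat(sprintf("  active zone length: median %.0f nm\n", x$az_length$median))
  invisible(x)
}

# strip non-serialisable bits for JSON export
summary_as_list <- function(x) {
  stopifnot(inherits(x, "dataset_summary"))
  list(
    n_profiles = x$n_profiles,
    total_vesicles = x$total_vesicles,
    diameter = list(
      pooled_mean = x$diameters$pooled$mean,
      pooled_sem = x$diameters$pooled$sem,
      pooled_median = x$diameters$pooled$median,
      mean_of_means = x$diameters$per_profile$mean,
      mean_of_means_sem = x$diameters$per_profile$sem),
    vesicles_per_profile = x$vesicles_per_profile[c("median", "ci95", "mean")],
    near_az_per_profile = x$near_az_per_profile[c("median", "ci95", "mean")],
    docked_per_profile = x$docked_per_profile[c("median", "ci95", "mean")],
    pool_counts = as.list(x$pool_counts),
    az_length = x$az_length[c("median", "ci95", "mean")],
    docked_fraction = x$docked_fraction,
    pits = x$pits,
    config = unclass(x$config))
}
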