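# Build small annotation profiles in code (no fixture files).

rec <- function(tool, name, class, geometry, x, y, measure = NA_real_,
                radius = NA_real_) {
  structure(list(tool = tool, name = name, class = class,
                 geometry = geometry, measure = measure,
                 x = x, y = y, radius = radius),
            class = "structure_record")
}

circle_rec <- function(class, x, y, radius,
                       name = gsub("_", " ", class)) {
  rec(1L, name, class, "circle", x, y, radius = radius)
}

line_rec <- function(class, xy, name = gsub("_", " ", class)) {
  rec(7L, name, class, "open_polyline", xy[, 1L], xy[, 2L],
      measure = synmorph::polyline_length(xy))
}

contour_rec <- function(class, xy, name = gsub("_", " ", class)) {
  rec(3L, name, class, "closed_contour", xy[, 1L], xy[, 2L],
      measure = synmorph::contour_area(xy))
}

make_profile <- function(..., image_id = "test", pixel_size = 1) {
  structure(list(image_id = image_id, records = list(...),
                 pixel_size = pixel_size, dialect = "comma"),
            class = "synapse_profile")
}

# a flat synapse: plasma membrane along y = 0 from x = -500..500,
# active zone the sub-segment x in [-200, 200] (both densely sampled so
# vertex-only and segment modes are comparable)
flat_membranes <- function(spacing = 1) {
  pm <- cbind(seq(-500, 500, by = spacing), 0)
  az <- cbind(seq(-200, 200, by = spacing), 0)
  list(pm = line_rec("plasma_membrane", pm),
       az = line_rec("active_zone", az))
}

# brute-force oracle: resample a polyline at fixed spacing and take the
# minimum point-to-sample distance
resample_polyline <- function(xy, spacing) {
  pts <- list()
  for (i in seq_len(nrow(xy) - 1L)) {
    a <- xy[i, ]; b <- xy[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / spacing) + 1L))
    pts[[i]] <- cbind(a[1L] + t * (b[1L] - a[1L]),
                      a[2L] + t * (b[2L] - a[2L]))
  }
  do.call(rbind, pts)
}

brute_point_distance <- function(p, xy, spacing = 0.01) {
  s <- resample_polyline(xy, spacing)
  sqrt(min((s[, 1L] - p[1L])^2 + (s[, 2L] - p[2L])^2))
}
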