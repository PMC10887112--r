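# Brightfield spheroid morphometry and live/dead viability quantification.

#' Measure spheroid size in a brightfield chamber ROI
#'
#' Segmentation follows the standard brightfield recipe: contrast enhancement
#' (a robust percentile stretch), automatic (Otsu) thresholding of the
#' inverted image, hole filling, then the largest connected component is
#' taken as the spheroid. The equivalent diameter is the diameter of the
#' circle with the component's area: `2 * sqrt(area / pi) * pixel_size`.
#'
#' A contrast guard precedes segmentation: when the Otsu split of the ROI
#' separates class means by less than `min_contrast` (in the image's own
#' intensity units) the chamber is treated as empty and a flagged zero-size
#' result is returned — otherwise contrast enhancement would amplify
#' background noise into spurious components.
#'
#' @param roi numeric matrix containing one chamber, intensities in `[0, 1]`.
#' @param pixel_size micrometres per pixel.
#' @param min_contrast minimum Otsu class-mean separation, in raw intensity
#'   units, for a foreground to be declared.
#' @param stretch_quantiles lower/upper percentiles mapped to 0 and 1 by the
#'   contrast stretch.
#' @return A one-row data frame of class `morphometry_result`:
#'   equivalent_diameter (um), area (um^2), area_px, empty (flag).
#' @export
measure_spheroid <- function(roi, pixel_size, min_contrast = 0.15,
                             stretch_quantiles = c(0.01, 0.99)) {
  stopifnot(is.matrix(roi), pixel_size > 0)
  rng <- range(roi)
  empty_result <- structure(
    data.frame(equivalent_diameter = 0, area = 0, area_px = 0L, empty = TRUE),
    class = c("morphometry_result", "data.frame"))
  if (diff(rng) < .Machine$double.eps) return(empty_result)
  norm <- (roi - rng[1]) / diff(rng)
  thr_raw <- EBImage::otsu(norm)
  fg <- norm < thr_raw  # spheroid is dark
  if (!any(fg) || all(fg) ||
      abs(mean(roi[!fg]) - mean(roi[fg])) < min_contrast)
    return(empty_result)
  q <- stats::quantile(roi, stretch_quantiles, names = FALSE)
  if (diff(q) <= 0) return(empty_result)
  enh <- pmin(pmax((roi - q[1]) / (q[2] - q[1]), 0), 1)
  inv <- 1 - enh
  mask <- inv > EBImage::otsu(inv)
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  if (length(areas) == 0L) return(empty_result)
  area_px <- max(areas)
  structure(data.frame(
    equivalent_diameter = 2 * sqrt(area_px / pi) * pixel_size,
    area = area_px * pixel_size^2, area_px = as.integer(area_px),
    empty = FALSE
  ), class = c("morphometry_result", "data.frame"))
}

# Count fluorescent spots in one channel. Spots are sparse, so the histogram
# is far too unbalanced for Otsu; the threshold is instead the midpoint
# between the background level (median) and the brightest pixel, with a
# contrast guard for spot-free channels. Connected components above the
# minimum area are counted.
.count_spots <- function(channel, min_area, min_contrast) {
  bg <- stats::median(channel)
  if (max(channel) - bg < min_contrast) return(list(count = 0L, area_px = 0L))
  mask <- channel > (bg + max(channel)) / 2
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- areas >= min_area
  list(count = sum(keep), area_px = sum(areas[keep]))
}

#' Quantify live/dead viability from a two-channel image pair
#'
#' Live (calcein-like, green) and dead (ethidium-homodimer-like, red)
#' channels are thresholded automatically and counted as connected components
#' above a minimum area, per the "live cells divided by total stained cells"
#' definition. Since dense spheroid staining can merge cells, a pixel-area
#' mode is offered: there viability is the green area fraction of the total
#' stained area.
#'
#' @param green,red numeric matrices of identical shape.
#' @param min_area minimum component area in pixels (default 4, suppresses
#'   noise speckle).
#' @param mode `"components"` (count cells, default) or `"area"` (stained
#'   pixel areas).
#' @param min_contrast Otsu class-separation guard; channels whose split
#'   separates class means by less hold no spots.
#' @return A one-row data frame of class `viability_result`: live_count,
#'   dead_count, viability (proportion, NA and flagged undefined when both
#'   counts are zero), undefined.
#' @export
quantify_viability <- function(green, red, min_area = 4L,
                               mode = c("components", "area"),
                               min_contrast = 0.2) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(green), is.matrix(red))
  if (!identical(dim(green), dim(red)))
    stop("green and red channels must be aligned with the same shape")
  g <- .count_spots(green, min_area, min_contrast)
  r <- .count_spots(red, min_area, min_contrast)
  num <- if (mode == "components") g$count else g$area_px
  den <- num + if (mode == "components") r$count else r$area_px
  structure(data.frame(
    live_count = g$count, dead_count = r$count,
    viability = if (den > 0) num / den else NA_real_,
    undefined = den == 0
  ), class = c("viability_result", "data.frame"))
}

#' Per-day growth summary and group differences
#'
#' Aggregates morphometry results by group and observation day (mean, SD, n),
#' computes pairwise differences of group means per day, and runs a two-sided
#' Student's t-test between groups per day where both have at least two
#' observations.
#'
#' @param results data frame with columns `group`, `day`,
#'   `equivalent_diameter`.
#' @return A list with `summary` (group, day, mean_diameter, sd_diameter, n)
#'   and `differences` (day, group_a, group_b, difference, t, p; test fields
#'   NA when a group has fewer than 2 observations).
#' @export
growth_series <- function(results) {
  stopifnot(all(c("group", "day", "equivalent_diameter") %in% names(results)))
  agg <- stats::aggregate(equivalent_diameter ~ group + day, data = results,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  summary_df <- data.frame(group = agg$group, day = agg$day,
                           mean_diameter = agg$equivalent_diameter[, "mean"],
                           sd_diameter = agg$equivalent_diameter[, "sd"],
                           n = agg$equivalent_diameter[, "n"])
  summary_df <- summary_df[order(summary_df$day, summary_df$group), ]
  rownames(summary_df) <- NULL
  groups <- sort(unique(results$group))
  diffs <- list()
  for (day in sort(unique(results$day))) {
    if (length(groups) < 2L) break
    for (i in seq_len(length(groups) - 1L)) for (j in seq((i + 1L), length(groups))) {
      a <- results$equivalent_diameter[results$group == groups[i] & results$day == day]
      b <- results$equivalent_diameter[results$group == groups[j] & results$day == day]
      if (length(a) == 0L || length(b) == 0L) next
      testable <- length(a) >= 2L && length(b) >= 2L
      tt <- if (testable) stats::t.test(a, b, var.equal = TRUE) else NULL
      diffs[[length(diffs) + 1L]] <- data.frame(
        day = day, group_a = groups[i], group_b = groups[j],
        difference = mean(a) - mean(b),
        t = if (testable) unname(tt$statistic) else NA_real_,
        p = if (testable) tt$p.value else NA_real_)
    }
  }
  list(summary = summary_df,
       differences = if (length(diffs)) do.call(rbind, diffs) else NULL)
}
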