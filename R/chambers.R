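# Microwell ROI detection, occupancy classification and chamber geometry.

#' Construct a chamber map
#'
#' @param centers numeric matrix of `(row, col)` chamber centers in pixels.
#' @param radius_px chamber radius in pixels (scalar or per chamber).
#' @param shape image shape `(rows, cols)` for the label image.
#' @param occupancy per-chamber occupancy label (`"empty"`, `"spheroid"`, or
#'   `"unclassified"`).
#' @return An object of class `chamber_map`: a `chambers` data frame
#'   (chamber_id, center_row, center_col, radius_px, occupancy) and a
#'   `label_image` of per-pixel chamber assignment (0 = background).
#' @export
chamber_map <- function(centers, radius_px, shape, occupancy = "unclassified") {
  centers <- matrix(as.numeric(centers), ncol = 2L)
  n <- nrow(centers)
  radius_px <- rep_len(radius_px, n)
  occupancy <- rep_len(occupancy, n)
  stopifnot(all(occupancy %in% c("empty", "spheroid", "unclassified")))
  ord <- order(centers[, 1], centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  radius_px <- radius_px[ord]; occupancy <- occupancy[ord]
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(n)) {
    d <- .pixel_dist(shape, centers[i, ])
    lab[d <= radius_px[i]] <- i
  }
  structure(list(
    chambers = data.frame(chamber_id = seq_len(n),
                          center_row = centers[, 1], center_col = centers[, 2],
                          radius_px = radius_px, occupancy = occupancy),
    label_image = lab
  ), class = "chamber_map")
}

#' @export
print.chamber_map <- function(x, ...) {
  tab <- table(x$chambers$occupancy)
  cat(sprintf("chamber_map: %d chamber(s) [%s]\n", nrow(x$chambers),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Detect microwell chambers by matched filtering
#'
#' Locates circular chambers of a known design diameter by normalized
#' cross-correlation of the image against a disk template, followed by greedy
#' non-maximum suppression at a minimum spacing of one chamber diameter.
#' Chamber diameter is known a priori from the device design, which makes a
#' matched filter robust at low contrast (compared to, e.g., a Hough
#' transform over unknown radii). Detections whose footprint would be
#' truncated by the image border are refused.
#'
#' Works on any image where chambers contrast with background, e.g. the DC
#' intensity of a dye-filled device (bright wells on dark background).
#'
#' @param image numeric matrix.
#' @param expected_diameter chamber diameter in micrometres.
#' @param pixel_size micrometres per pixel; the diameter must span at least 5
#'   pixels.
#' @param min_score minimum normalized cross-correlation score in `[0, 1]`.
#' @param spacing_factor minimum center spacing in chamber diameters.
#' @return A [chamber_map] with occupancy `"unclassified"`.
#' @export
detect_chambers <- function(image, expected_diameter, pixel_size,
                            min_score = 0.5, spacing_factor = 1) {
  stopifnot(is.matrix(image), expected_diameter > 0, pixel_size > 0)
  r <- expected_diameter / 2 / pixel_size
  if (2 * r < 5) stop("expected chamber diameter must span at least 5 pixels")
  w <- ceiling(r)
  L <- 2L * w + 1L
  xy <- .pixel_dist(c(L, L), c(w + 1, w + 1))
  tmpl <- (xy <= r) * 1
  t0 <- tmpl - mean(tmpl)
  box <- matrix(1, L, L)
  n <- L^2
  num <- EBImage::filter2(image, t0, boundary = 0)
  s1 <- EBImage::filter2(image, box, boundary = 0)
  s2 <- EBImage::filter2(image^2, box, boundary = 0)
  varsum <- pmax(s2 - s1^2 / n, 0)
  denom <- sqrt(varsum * sum(t0^2))
  score <- ifelse(denom > sqrt(.Machine$double.eps), num / denom, 0)
  # refuse border-truncated footprints
  ok <- matrix(FALSE, nrow(image), ncol(image))
  rr <- seq(w + 1L, nrow(image) - w); cc <- seq(w + 1L, ncol(image) - w)
  if (length(rr) && length(cc)) ok[rr, cc] <- TRUE
  cand <- which(ok & score >= min_score, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    stop(sprintf("no chamber detections at score >= %.2f (template response range %.3f .. %.3f)",
                 min_score, min(score), max(score)))
  sc <- score[cand]
  cand <- cand[order(sc, decreasing = TRUE), , drop = FALSE]
  min_d <- spacing_factor * 2 * r
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) > 0 &&
        min(sqrt((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2)) < min_d) next
    keep <- rbind(keep, p)
  }
  chamber_map(keep, radius_px = r, shape = dim(image))
}

#' Classify chamber occupancy from a brightfield image
#'
#' A chamber is spheroid-occupied when a connected dark region covering more
#' than `area_fraction` of the chamber area exists inside its ROI; otherwise
#' it is empty. "Dark" means below the midpoint between the image median
#' (background-dominated) and minimum. A manual override always wins, which
#' mirrors experiment designs where reference chambers are empty by
#' construction rather than inference.
#'
#' @param chambers a [chamber_map].
#' @param brightfield numeric brightfield matrix of matching shape.
#' @param area_fraction minimum dark area fraction of the chamber (default
#'   0.1).
#' @param override optional named character vector `chamber_id -> occupancy`
#'   taking precedence over the image.
#' @return The chamber map with occupancy filled in.
#' @export
classify_occupancy <- function(chambers, brightfield, area_fraction = 0.1,
                               override = NULL) {
  stopifnot(inherits(chambers, "chamber_map"), is.matrix(brightfield))
  cm <- chambers$chambers
  thr <- (stats::median(brightfield) + min(brightfield)) / 2
  dark <- (brightfield < thr) * 1
  lab_all <- EBImage::bwlabel(dark)
  for (i in seq_len(nrow(cm))) {
    d <- .pixel_dist(dim(brightfield), c(cm$center_row[i], cm$center_col[i]))
    roi <- d <= cm$radius_px[i]
    comps <- lab_all[roi]
    comps <- comps[comps > 0]
    biggest <- if (length(comps)) max(table(comps)) else 0
    cm$occupancy[i] <- if (biggest > area_fraction * sum(roi)) "spheroid" else "empty"
  }
  if (!is.null(override)) {
    ids <- as.integer(names(override))
    stopifnot(all(ids %in% cm$chamber_id),
              all(override %in% c("empty", "spheroid")))
    cm$occupancy[match(ids, cm$chamber_id)] <- unname(override)
  }
  chambers$chambers <- cm
  chambers
}

#' Set chamber occupancy from a design-level assignment
#'
#' @param chambers a [chamber_map].
#' @param occupancy character vector recycled over chambers (in chamber-id
#'   order).
#' @return The updated chamber map.
#' @export
set_occupancy <- function(chambers, occupancy) {
  stopifnot(inherits(chambers, "chamber_map"),
            all(occupancy %in% c("empty", "spheroid")))
  chambers$chambers$occupancy <- rep_len(occupancy, nrow(chambers$chambers))
  chambers
}

#' Cylindrical chamber volume
#'
#' `V = pi * (d/2)^2 * h`, converted from cubic micrometres to nanolitres
#' (1 nL = 1e6 um^3). The 200 um x 300 um design works out to about 9.4 nL.
#'
#' @param diameter chamber diameter in micrometres.
#' @param height chamber height in micrometres.
#' @return Volume in nanolitres.
#' @export
chamber_volume <- function(diameter, height) {
  stopifnot(all(diameter >= 0), all(height >= 0))
  pi * (diameter / 2)^2 * height / 1e6
}
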