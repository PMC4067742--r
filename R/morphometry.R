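#' Segment aggregates in a super-resolution image
#'
#' 8-connected components of grid pixels holding at least `min_count`
#' localizations. The default threshold of 2 suppresses isolated
#' single-blink pixels. Labelling is by iterative minimum-label propagation
#' over the 8-neighbourhood until a fixed point.
#'
#' @param sr_image An `sr_image`.
#' @param min_count Minimum localizations per pixel (>= 1).
#' @return An `aggregate_labels`: integer label matrix (0 = background) with
#'   a `regions` attribute, a list of data.frames (`row`, `col`, `count`)
#'   per label.
#' @export
segment_aggregates <- function(sr_image, min_count = 2L) {
  if (min_count < 1) stopf("`min_count` must be >= 1",
                           class = "flimstorm_invalid_parameter")
  counts <- unclass(sr_image)
  fg <- counts >= min_count
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_len(sum(fg))
  if (any(fg)) {
    repeat {
      new_lab <- lab
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        sr <- max(1L, 1L + di):min(nr, nr + di)
        tr <- max(1L, 1L - di):min(nr, nr - di)
        sc <- max(1L, 1L + dj):min(nc, nc + dj)
        tc <- max(1L, 1L - dj):min(nc, nc - dj)
        shifted <- matrix(0L, nr, nc)
        shifted[tr, tc] <- lab[sr, sc]
        upd <- fg & shifted > 0L & shifted < new_lab
        new_lab[upd] <- shifted[upd]
      }
      if (identical(new_lab, lab)) break
      lab <- new_lab
    }
    lab[fg] <- match(lab[fg], sort(unique(lab[fg])))
  }
  labs <- sort(unique(lab[lab > 0L]))
  regions <- lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    data.frame(row = idx[, 1L], col = idx[, 2L], count = counts[idx])
  })
  names(regions) <- labs
  structure(lab, regions = regions, bin_size = attr(sr_image, "bin_size"),
            class = "aggregate_labels")
}

#' @export
print.aggregate_labels <- function(x, ...) {
  cat(sprintf("Aggregate segmentation: %d regions in a %d x %d grid\n",
              length(attr(x, "regions")), nrow(x), ncol(x)))
  invisible(x)
}

# pixel centres of a region in nm, 0-based half-open pixel convention
region_centres_nm <- function(region, bin_size) {
  cbind(x = (region$col - 0.5) * bin_size, y = (region$row - 0.5) * bin_size)
}

#' Longest dimension of a segmented region by pixel counting
#'
#' The maximal pairwise distance between pixel centres (the Feret diameter
#' realized on the grid) plus one bin as an end-cap correction, so a single
#' pixel measures one bin and a collinear run of `n` pixels measures
#' `n * bin_size`.
#'
#' @param region data.frame with `row`, `col` (grid indices).
#' @param bin_size Grid pixel size in nm.
#' @return Longest dimension in nm.
#' @export
longest_dimension <- function(region, bin_size) {
  if (nrow(region) == 0L) stopf("region is empty", class = "flimstorm_invalid_input")
  check_scalar_pos(bin_size, "bin_size")
  feret_extents(region, bin_size)$longest
}

# Feret (max pairwise) extent and the extent orthogonal to the Feret axis,
# both with the one-bin end-cap. Uses the convex hull to keep the pairwise
# search small.
feret_extents <- function(region, bin_size) {
  pts <- region_centres_nm(region, bin_size)
  n <- nrow(pts)
  if (n == 1L)
    return(list(longest = bin_size, orthogonal = bin_size))
  hull <- if (n > 3L) pts[grDevices::chull(pts), , drop = FALSE] else pts
  d <- as.matrix(stats::dist(hull))
  ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
  p1 <- hull[ij[1L], ]; p2 <- hull[ij[2L], ]
  longest <- d[ij[1L], ij[2L]]
  axis <- (p2 - p1)
  if (longest > 0) {
    axis <- axis / longest
    perp <- c(-axis[2L], axis[1L])
    proj <- pts %*% perp
    ortho <- max(proj) - min(proj)
  } else ortho <- 0
  list(longest = longest + bin_size, orthogonal = ortho + bin_size)
}

#' Measure all aggregates in a super-resolution image
#'
#' Segments with [segment_aggregates()] and measures each region's longest
#' dimension (and the orthogonal extent, giving an aspect ratio that
#' separates elongated from spherical species).
#'
#' @param sr_image An `sr_image`.
#' @param min_count Passed to [segment_aggregates()].
#' @param condition Condition identifier (e.g. peptide x timepoint).
#' @return An `aggregate_records` data.frame: `label`, `longest_dimension`,
#'   `orthogonal_dimension`, `aspect_ratio`, `pixel_count`,
#'   `n_localizations`, `passes_filter` (NA until filtered), `condition`.
#' @export
measure_aggregates <- function(sr_image, min_count = 2L, condition = NA_character_) {
  seg <- segment_aggregates(sr_image, min_count)
  regions <- attr(seg, "regions")
  bin <- attr(seg, "bin_size")
  if (length(regions) == 0L) {
    out <- data.frame(label = integer(0), longest_dimension = numeric(0),
                      orthogonal_dimension = numeric(0),
                      aspect_ratio = numeric(0), pixel_count = integer(0),
                      n_localizations = numeric(0), passes_filter = logical(0),
                      condition = character(0))
    class(out) <- c("aggregate_records", "data.frame")
    return(out)
  }
  rows <- lapply(seq_along(regions), function(k) {
    r <- regions[[k]]
    fe <- feret_extents(r, bin)
    data.frame(label = as.integer(names(regions)[k]),
               longest_dimension = fe$longest,
               orthogonal_dimension = fe$orthogonal,
               aspect_ratio = fe$longest / fe$orthogonal,
               pixel_count = nrow(r), n_localizations = sum(r$count),
               passes_filter = NA, condition = condition)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("aggregate_records", "data.frame")
  out
}

#' Resolution-limit filter for aggregate records
#'
#' Only aggregates whose longest dimension exceeds the lateral resolution
#' limit of the experiment can be interpreted as having approximately the
#' correct size; `passes_filter` is set on every record and, by default,
#' only passing records are returned.
#'
#' @param records An `aggregate_records` data.frame.
#' @param resolution Resolution limit in nm (> 0).
#' @param keep_only If `TRUE` (default) return only passing records; the
#'   flag is set on all records either way.
#' @return `aggregate_records` with `passes_filter` set.
#' @export
filter_by_resolution <- function(records, resolution, keep_only = TRUE) {
  check_scalar_pos(resolution, "resolution")
  records$passes_filter <- records$longest_dimension > resolution
  if (keep_only) records <- records[records$passes_filter, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("aggregate_records", "data.frame")
  records
}

#' Per-condition aggregate size summary
#'
#' Mean longest dimension with SEM over passing records, pooled per
#' condition. A single record yields SEM 0 with a degenerate-n warning.
#'
#' @param records `aggregate_records` (filter flags already set, or unset in
#'   which case all records count).
#' @param condition Condition to summarize; `NULL` summarizes every
#'   condition present.
#' @return A `size_summary` data.frame: `condition`, `mean_size`, `sem_size`,
#'   `n_aggregates`.
#' @export
summarize_sizes <- function(records, condition = NULL) {
  keep <- if (all(is.na(records$passes_filter))) rep(TRUE, nrow(records))
          else !is.na(records$passes_filter) & records$passes_filter
  recs <- records[keep, , drop = FALSE]
  conds <- condition %||% unique(recs$condition)
  rows <- lapply(conds, function(cd) {
    sizes <- recs$longest_dimension[recs$condition %in% cd]
    if (length(sizes) == 0L)
      stopf("no passing aggregates in condition '%s'", cd,
            class = "flimstorm_empty_condition")
    if (length(sizes) == 1L)
      warning("single aggregate in condition '", cd, "': SEM is degenerate (0)")
    ms <- mean_sem(sizes)
    data.frame(condition = cd, mean_size = ms$mean, sem_size = ms$sem,
               n_aggregates = ms$n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("size_summary", "data.frame")
  out
}

#' @export
print.size_summary <- function(x, ...) {
  cat("Aggregate size summary (longest dimension, nm):\n")
  for (k in seq_len(nrow(x)))
    cat(sprintf("  %-20s %.1f +/- %.1f nm (SEM, n = %d)\n",
                x$condition[k], x$mean_size[k], x$sem_size[k],
                x$n_aggregates[k]))
  invisible(x)
}
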