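#' Lesion volume of interest (VOI)
#'
#' The set of tumor voxels defining one lesion: 0-based grid coordinates, the
#' SUV at each voxel, and the voxel volume in cm^3 carried over from the
#' source volume. Constructed by the segmentation functions; build directly
#' only for synthetic cases.
#'
#' @param voxel_indices integer matrix, one row per voxel, 3 columns of
#'   0-based grid coordinates; rows must be unique.
#' @param suv_values numeric SUVs aligned 1:1 with the index rows.
#' @param voxel_volume voxel volume in cm^3.
#' @param label free-text lesion label, e.g. `"primary"` or `"axillary LN"`.
#' @return An object of class `lesion_voi`.
#' @export
lesion_voi <- function(voxel_indices, suv_values, voxel_volume, label = "lesion") {
  voxel_indices <- matrix(as.integer(voxel_indices), ncol = 3)
  if (nrow(voxel_indices) == 0L) stop("a VOI must contain at least one voxel")
  if (nrow(voxel_indices) != length(suv_values))
    stop("suv_values must align 1:1 with voxel_indices")
  if (anyDuplicated(voxel_indices)) stop("duplicate voxel indices in VOI")
  if (!is.numeric(voxel_volume) || voxel_volume <= 0)
    stop("voxel_volume must be > 0 cm^3")
  structure(list(voxel_indices = voxel_indices,
                 suv_values = as.numeric(suv_values),
                 voxel_volume = voxel_volume, label = label),
            class = "lesion_voi")
}

#' @export
print.lesion_voi <- function(x, ...) {
  cat(sprintf("Lesion VOI '%s': %d voxels (%.3g cm^3), SUV %.3g-%.3g\n",
              x$label, nrow(x$voxel_indices),
              nrow(x$voxel_indices) * x$voxel_volume,
              min(x$suv_values), max(x$suv_values)))
  invisible(x)
}

# 26-neighbourhood offsets (all nonzero sign combinations in 3-D)
.offsets26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

# Connected component of `mask` containing `seed` (1-based coords), by
# breadth-first search with vectorised frontier expansion.
.connected_component <- function(mask, seed) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, ncol = 3)
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(.offsets26)), , drop = FALSE] +
      .offsets26[rep(seq_len(nrow(.offsets26)), nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- unique(nb[ok, , drop = FALSE])
    keep <- mask[nb] & !visited[nb]
    frontier <- nb[keep, , drop = FALSE]
    visited[frontier] <- TRUE
  }
  which(visited, arr.ind = TRUE)
}

#' Segment a lesion at a fixed SUV threshold
#'
#' Returns the 26-connected component of voxels with SUV at or above
#' `threshold` that contains the seed voxel. The default threshold of SUV 2.5
#' is the fixed-threshold VOI definition used for MTV/TLG and for the CSC
#' parameters; the comparison is inclusive (a voxel exactly at the threshold
#' belongs to the lesion).
#'
#' @param vol an [suv_volume()].
#' @param seed integer length-3, 0-based grid coordinates of a voxel inside
#'   the lesion; its SUV must be at or above the threshold.
#' @param threshold SUV threshold, default 2.5.
#' @param label lesion label stored on the VOI.
#' @return A [lesion_voi()].
#' @export
segment_fixed_threshold <- function(vol, seed, threshold = 2.5, label = "lesion") {
  stopifnot(inherits(vol, "suv_volume"))
  seed <- as.integer(seed) + 1L  # to 1-based
  d <- dim(vol$data)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed voxel outside grid bounds")
  if (vol$data[seed[1], seed[2], seed[3]] < threshold)
    stop(sprintf("seed not avid: SUV %.3g below threshold %.3g",
                 vol$data[seed[1], seed[2], seed[3]], threshold))
  idx <- .connected_component(vol$data >= threshold, seed)
  lesion_voi(idx - 1L, vol$data[idx], vol$voxel_volume, label = label)
}

#' Segment the 40%-of-SUVmax relative-threshold volume
#'
#' Takes SUVmax within `base_voi` (the fixed-threshold VOI), thresholds the
#' volume at `fraction * SUVmax`, and returns the 26-connected component
#' anchored at the base VOI's hottest voxel. A tie for the hottest voxel is
#' broken by the lowest (z, y, x) lexicographic index so the result is
#' deterministic.
#'
#' @param vol an [suv_volume()].
#' @param base_voi the fixed-threshold [lesion_voi()] for the same lesion.
#' @param fraction fraction of SUVmax, default 0.40.
#' @return A [lesion_voi()].
#' @export
segment_relative_threshold <- function(vol, base_voi, fraction = 0.40) {
  stopifnot(inherits(vol, "suv_volume"), inherits(base_voi, "lesion_voi"))
  suvmax <- max(base_voi$suv_values)
  hottest <- which(base_voi$suv_values == suvmax)
  if (length(hottest) > 1) {
    zyx <- base_voi$voxel_indices[hottest, c(3, 2, 1), drop = FALSE]
    hottest <- hottest[do.call(order, as.data.frame(zyx))[1]]
  }
  peak <- base_voi$voxel_indices[hottest, ] + 1L
  idx <- .connected_component(vol$data >= fraction * suvmax, peak)
  lesion_voi(idx - 1L, vol$data[idx], vol$voxel_volume,
             label = paste0(base_voi$label, "_40pct"))
}

#' FDG-avidity inclusion check
#'
#' A lesion (or whole volume) qualifies for analysis only if its SUVmax is at
#' least 2.5; non-avid tumors cannot be delineated at the fixed threshold and
#' are excluded from the cohort pipeline.
#'
#' @param x a [lesion_voi()], [suv_volume()], or numeric vector of SUVs.
#' @param threshold avidity threshold, default 2.5 (inclusive).
#' @return `TRUE` if SUVmax >= threshold.
#' @export
check_avidity <- function(x, threshold = 2.5) {
  suvs <- if (inherits(x, "lesion_voi")) x$suv_values
          else if (inherits(x, "suv_volume")) x$data
          else x
  if (length(suvs) == 0) stop("empty input")
  max(suvs) >= threshold
}

#' Export / import a VOI as JSON
#'
#' @param voi a [lesion_voi()].
#' @param path JSON file path.
#' @return `read_voi_json` returns a [lesion_voi()]; `write_voi_json` returns
#'   `path` invisibly.
#' @export
write_voi_json <- function(voi, path) {
  stopifnot(inherits(voi, "lesion_voi"))
  jsonlite::write_json(
    list(label = voi$label, voxel_volume = voi$voxel_volume,
         voxel_indices = voi$voxel_indices, suv_values = voi$suv_values),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_voi_json
#' @export
read_voi_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lesion_voi(x$voxel_indices, x$suv_values, x$voxel_volume, label = x$label)
}

#' Export a VOI as a 0/1 NIfTI mask
#'
#' @param voi a [lesion_voi()].
#' @param dim grid dimensions of the source volume.
#' @param spacing voxel spacing in mm.
#' @param path output NIfTI path.
#' @export
write_voi_mask <- function(voi, dim, spacing, path) {
  mask <- array(0, dim)
  mask[voi$voxel_indices + 1L] <- 1
  write_volume(suv_volume(mask, spacing = spacing), path)
}
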