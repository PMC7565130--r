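#' Three-way partition of a lesion's SUV histogram
#'
#' The voxel SUVs of a lesion VOI are split into `k = 3` clusters by k-means.
#' The highest-centroid cluster is read as the proliferative, most glycolytic
#' compartment (the CSC proxy), the lowest as differentiated cancer cells,
#' and the middle as a mixed population arising from the limited spatial
#' resolution of PET (4-mm voxels contain both phenotypes).
#'
#' Two clustering engines are provided. The default `"exact-dp"` computes the
#' globally WCSS-optimal partition by dynamic programming on the sorted
#' values — for 1-D data the optimum is a set of contiguous segments, so the
#' exact solution is cheap and fully deterministic. `"lloyd"` is standard
#' Lloyd k-means with k-means++ seeding under `seed`, retained as a fidelity
#' mode for comparison with generic k-means software.
#'
#' Clustering operates on the full voxel-value list by default (each voxel is
#' one observation). Setting `bin_width` switches to a binned-histogram mode
#' in which SUVs are snapped to bin centres and bins are weighted by their
#' counts, for sensitivity analysis of histogram-software pipelines.
#'
#' @param voi a [lesion_voi()] with at least `k` distinct SUV values.
#' @param k number of clusters, default 3.
#' @param method `"exact-dp"` (default) or `"lloyd"`.
#' @param seed integer seed for the Lloyd mode (ignored by exact-dp).
#' @param bin_width optional SUV bin width (e.g. 0.1) for binned mode.
#' @return An object of class `cluster_partition`: `labels` (cluster id 0, 1,
#'   ..., k-1 per VOI voxel, numbered so centroids ascend — cluster k-1 is the
#'   most glycolytic), `centroids` (ascending SUV), `sizes` (voxels per
#'   cluster), `wcss` (within-cluster sum of squares, SUV^2), `method`.
#' @examples
#' voi <- lesion_voi(cbind(0:14, 0, 0), rep(c(3, 6, 9), each = 5), 0.064)
#' cluster_suv_histogram(voi)$centroids  # 3 6 9
#' @export
cluster_suv_histogram <- function(voi, k = 3, method = c("exact-dp", "lloyd"),
                                  seed = 1L, bin_width = NULL) {
  stopifnot(inherits(voi, "lesion_voi"))
  method <- match.arg(method)
  x <- voi$suv_values
  if (!is.null(bin_width)) {
    if (bin_width <= 0) stop("bin_width must be > 0")
    x <- (floor(x / bin_width) + 0.5) * bin_width  # snap to bin centres
  }
  n_distinct <- length(unique(x))
  if (n_distinct < k)
    stop(sprintf("degenerate histogram: %d distinct SUV value(s), need >= %d",
                 n_distinct, k))
  fit <- if (method == "exact-dp") .cluster_dp(x, k) else .cluster_lloyd(x, k, seed)
  structure(list(labels = fit$labels, centroids = fit$centroids,
                 sizes = fit$sizes, wcss = fit$wcss, method = method),
            class = "cluster_partition")
}

# Exact DP on distinct sorted values with multiplicity weights; identical to
# running on the full list, at lower n.
.cluster_dp <- function(x, k) {
  ux <- sort(unique(x))
  pos <- match(x, ux)
  fit <- .kmeans_dp_cpp(ux, as.numeric(tabulate(pos, nbins = length(ux))), k)
  labels <- fit$labels[pos]                       # 0-based, ascending by construction
  list(labels = labels, centroids = fit$centroids,
       sizes = as.integer(tabulate(labels + 1L, nbins = k)), wcss = fit$wcss)
}

# Lloyd k-means with k-means++ seeding; labels renumbered so centroids
# ascend. Coincident centroids (possible on adversarial draws) trigger a
# reseeded rerun, up to 10 attempts.
.cluster_lloyd <- function(x, k, seed) {
  for (attempt in seq_len(10)) {
    centers <- withr_seed(seed + attempt - 1L, .kmeanspp_init(x, k))
    km <- suppressWarnings(
      stats::kmeans(x, centers = matrix(centers, ncol = 1),
                    algorithm = "Lloyd", iter.max = 100))
    cen <- as.numeric(km$centers)
    if (anyDuplicated(cen) == 0) {
      ord <- order(cen)
      relab <- match(km$cluster, ord) - 1L
      return(list(labels = relab, centroids = cen[ord],
                  sizes = as.integer(km$size[ord]), wcss = km$tot.withinss))
    }
  }
  stop("Lloyd clustering produced coincident centroids in 10 seeded attempts")
}

# k-means++: first centre uniform, then D^2-weighted draws
.kmeanspp_init <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  d2 <- (x - centers[1])^2
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) d2[] <- 1
    centers[j] <- x[sample.int(length(x), 1, prob = d2)]
    d2 <- pmin(d2, (x - centers[j])^2)
  }
  centers
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("SUV partition (%s): centroids %s; sizes %s; WCSS %.4g\n",
              x$method, paste(signif(x$centroids, 4), collapse = " / "),
              paste(x$sizes, collapse = " / "), x$wcss))
  invisible(x)
}

#' CSC metabolic parameters of a lesion
#'
#' Volumetrics of the most glycolytic (highest-centroid) cluster:
#' `mtv_csc` = cluster voxel count x voxel volume (cm^3), `tlg_csc` = summed
#' cluster SUV x voxel volume (SUV.cm^3), and `csc_proportion` = 100 x
#' MTVcsc / MTV (percent of the fixed-threshold lesion volume).
#'
#' @param voi the fixed-threshold [lesion_voi()].
#' @param partition the [cluster_suv_histogram()] partition of the same VOI.
#' @return A one-row data.frame with `mtv_csc`, `tlg_csc`, `csc_proportion`.
#' @export
csc_parameters <- function(voi, partition) {
  stopifnot(inherits(voi, "lesion_voi"), inherits(partition, "cluster_partition"))
  if (length(partition$labels) != length(voi$suv_values))
    stop("partition voxel count does not match the VOI")
  top <- max(partition$labels)
  in_top <- partition$labels == top
  mtv <- length(voi$suv_values) * voi$voxel_volume
  data.frame(mtv_csc = sum(in_top) * voi$voxel_volume,
             tlg_csc = sum(voi$suv_values[in_top]) * voi$voxel_volume,
             csc_proportion = 100 * sum(in_top) / length(voi$suv_values))
}

#' Conventional metabolic parameters of a lesion
#'
#' SUVmax, MTV and TLG on the fixed-threshold (SUV 2.5) VOI, and MTV40%/TLG40%
#' on the 40%-of-SUVmax VOI. TLG is computed as summed voxel SUV x voxel
#' volume, the usual mean-SUV x MTV identity.
#'
#' @param voi the fixed-threshold [lesion_voi()].
#' @param voi40 the relative-threshold [lesion_voi()] from
#'   [segment_relative_threshold()]; must share the voxel volume.
#' @return A one-row data.frame with `suv_max`, `mtv`, `tlg`, `mtv40`, `tlg40`.
#' @export
conventional_parameters <- function(voi, voi40) {
  stopifnot(inherits(voi, "lesion_voi"), inherits(voi40, "lesion_voi"))
  if (abs(voi$voxel_volume - voi40$voxel_volume) > 1e-12)
    stop("VOIs have different voxel volumes")
  vv <- voi$voxel_volume
  data.frame(suv_max = max(voi$suv_values),
             mtv = length(voi$suv_values) * vv,
             tlg = sum(voi$suv_values) * vv,
             mtv40 = length(voi40$suv_values) * vv,
             tlg40 = sum(voi40$suv_values) * vv)
}

#' Patient-level MTVcsc across lesions
#'
#' MTVcsc is measured in every avid lesion (breast primary and axillary
#' nodes); the patient-level value is the maximum across lesions, with the
#' contributing lesion recorded. In the study cohort the primary tumor
#' carried the maximum in most patients.
#'
#' @param lesions named numeric vector (or list) of per-lesion `mtv_csc`
#'   values in cm^3; names are lesion labels.
#' @return A list with `mtv_csc` (the maximum) and `lesion` (its label).
#' @export
patient_level_mtvcsc <- function(lesions) {
  v <- unlist(lesions)
  if (length(v) == 0) stop("no lesions supplied")
  i <- which.max(v)
  list(mtv_csc = unname(v[i]),
       lesion = if (is.null(names(v))) as.character(i) else names(v)[i])
}
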