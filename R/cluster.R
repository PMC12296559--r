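# Top-fraction voxel selection within labelled regions and DBSCAN clustering
# of source-space maps.

#' Select the top fraction of voxels in a source map
#'
#' Ranks voxels carrying a non-excluded region label and keeps the strongest
#' `ceiling(fraction * n_eligible)`. For power maps (`ranking = "signed"`)
#' ranking is by value, descending. For ratio maps (`ranking = "two_sided"`)
#' the positive and negative sides are ranked by magnitude separately and
#' `ceiling(fraction * n_side)` voxels kept per side, since condition
#' contrasts are meaningful in both directions. `"abs"` ranks all voxels by
#' magnitude in one family. Ties break by voxel order, so selection is
#' deterministic.
#'
#' @param map a [source_power_map()].
#' @param labels character region label per map voxel (atlas substitute);
#'   `NA` labels are ineligible.
#' @param fraction fraction of eligible voxels to keep (default 0.01).
#' @param exclude_labels labels to drop before ranking (e.g. cerebellar
#'   regions); default none.
#' @param ranking `"signed"`, `"two_sided"` or `"abs"`; default `"signed"`
#'   for power/NAI maps and `"two_sided"` for ratio maps.
#' @return data.frame with `voxel` (index into the map's voxel set), `value`,
#'   `side` (`"pos"`/`"neg"`).
#' @export
select_top_voxels <- function(map, labels, fraction = 0.01,
                              exclude_labels = character(0), ranking = NULL) {
  stopifnot(inherits(map, "source_power_map"))
  assert_that(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  assert_that(length(labels) == length(map$value),
              "need one label per map voxel")
  if (is.null(ranking)) {
    ranking <- if (identical(map$kind, "ratio")) "two_sided" else "signed"
  }
  ranking <- match.arg(ranking, c("signed", "two_sided", "abs"))
  eligible <- which(!is.na(labels) & !(labels %in% exclude_labels))
  assert_that(length(eligible) > 0, "no eligible voxels after label exclusion")
  v <- map$value[eligible]
  pick_top <- function(idx, key) {
    k <- ceiling(fraction * length(idx))
    idx[order(-key, idx)[seq_len(min(k, length(idx)))]]
  }
  sel <- switch(ranking,
    signed = pick_top(eligible, v),
    abs = pick_top(eligible, abs(v)),
    two_sided = {
      pos <- eligible[v > 0]
      neg <- eligible[v < 0]
      c(if (length(pos)) pick_top(pos, map$value[pos]),
        if (length(neg)) pick_top(neg, -map$value[neg]))
    })
  sel <- sort(sel)
  data.frame(voxel = map$voxels[sel], value = map$value[sel],
             side = ifelse(map$value[sel] >= 0, "pos", "neg"))
}

#' DBSCAN clustering of source voxels
#'
#' Standard density-based clustering with the Euclidean metric. With
#' `min_points = 2` (the default) clusters coincide with the connected
#' components of the eps-neighborhood graph and singletons are noise.
#' On a cubic lattice, `eps = 1.5 * grid spacing` connects face neighbors
#' (distance 1 spacing) and edge neighbors (sqrt(2) ~ 1.41 spacing) but not
#' corner neighbors (sqrt(3) ~ 1.73) or two-step axial neighbors (2).
#'
#' @param points n x 3 matrix of voxel coordinates (metres).
#' @param eps neighborhood radius (metres).
#' @param min_points minimum neighborhood size (including the point itself)
#'   for a core point; default 2.
#' @param labels optional region label per point, used for the per-cluster
#'   label histogram.
#' @param values optional map value per point (mean reported per cluster).
#' @return An object of class `cluster_set`: `assignment` (integer per point,
#'   `NA` = noise), `clusters` (list of member index vectors), `centroids`,
#'   `summary` data.frame (`cluster`, `n_voxels`, centroid, `dominant_label`,
#'   `mean_value`), `eps`, `min_points`.
#' @export
dbscan_cluster <- function(points, eps, min_points = 2L, labels = NULL,
                           values = NULL) {
  assert_that(eps > 0, "eps must be positive")
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) {
    return(structure(list(assignment = integer(0), clusters = list(),
                          centroids = matrix(0, 0, 3),
                          summary = data.frame(), eps = eps,
                          min_points = min_points),
                     class = "cluster_set"))
  }
  d2 <- as.matrix(stats::dist(points))^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))  # includes i
  core <- vapply(nb, length, 0L) >= min_points
  assignment <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(assignment[i])) next
    cl <- cl + 1L
    assignment[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (is.na(assignment[j])) {
        assignment[j] <- cl
        if (core[j]) queue <- union(queue, nb[[j]][is.na(assignment[nb[[j]]])])
      }
    }
  }
  ids <- seq_len(cl)
  clusters <- lapply(ids, function(k) which(assignment == k))
  centroids <- t(vapply(clusters, function(m) colMeans(points[m, , drop = FALSE]),
                        numeric(3)))
  summ <- do.call(rbind, lapply(ids, function(k) {
    m <- clusters[[k]]
    dom <- if (!is.null(labels)) {
      names(sort(table(labels[m]), decreasing = TRUE))[1]
    } else NA_character_
    data.frame(cluster = k, n_voxels = length(m),
               x = centroids[k, 1], y = centroids[k, 2], z = centroids[k, 3],
               dominant_label = dom,
               mean_value = if (!is.null(values)) mean(values[m]) else NA_real_)
  }))
  structure(list(assignment = assignment, clusters = clusters,
                 centroids = centroids,
                 summary = if (is.null(summ)) data.frame() else summ,
                 eps = eps, min_points = min_points,
                 labels = labels),
            class = "cluster_set")
}
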