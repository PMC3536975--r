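#' Top-k voxels of a t map
#'
#' Returns the k voxels with the highest t values (the values
#' themselves, not their magnitudes). Boundary ties are broken by
#' lowest linear index so the selection is deterministic.
#'
#' @param tValues Per-voxel t values.
#' @param k Number of voxels to keep (default 500).
#' @return Sorted integer vector of linear voxel indices.
#' @export
topVoxels <- function(tValues, k = 500L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- length(tValues)
  if (k > n) {
    warning(sprintf("k = %d exceeds the %d available voxels; returning all", k, n))
    k <- n
  }
  ord <- order(-tValues, seq_len(n))
  sort(ord[seq_len(k)])
}

#' Merge per-contrast voxel selections
#'
#' Set union of the four top-k selections; the result size is at most
#' 4k.
#'
#' @param masks List of integer index vectors (typically one per t
#'   map).
#' @return Sorted unique indices, with a `"source"` attribute retaining
#'   the input list.
#' @export
mergeSelections <- function(masks) {
  out <- sort(unique(unlist(masks, use.names = FALSE)))
  attr(out, "source") <- masks
  out
}

#' Remove small clusters from a voxel selection
#'
#' Computes connected components of the selected voxels under the given
#' 3D neighbourhood and drops components smaller than `minCluster`
#' voxels. 6-connectivity (face adjacency) is the default; 18 and 26
#' are selectable.
#'
#' @param voxels Integer linear voxel indices.
#' @param dims Volume grid dimensions.
#' @param minCluster Minimum surviving component size (default 5).
#' @param connectivity 6, 18 or 26.
#' @param source Optional named list recording which t map proposed
#'   which voxels (carried into the mask).
#' @return A [FeatureMask-class].
#' @export
removeSmallClusters <- function(voxels, dims, minCluster = 5L,
                                connectivity = 6L, source = list()) {
  minCluster <- as.integer(minCluster)
  if (minCluster < 1L) stop("minCluster must be >= 1", call. = FALSE)
  dims <- as.integer(dims)
  voxels <- sort(unique(as.integer(voxels)))
  if (!length(voxels)) {
    return(new("FeatureMask", voxelIndices = integer(), clusterLabels = integer(),
               source = source, dims = dims))
  }
  offsets <- neighborOffsets(connectivity)
  ijk <- linearToIjk(voxels, dims)
  edges <- integer()
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(ijk, 2, offsets[r, ], "+")
    valid <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(valid)) next
    nbIdx <- ijkToLinear(nb[valid, , drop = FALSE], dims)
    pos <- match(nbIdx, voxels)
    hit <- !is.na(pos)
    if (any(hit)) {
      edges <- c(edges, rbind(which(valid)[hit], pos[hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(voxels), directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$membership %in% which(comp$csize >= minCluster)
  labels <- comp$membership[keep]
  # relabel components 1..m in order of first appearance
  labels <- as.integer(match(labels, unique(labels)))
  new("FeatureMask", voxelIndices = voxels[keep], clusterLabels = labels,
      source = source, dims = dims)
}

neighborOffsets <- function(connectivity) {
  all <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  all <- all[rowSums(abs(all)) > 0, , drop = FALSE]
  ord <- rowSums(abs(all))
  half <- all[all[, 1] > 0 | (all[, 1] == 0 & all[, 2] > 0) |
                (all[, 1] == 0 & all[, 2] == 0 & all[, 3] > 0), , drop = FALSE]
  ordHalf <- rowSums(abs(half))
  switch(as.character(connectivity),
         "6" = half[ordHalf == 1, , drop = FALSE],
         "18" = half[ordHalf <= 2, , drop = FALSE],
         "26" = half,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

#' Full voxel selection from four t maps
#'
#' The two-step selection of the localizer analysis: merge the voxels
#' with the `k` highest values from each of the four contrast t maps,
#' then remove clusters smaller than `minCluster` voxels.
#'
#' @param tMaps Named list of four per-voxel t-value vectors.
#' @param dims Volume grid dimensions.
#' @param k Top voxels per map (default 500).
#' @param minCluster Minimum cluster size (default 5).
#' @param connectivity Neighbourhood for clustering (default 6).
#' @return A [FeatureMask-class].
#' @export
selectFeatures <- function(tMaps, dims, k = 500L, minCluster = 5L,
                           connectivity = 6L) {
  perMap <- lapply(tMaps, topVoxels, k = k)
  merged <- mergeSelections(perMap)
  removeSmallClusters(merged, dims = dims, minCluster = minCluster,
                      connectivity = connectivity, source = perMap)
}

#' @rdname selectFeatures
#' @param x A `FeatureMask`.
#' @export
setGeneric("maskIndices", function(x) standardGeneric("maskIndices"))

#' @rdname selectFeatures
#' @export
setMethod("maskIndices", "FeatureMask", function(x) x@voxelIndices)

#' @rdname selectFeatures
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname selectFeatures
#' @export
setMethod("clusterLabels", "FeatureMask", function(x) x@clusterLabels)

setMethod("length", "FeatureMask", function(x) length(x@voxelIndices))

setMethod("show", "FeatureMask", function(object) {
  cat(sprintf("FeatureMask: %d voxels in %d clusters on a %s grid\n",
              length(object@voxelIndices),
              length(unique(object@clusterLabels)),
              paste(object@dims, collapse = " x ")))
})

#' Export a feature mask
#'
#' Writes the mask both as a binary 3D NIfTI and as a plain-text list of
#' linear voxel indices.
#'
#' @param mask A [FeatureMask-class].
#' @param niftiPath,indexPath Output paths (either may be `NULL` to
#'   skip).
#' @param voxelMm Voxel size for the NIfTI header.
#' @export
writeMask <- function(mask, niftiPath = NULL, indexPath = NULL,
                      voxelMm = c(1, 1, 1)) {
  stopifnot(is(mask, "FeatureMask"))
  if (!is.null(niftiPath)) {
    vol <- array(0L, dim = mask@dims)
    vol[mask@voxelIndices] <- 1L
    writeVolume3d(vol, niftiPath, voxelMm = voxelMm)
  }
  if (!is.null(indexPath)) {
    writeLines(as.character(mask@voxelIndices), indexPath)
  }
  invisible(mask)
}
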