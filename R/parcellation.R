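#' Parcellation container
#'
#' An integer label volume (0 = background) together with, for each parcel, a
#' unit-sphere centroid used by the spin permutation test. Mirrors the way
#' cortical atlases (e.g., a 200-parcel cortical parcellation) are used for
#' regional summaries: subcortex and unlabeled tissue are background and never
#' contribute.
#'
#' @param labels integer 3D array, 0 for background.
#' @param centroids numeric matrix (parcels x 3), rows unit-norm, row order
#'   matching `parcel_ids`.
#' @param parcel_ids integer vector of parcel labels; defaults to the sorted
#'   nonzero labels present in `labels`.
#' @return object of class `"parcellation"`.
#' @export
parcellation <- function(labels, centroids, parcel_ids = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  if (is.null(parcel_ids))
    parcel_ids <- sort(unique(labels[labels > 0]))
  parcel_ids <- as.integer(parcel_ids)
  if (length(parcel_ids) == 0L) stop("no nonzero labels")
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != length(parcel_ids) || ncol(centroids) != 3L)
    stop("'centroids' must be a (n_parcels x 3) matrix")
  norms <- sqrt(rowSums(centroids^2))
  if (any(abs(norms - 1) > 1e-12))
    stop("centroids must be unit vectors")
  present <- unique(labels[labels > 0])
  if (!all(parcel_ids %in% present))
    stop("every parcel_id must occur in 'labels'")
  structure(list(labels = labels, parcel_ids = parcel_ids,
                 centroids = centroids), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d parcels, %d labeled voxels\n",
              length(x$parcel_ids), sum(x$labels > 0)))
  invisible(x)
}

#' Per-parcel medians of a volumetric map
#'
#' Regional summary used throughout the parcel-level analyses: the median of
#' the map's voxel values within each parcel, in `parcel_ids` order. Even
#' parcel sizes average the two central values, consistent with the group
#' median convention.
#'
#' @param map a [volume_map()] on the parcellation's grid.
#' @param parc a [parcellation()].
#' @return numeric vector, one median per parcel.
#' @export
parcel_medians <- function(map, parc) {
  if (!identical(dim(map$values), dim(parc$labels)))
    stop("map grid does not match parcellation grid")
  lab <- parc$labels
  keep <- lab > 0
  med <- tapply(map$values[keep], lab[keep], stats::median)
  got <- as.integer(names(med))
  if (!all(parc$parcel_ids %in% got))
    stop("empty parcel(s): ",
         paste(setdiff(parc$parcel_ids, got), collapse = ", "))
  as.numeric(med[match(parc$parcel_ids, got)])
}

#' Renumber parcels contiguously
#'
#' Relabels parcels 1..n in order of first appearance in the label volume,
#' reordering the centroid table to keep each parcel paired with its
#' centroid.
#'
#' @param parc a [parcellation()].
#' @return a [parcellation()] with `parcel_ids == 1:n`.
#' @export
relabel_contiguous <- function(parc) {
  lab <- parc$labels
  nz <- lab[lab > 0]
  if (length(nz) == 0L) stop("no nonzero labels")
  first <- unique(as.vector(nz))        # order of first appearance
  new <- array(0L, dim(lab))
  new[lab > 0] <- match(nz, first)
  centroids <- parc$centroids[match(first, parc$parcel_ids), , drop = FALSE]
  parcellation(new, centroids, parcel_ids = seq_along(first))
}

#' Read / write parcel geometry as CSV
#'
#' Centroid tables use columns `parcel_id,x,y,z` (unit-sphere coordinates);
#' parcel value vectors use `parcel_id,value`.
#'
#' @param parc a [parcellation()].
#' @param path file path.
#' @export
write_centroids_csv <- function(parc, path) {
  df <- data.frame(parcel_id = parc$parcel_ids,
                   x = parc$centroids[, 1L],
                   y = parc$centroids[, 2L],
                   z = parc$centroids[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids_csv
#' @return `read_centroids_csv()` returns a matrix with rownames the parcel
#'   ids.
#' @export
read_centroids_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("parcel_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("centroid CSV must have columns parcel_id,x,y,z")
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$parcel_id
  m
}

#' @rdname write_centroids_csv
#' @param values numeric vector ordered as `parc$parcel_ids`.
#' @export
write_parcel_csv <- function(values, parc, path) {
  utils::write.csv(data.frame(parcel_id = parc$parcel_ids, value = values),
                   path, row.names = FALSE)
  invisible(path)
}
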