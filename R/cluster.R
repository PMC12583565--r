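#' Hierarchical clustering of samples over a probe set
#'
#' Agglomerative clustering of sample columns on distances over the
#' selected probes' beta values (the usual episignature heatmap ordering).
#' Samples are sorted lexicographically before the merge so the result is
#' independent of input column order, with ties broken by sample id.
#'
#' @param beta Beta matrix.
#' @param probe_set Probe ids (or a [select_probes()] result).
#' @param metric Distance metric for [stats::dist()]; default
#'   `"euclidean"`.
#' @param linkage Linkage for [stats::hclust()]; default `"ward.D2"`.
#' @return Object of class `episig_dendrogram`: the underlying `hclust`
#'   fit plus `labels`, `leaf_order`, `linkage`, `metric`.
#' @export
hierarchical_cluster <- function(beta, probe_set, metric = "euclidean",
                                 linkage = "ward.D2") {
  probes <- .probe_ids_of(probe_set)
  missing_p <- setdiff(probes, rownames(beta))
  if (length(missing_p))
    stop("probes absent from beta matrix: ", paste(missing_p, collapse = ", "))
  if (ncol(beta) < 2L) stop("clustering needs at least 2 samples")
  ids <- sort(colnames(beta))
  X <- t(beta[probes, ids, drop = FALSE])
  hc <- stats::hclust(stats::dist(X, method = metric), method = linkage)
  structure(list(hclust = hc, labels = ids, leaf_order = ids[hc$order],
                 linkage = linkage, metric = metric),
            class = "episig_dendrogram")
}

#' @export
print.episig_dendrogram <- function(x, ...) {
  cat(sprintf("episig_dendrogram: %d samples, %s linkage on %s distance\n",
              length(x$labels), x$linkage, x$metric))
  invisible(x)
}

#' @export
plot.episig_dendrogram <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Classical (Torgerson) metric MDS embedding of samples
#'
#' Double-centers the squared Euclidean distance matrix over the selected
#' probes and returns the top `dims` principal coordinates. Coordinates are
#' centered by construction; the sign of each axis is fixed so that its
#' first nonzero loading (in sample-id order) is positive, making plots and
#' tests reproducible.
#'
#' @param beta Beta matrix.
#' @param probe_set Probe ids (or a [select_probes()] result).
#' @param dims Embedding dimension (default 2; must be < number of
#'   samples).
#' @return Data frame `sample_id`, `x`, `y` (further axes named `dim3`,
#'   ... when `dims > 2`).
#' @export
mds_embed <- function(beta, probe_set, dims = 2L) {
  probes <- .probe_ids_of(probe_set)
  missing_p <- setdiff(probes, rownames(beta))
  if (length(missing_p))
    stop("probes absent from beta matrix: ", paste(missing_p, collapse = ", "))
  n <- ncol(beta)
  if (dims >= n) stop("dims must be smaller than the number of samples")
  if (n < 3L && dims >= 2L) stop("need at least 3 samples for a 2-D embedding")
  ids <- sort(colnames(beta))
  X <- t(beta[probes, ids, drop = FALSE])
  co <- stats::cmdscale(stats::dist(X), k = dims)
  # pad with zero axes when the configuration is degenerate (< dims rank)
  if (ncol(co) < dims)
    co <- cbind(co, matrix(0, nrow = n, ncol = dims - ncol(co)))
  for (j in seq_len(ncol(co))) {
    nz <- which(abs(co[, j]) > 1e-12)
    if (length(nz) && co[nz[1L], j] < 0) co[, j] <- -co[, j]
  }
  out <- data.frame(sample_id = ids, co, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[-1L] <- c("x", "y", if (dims > 2L) paste0("dim", 3:dims))[seq_len(dims)]
  out
}

#' Projection of samples onto the case-control centroid axis
#'
#' Utility for mosaic-intermediacy checks: projects each embedded sample
#' onto the axis from the control centroid (0) to the case centroid (1).
#'
#' @param embedding [mds_embed()] output.
#' @param case_ids,control_ids Sample ids defining the two centroids.
#' @return Named numeric vector of projections for all embedded samples.
#' @export
centroid_axis_projection <- function(embedding, case_ids, control_ids) {
  co <- as.matrix(embedding[, setdiff(names(embedding), "sample_id")])
  rownames(co) <- embedding$sample_id
  c_ctrl <- colMeans(co[control_ids, , drop = FALSE])
  c_case <- colMeans(co[case_ids, , drop = FALSE])
  axis <- c_case - c_ctrl
  denom <- sum(axis^2)
  if (denom < 1e-24) stop("case and control centroids coincide")
  drop((sweep(co, 2L, c_ctrl) %*% axis) / denom)
}
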