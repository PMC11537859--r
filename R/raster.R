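#' Spike-count raster
#'
#' Container for a population spike-count matrix binned at a fixed width
#' (40 ms by default, matching 25-Hz behavioral video).  Rows are neurons,
#' columns are time bins.  Each neuron carries a putative cell-type label
#' (fast-spiking `"FS"`, regular-spiking `"RS"`, or `"unclassified"`) and
#' each bin a segment id; contiguous runs of the same id delimit the
#' independent recording segments (e.g. spontaneous periods) that the HMM
#' treats as separate chains.
#'
#' @param counts integer matrix, neurons x bins, non-negative.
#' @param bin_width bin duration in seconds (default 0.040).
#' @param cell_type character vector of per-neuron labels in
#'   `c("FS", "RS", "unclassified")`; recycled default `"unclassified"`.
#' @param segment_id integer vector of per-bin segment ids, non-decreasing;
#'   default: a single segment.
#' @return An object of class `spike_raster` with elements `counts`,
#'   `bin_width`, `cell_type`, `segment_id`.
#' @export
spike_raster <- function(counts, bin_width = 0.040, cell_type = NULL,
                         segment_id = NULL) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a positive scalar (seconds)")
  nc <- nrow(counts); nt <- ncol(counts)
  cell_type <- cell_type %||% rep("unclassified", nc)
  if (length(cell_type) != nc)
    stop("`cell_type` must have one label per neuron")
  if (!all(cell_type %in% c("FS", "RS", "unclassified")))
    stop("`cell_type` labels must be FS, RS or unclassified")
  segment_id <- segment_id %||% rep(1L, nt)
  segment_id <- as.integer(segment_id)
  if (length(segment_id) != nt)
    stop("`segment_id` must have one id per bin")
  if (is.unsorted(segment_id))
    stop("`segment_id` must be non-decreasing along time")
  structure(
    list(counts = counts, bin_width = bin_width, cell_type = cell_type,
         segment_id = segment_id),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "spike_raster: %d neurons x %d bins (%.0f ms bins, %.1f s, %d segments)\n",
    nrow(x$counts), ncol(x$counts), x$bin_width * 1000,
    ncol(x$counts) * x$bin_width, length(unique(x$segment_id))))
  tab <- table(factor(x$cell_type, c("FS", "RS", "unclassified")))
  cat(sprintf("  cell types: %d FS, %d RS, %d unclassified\n",
              tab[["FS"]], tab[["RS"]], tab[["unclassified"]]))
  invisible(x)
}

#' Subset a raster by segment
#'
#' Keeps the bins belonging to the requested segments (used to form
#' train/test splits by alternating segments).
#'
#' @param raster a [spike_raster()].
#' @param segments integer vector of segment ids to keep.
#' @return A `spike_raster` restricted to those segments.
#' @export
raster_subset <- function(raster, segments) {
  stopifnot(inherits(raster, "spike_raster"))
  keep <- raster$segment_id %in% segments
  if (!any(keep)) stop("no bins match the requested segments")
  spike_raster(raster$counts[, keep, drop = FALSE], raster$bin_width,
               raster$cell_type, raster$segment_id[keep])
}

# Split a raster into a list of per-segment count matrices.
segment_counts <- function(raster) {
  ids <- unique(raster$segment_id)
  lapply(ids, function(i)
    raster$counts[, raster$segment_id == i, drop = FALSE])
}
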