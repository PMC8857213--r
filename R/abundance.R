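#' Truncated average sequencing depth (TAD)
#'
#' Mean coverage after symmetric trimming: values are sorted, the lowest
#' and highest `(1 - central_fraction) / 2` quantiles are discarded by
#' count (rounded down), and the remainder is averaged.  TAD80
#' (`central_fraction = 0.8`) is the convention: it removes depth spikes
#' from conserved regions and dips from assembly gaps while staying an
#' unbiased depth estimate for well-covered genomes.
#'
#' @param depths numeric vector of per-position (or per-tile) coverage
#'   values, all `>= 0`.
#' @param central_fraction fraction of central values kept, in (0, 1];
#'   1 gives the plain arithmetic mean.
#' @return a single coverage value.
#' @examples
#' truncated_average_depth(0:9)        # trims 0 and 9 -> mean(1:8) = 4.5
#' truncated_average_depth(0:9, 1.0)   # plain mean = 4.5
#' @export
truncated_average_depth <- function(depths, central_fraction = 0.8) {
  if (length(depths) == 0) stop("empty depth vector", call. = FALSE)
  if (!is.numeric(depths) || any(!is.finite(depths) | depths < 0))
    stop("depths must be finite and >= 0", call. = FALSE)
  if (central_fraction <= 0 || central_fraction > 1)
    stop("`central_fraction` must be in (0, 1]", call. = FALSE)
  n <- length(depths)
  k <- floor(n * (1 - central_fraction) / 2)
  if (2 * k >= n) k <- floor((n - 1) / 2)  # always keep >= 1 value
  s <- sort(depths)
  mean(s[(k + 1):(n - k)])
}

#' TAD of a MAG over all its contigs
#'
#' Per-position depths of every contig are concatenated before trimming,
#' so long contigs weigh proportionally to their length and the trim acts
#' on the genome-wide depth distribution, not per contig.
#'
#' @param contigs character vector of the MAG's contig ids.
#' @param depths named list mapping contig id to its numeric depth vector
#'   (one sample).
#' @inheritParams truncated_average_depth
#' @return a single coverage value.
#' @export
mag_tad <- function(contigs, depths, central_fraction = 0.8) {
  miss <- setdiff(contigs, names(depths))
  if (length(miss))
    stop("no depth profile for contig(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  truncated_average_depth(unlist(depths[contigs], use.names = FALSE),
                          central_fraction)
}

#' Community rpoB sequencing depth of one sample
#'
#' Pools the depth values over the union of all rpoB-tagged regions in the
#' sample's assembly and takes the TAD of the pooled vector.  rpoB is a
#' single-copy gene, so its metagenome-wide depth approximates total
#' genome equivalents and serves as the per-sample abundance normaliser.
#'
#' @param regions data.frame of rpoB regions with columns `contig_id`,
#'   `start`, `end` (1-based inclusive, in the coordinate units of the
#'   depth vectors: positions for per-position profiles, tiles for tiled
#'   profiles).
#' @inheritParams mag_tad
#' @return a single coverage value.
#' @export
rpob_depth <- function(regions, depths, central_fraction = 0.8) {
  if (is.null(regions) || nrow(regions) == 0)
    stop("no rpoB-tagged regions: abundance undefined for this sample",
         call. = FALSE)
  pooled <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    v <- depths[[regions$contig_id[i]]]
    if (is.null(v))
      stop("no depth profile for rpoB contig ", regions$contig_id[i],
           call. = FALSE)
    idx <- max(1L, regions$start[i]):min(length(v), regions$end[i])
    v[idx]
  }), use.names = FALSE)
  truncated_average_depth(pooled, central_fraction)
}

#' Per-sample MAG relative abundance series
#'
#' For every (MAG, sample) pair computes the MAG's TAD, the sample's
#' community rpoB depth, and their quotient -- the MAG's abundance as a
#' fraction of the metagenome.  A MAG with no depth profile in a sample is
#' reported with abundance 0 and `present = FALSE`.
#'
#' @param mag_contigs named list mapping MAG id to its contig id vector.
#' @param depths named list of samples; each element a named list mapping
#'   contig id to a numeric depth vector.
#' @param rpob_regions either one data.frame of rpoB regions applied to
#'   every sample, or a named list (by sample id) of such data.frames
#'   (see [rpob_depth()]).
#' @inheritParams truncated_average_depth
#' @return data.frame with columns `mag_id`, `sample_id`, `tad`,
#'   `rpob_depth`, `relative_abundance`, `present`.
#' @export
abundance_series <- function(mag_contigs, depths, rpob_regions,
                             central_fraction = 0.8) {
  samples <- names(depths)
  if (is.null(samples)) stop("`depths` must be a named list of samples",
                             call. = FALSE)
  rows <- lapply(samples, function(s) {
    reg <- if (is.data.frame(rpob_regions)) rpob_regions
           else rpob_regions[[s]]
    rd <- rpob_depth(reg, depths[[s]], central_fraction)
    do.call(rbind, lapply(names(mag_contigs), function(m) {
      ctg <- mag_contigs[[m]]
      present <- all(ctg %in% names(depths[[s]]))
      tad <- if (present) mag_tad(ctg, depths[[s]], central_fraction) else 0
      data.frame(mag_id = m, sample_id = s, tad = tad, rpob_depth = rd,
                 relative_abundance = if (rd > 0) tad / rd else 0,
                 present = present, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
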