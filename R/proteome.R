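#' Normalised spectral abundance factor (NSAF)
#'
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)`: spectral counts are
#' length-normalised and then scaled to sum to 1 over the proteins of one
#' sample-replicate, so values are comparable across proteins of
#' different sizes and across runs of different depth.
#'
#' @param spectral_count non-negative counts; `NA` (protein not
#'   identified in the run) is treated as 0.
#' @param protein_length protein lengths in amino acids (> 0).
#' @return numeric vector of NSAF values summing to 1.
#' @examples
#' nsaf(c(10, 20, 30), c(100, 200, 300))  # all equal: 1/3 each
#' @export
nsaf <- function(spectral_count, protein_length) {
  if (any(protein_length <= 0)) stop("protein lengths must be > 0",
                                     call. = FALSE)
  spectral_count[is.na(spectral_count)] <- 0
  if (any(spectral_count < 0)) stop("spectral counts must be >= 0",
                                    call. = FALSE)
  saf <- spectral_count / protein_length
  tot <- sum(saf)
  if (tot == 0)
    stop("all spectral counts are zero: NSAF undefined", call. = FALSE)
  saf / tot
}

#' Per-replicate NSAF over a spectral-count table
#'
#' Computes NSAF independently within each (sample, replicate) group --
#' normalisation is per run, not on summed counts.
#'
#' @param counts data.frame with columns `protein_id`, `protein_length`,
#'   `sample_id`, `replicate_id`, `spectral_count` (`NA` = not
#'   identified).
#' @return the input with an `nsaf` column appended.
#' @export
nsaf_table <- function(counts) {
  need <- c("protein_id", "protein_length", "sample_id", "replicate_id",
            "spectral_count")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("count table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(counts$sample_id, counts$replicate_id, drop = TRUE)
  if (anyDuplicated(interaction(counts$protein_id, key, drop = TRUE)))
    stop("duplicate (protein, sample, replicate) rows", call. = FALSE)
  counts$nsaf <- ave(seq_len(nrow(counts)), key, FUN = function(i) {
    nsaf(counts$spectral_count[i], counts$protein_length[i])
  })
  counts
}

#' Average per-replicate values with absent-as-zero
#'
#' Proteins not identified in a replicate contribute 0: the mean is taken
#' over exactly `n_replicates` slots, padding missing or `NA` values with
#' zeros.  With three replicates, `{0.3, absent, 0.3}` averages to 0.2.
#'
#' @param values numeric vector of per-replicate values for one protein
#'   (length <= `n_replicates`; `NA` allowed).
#' @param n_replicates number of biological replicates (default 3).
#' @return the arithmetic mean over `n_replicates` slots.
#' @export
average_replicates <- function(values, n_replicates = 3) {
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (length(values) > n_replicates)
    stop("more values than replicates", call. = FALSE)
  sum(values, na.rm = TRUE) / n_replicates
}

#' Replicate-averaged NSAF per protein and sample
#'
#' Runs [nsaf_table()] and then [average_replicates()] per (protein,
#' sample), treating replicates without an identification as zero.
#'
#' @inheritParams nsaf_table
#' @inheritParams average_replicates
#' @return data.frame with columns `protein_id`, `sample_id`,
#'   `mean_nsaf`.
#' @export
nsaf_sample_means <- function(counts, n_replicates = 3) {
  tab <- nsaf_table(counts)
  agg <- aggregate(nsaf ~ protein_id + sample_id, data = tab,
                   FUN = function(v) sum(v, na.rm = TRUE) / n_replicates,
                   na.action = stats::na.pass)
  names(agg)[names(agg) == "nsaf"] <- "mean_nsaf"
  agg[order(agg$sample_id, agg$protein_id), , drop = FALSE]
}

#' Assign detected proteins to MAG proteins
#'
#' Keeps matches with identity >= `min_identity` percent and alignment
#' coverage >= `min_coverage` percent (both inclusive), then assigns each
#' detected protein to the surviving MAG protein with the highest
#' identity; ties break to the lexicographically smallest `mag_protein`.
#' Raising `min_identity` can only remove assignments, never add them.
#'
#' @param matches data.frame with columns `mag_protein`,
#'   `detected_protein`, `percent_identity`, `alignment_coverage`.
#' @param min_identity percent identity threshold (default 99).
#' @param min_coverage percent alignment-coverage threshold (default 50).
#' @return data.frame with columns `detected_protein`, `mag_protein`,
#'   `percent_identity` (one row per assigned detected protein).
#' @export
map_proteins_to_mag <- function(matches, min_identity = 99,
                                min_coverage = 50) {
  keep <- matches$percent_identity >= min_identity &
    matches$alignment_coverage >= min_coverage
  m <- matches[keep, , drop = FALSE]
  if (nrow(m) == 0)
    return(data.frame(detected_protein = character(0),
                      mag_protein = character(0),
                      percent_identity = numeric(0)))
  m <- m[order(m$detected_protein, -m$percent_identity, m$mag_protein), ,
         drop = FALSE]
  m <- m[!duplicated(m$detected_protein), , drop = FALSE]
  rownames(m) <- NULL
  m[, c("detected_protein", "mag_protein", "percent_identity")]
}
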