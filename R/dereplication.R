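#' Build an undirected ANI graph from directed pairwise records
#'
#' FastANI-style records are directed (query vs reference) and typically
#' asymmetric.  An undirected edge `(a, b)` is created when at least one
#' direction passes both gates: ANI at or above `ani_threshold` (percent)
#' and aligned fraction at or above `af_threshold` (0--1).
#'
#' @param records data.frame with columns `query_bin`, `ref_bin`, `ani`
#'   (percent, 0--100) and `aligned_fraction` (0--1).
#' @param ani_threshold percent; 95 approximates the species boundary,
#'   99 the strain boundary.
#' @param af_threshold minimum aligned fraction (default 0.65).
#' @return data.frame with columns `a`, `b` (each row one undirected edge,
#'   `a < b` lexicographically), possibly zero rows.
#' @examples
#' rec <- data.frame(query_bin = "x", ref_bin = "y",
#'                   ani = 96, aligned_fraction = 0.7)
#' build_ani_graph(rec, 95, 0.65)
#' @export
build_ani_graph <- function(records, ani_threshold = 95, af_threshold = 0.65) {
  if (ani_threshold < 0 || ani_threshold > 100)
    stop("`ani_threshold` must be a percent in [0, 100]", call. = FALSE)
  if (af_threshold < 0 || af_threshold > 1)
    stop("`af_threshold` must be a fraction in [0, 1]", call. = FALSE)
  need <- c("query_bin", "ref_bin", "ani", "aligned_fraction")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("ANI table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(records$ani) | records$ani < 0 | records$ani > 100 |
                 !is.finite(records$aligned_fraction) |
                 records$aligned_fraction < 0 | records$aligned_fraction > 1 |
                 records$query_bin == records$ref_bin)
  if (length(bad))
    stop("malformed ANI record at row ", bad[1],
         " (ani outside [0,100], aligned_fraction outside [0,1], or self-pair)",
         call. = FALSE)
  ok <- records$ani >= ani_threshold & records$aligned_fraction >= af_threshold
  if (!any(ok))
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  a <- pmin(records$query_bin[ok], records$ref_bin[ok])
  b <- pmax(records$query_bin[ok], records$ref_bin[ok])
  e <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  e[order(e$a, e$b), , drop = FALSE]
}

#' Cluster bins as connected components of the ANI graph
#'
#' Single-linkage reading of the thresholded graph: each connected
#' component is one cluster; bins with no passing edge form singletons.
#'
#' @param bins character vector of all bin ids (edges may cover a subset).
#' @param edges edge data.frame from [build_ani_graph()].
#' @return data.frame with columns `bin_id`, `cluster_id`.  Cluster ids are
#'   `"c1"`, `"c2"`, ... assigned in order of each cluster's
#'   lexicographically smallest member, so output is deterministic.
#' @export
cluster_bins <- function(bins, edges) {
  bins <- as.character(bins)
  if (anyDuplicated(bins)) stop("duplicate bin ids", call. = FALSE)
  unknown <- setdiff(unique(c(edges$a, edges$b)), bins)
  if (length(unknown))
    stop("edge endpoint(s) not in bin set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sort(bins), stringsAsFactors = FALSE))
  memb <- igraph::components(g)$membership
  # relabel components by smallest member bin id
  smallest <- tapply(names(memb), memb, min)
  ord <- rank(smallest, ties.method = "first")
  out <- data.frame(bin_id = names(memb),
                    cluster_id = paste0("c", ord[as.character(memb)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$bin_id), ]
  rownames(out) <- NULL
  out
}

#' Select the representative bin of one cluster
#'
#' The representative is the member with the highest [quality_score()].
#' With `prefer_16s = TRUE`, members carrying a 16S rRNA gene take
#' precedence: a higher-scoring bin without 16S is not selected when any
#' member encodes a 16S gene.  Ties break to the lexicographically
#' smallest `bin_id`.
#'
#' @param members character vector of bin ids in the cluster.
#' @param quality data.frame with `bin_id`, `completion`, `contamination`,
#'   `n50` and (if `prefer_16s`) logical `has_16s`.
#' @param prefer_16s prefer 16S-bearing members when any exist.
#' @return a single bin id.
#' @export
select_representative <- function(members, quality, prefer_16s = FALSE) {
  if (length(members) == 0) stop("empty cluster", call. = FALSE)
  q <- quality[match(members, quality$bin_id), , drop = FALSE]
  if (anyNA(q$bin_id))
    stop("no quality record for bin(s): ",
         paste(members[is.na(q$bin_id)], collapse = ", "), call. = FALSE)
  q$score <- quality_score(q$completion, q$contamination, q$n50)
  pool <- q
  if (isTRUE(prefer_16s)) {
    if (is.null(q$has_16s))
      stop("`prefer_16s = TRUE` requires a `has_16s` column", call. = FALSE)
    if (any(q$has_16s)) pool <- q[q$has_16s, , drop = FALSE]
  }
  pool <- pool[order(-pool$score, pool$bin_id), , drop = FALSE]
  pool$bin_id[1]
}

#' Dereplicate a bin set by ANI clustering
#'
#' Composes [build_ani_graph()], [cluster_bins()] and
#' [select_representative()]: bins are clustered at `ani_threshold` /
#' `af_threshold` and one representative is chosen per cluster.
#' Dereplication is idempotent: re-running on the representatives alone
#' yields only singletons.
#'
#' @inheritParams build_ani_graph
#' @inheritParams select_representative
#' @param ani ANI record data.frame (see [build_ani_graph()]).
#' @return data.frame with columns `bin_id`, `cluster_id`,
#'   `is_representative`.
#' @examples
#' q <- data.frame(bin_id = c("a", "b", "c"), completion = c(95, 90, 80),
#'                 contamination = 0, n50 = 1e5)
#' ani <- data.frame(query_bin = "a", ref_bin = "b",
#'                   ani = 97, aligned_fraction = 0.8)
#' dereplicate(q, ani, ani_threshold = 95)
#' @export
dereplicate <- function(quality, ani, ani_threshold = 95,
                        af_threshold = 0.65, prefer_16s = FALSE) {
  edges <- build_ani_graph(ani, ani_threshold, af_threshold)
  cl <- cluster_bins(quality$bin_id, edges)
  reps <- vapply(split(cl$bin_id, cl$cluster_id), select_representative,
                 character(1), quality = quality, prefer_16s = prefer_16s)
  cl$is_representative <- cl$bin_id == reps[cl$cluster_id]
  cl
}
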