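# Independent brute-force oracles and fixture builders used across tests.

# Brute-force single-linkage clustering: boolean adjacency from the
# either-direction edge predicate, transitive closure by repeated
# expansion, partition read off the closure rows.  Independent of igraph.
oracle_partition <- function(bins, records, ani_threshold, af_threshold) {
  n <- length(bins)
  A <- diag(TRUE, n)
  dimnames(A) <- list(bins, bins)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$ani >= ani_threshold && r$aligned_fraction >= af_threshold) {
      A[r$query_bin, r$ref_bin] <- TRUE
      A[r$ref_bin, r$query_bin] <- TRUE
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  unname(lapply(unique(apply(A, 1, paste, collapse = "")), function(key) {
    sort(bins[apply(A, 1, paste, collapse = "") == key])
  }))
}

# partition (list of member sets) from a cluster assignment data.frame
partition_of <- function(assignment) {
  unname(lapply(split(assignment$bin_id, assignment$cluster_id), sort))
}

same_partition <- function(p1, p2) {
  key <- function(p) sort(vapply(p, paste, character(1), collapse = "|"))
  identical(key(p1), key(p2))
}

# random directed ANI instance over <= 12 bins
random_ani_instance <- function(n_bins) {
  bins <- sprintf("b%02d", seq_len(n_bins))
  pairs <- t(combn(bins, 2))
  recs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    # both directions, independently jittered (FastANI output is
    # asymmetric); some pairs only reported one way
    base_ani <- runif(1, 85, 100)
    base_af <- runif(1, 0.4, 1)
    r <- data.frame(query_bin = pairs[i, 1], ref_bin = pairs[i, 2],
                    ani = base_ani, aligned_fraction = base_af)
    if (runif(1) < 0.8)
      r <- rbind(r, data.frame(query_bin = pairs[i, 2],
                               ref_bin = pairs[i, 1],
                               ani = min(100, base_ani + runif(1, -1, 1)),
                               aligned_fraction =
                                 min(1, max(0, base_af + runif(1, -.1, .1)))))
    r
  }))
  list(bins = bins, records = recs)
}

# Exact two-sided rank-sum p-value by enumeration of all group
# assignments (no ties assumed).
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  m <- length(a)
  r_obs <- sum(rank(pooled)[seq_len(m)])
  mid <- m * (length(pooled) + 1) / 2
  combs <- combn(length(pooled), m)
  stats <- apply(combs, 2, function(i) sum(rank(pooled)[i]))
  mean(abs(stats - mid) >= abs(r_obs - mid))
}

# TRUE iff some window of at most `span` consecutive genes holds >= 3
# BMC-H and >= 1 BMC-P tags (brute interval scan over all windows)
oracle_bmc_exists <- function(tags, span) {
  n <- length(tags)
  is_h <- grepl("(^|;)PF00936(;|$)", tags)
  is_p <- grepl("(^|;)PF03319(;|$)", tags)
  for (i in seq_len(n)) for (j in i:min(n, i + span - 1)) {
    if (sum(is_h[i:j]) >= 3 && any(is_p[i:j])) return(TRUE)
  }
  FALSE
}

# bare gene table: one contig, n genes, all tags empty, strand "+"
make_contig <- function(n, contig = "ctgA", bin = "binA") {
  r <- seq_len(n) - 1L
  data.frame(gene_id = sprintf("%s_g%03d", contig, r), bin_id = bin,
             contig_id = contig, rank = r, start = r * 1000L + 1L,
             end = r * 1000L + 900L, strand = "+", tags = "",
             stringsAsFactors = FALSE)
}

set_tag <- function(genes, rank, tag, strand = NULL,
                    contig = genes$contig_id[1]) {
  i <- which(genes$contig_id == contig & genes$rank == rank)
  genes$tags[i] <- tag
  if (!is.null(strand)) genes$strand[i] <- strand
  genes
}

# Toy annotation table realising the community book-keeping of the
# worked example: 44 MAGs in three phyla, 163 fucosidase and 61
# rhamnosidase genes, a 12-MAG dual-high (GH & sulfatase >= 1%) subset
# carrying 89 fucosidases and 26 rhamnosidases, 1000 genes per MAG.
worked_example_genes <- function() {
  v_fuc <- c(11, 10, 9, 9, 8, 8, 7, 7, 6, 5, 4, 2)        # sum 86
  v_rha <- c(3, 2, 2, 3, 2, 2, 2, 2, 2, 2, 2, 6)          # sum 30
  v_dual <- c(rep(TRUE, 11), FALSE)
  b_fuc <- c(rep(5, 8), rep(2, 13), rep(1, 6))            # sum 72
  b_rha <- c(2, rep(3, 7), rep(0, 13), rep(0, 6))         # sum 23
  b_dual <- c(TRUE, rep(FALSE, 26))
  o_fuc <- rep(1, 5)                                      # sum 5
  o_rha <- c(2, 2, 2, 1, 1)                               # sum 8
  o_dual <- rep(FALSE, 5)
  spec <- data.frame(
    bin_id = c(sprintf("V%02d", 1:12), sprintf("B%02d", 1:27),
               sprintf("O%02d", 1:5)),
    phylum = c(rep("Verrucomicrobiota", 12), rep("Bacteroidota", 27),
               rep("Planctomycetota", 5)),
    fuc = c(v_fuc, b_fuc, o_fuc), rha = c(v_rha, b_rha, o_rha),
    dual = c(v_dual, b_dual, o_dual), stringsAsFactors = FALSE)
  total <- 1000L
  genes <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    extra_gh <- if (s$dual) 15L else 2L
    n_sulf <- if (s$dual) 12L else 1L
    tags <- c(rep("GH29", s$fuc), rep("GH78", s$rha),
              rep("GH2", extra_gh), rep("S1_22", n_sulf))
    tags <- c(tags, rep("", total - length(tags)))
    data.frame(gene_id = sprintf("%s_g%04d", s$bin_id, seq_len(total)),
               bin_id = s$bin_id, tags = tags, stringsAsFactors = FALSE)
  }))
  meta <- spec[, c("bin_id", "phylum")]
  list(genes = genes, meta = meta)
}
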