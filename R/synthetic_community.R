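#' Configuration for a synthetic mock community
#'
#' Defines the planted ground truth of a mock community: species-level
#' ANI clusters (optionally with nested strain subclusters), per-sample
#' relative abundances, genome/contig structure and the depth noise
#' model.  Every downstream stage of the pipeline can be exercised
#' against the returned truth with no external data.
#'
#' @param n_clusters number of species-level ANI clusters.
#' @param bins_per_cluster bins per strain group (each cluster holds
#'   `strains_per_cluster * bins_per_cluster` bins).
#' @param within_cluster_ani percent ANI between bins of the same strain
#'   group (e.g. 99.5).
#' @param between_cluster_ani percent ANI between bins of different
#'   clusters (e.g. 80).
#' @param strains_per_cluster strain subclusters nested in each cluster
#'   (1 = no substructure).
#' @param strain_ani percent ANI between strains of the same cluster;
#'   must lie strictly between `between_cluster_ani` and
#'   `within_cluster_ani`.
#' @param aligned_fraction aligned fraction emitted for within-cluster
#'   pairs (0--1).
#' @param genome_length genome size per bin, bp.
#' @param min_contig_length contig length, bp (>= 2500; contigs shorter
#'   than 2.5 kbp are below the assembly cutoff this mimics).
#' @param n_samples number of samples in the time series.
#' @param true_abundances `n_clusters x n_samples` matrix of planted
#'   relative abundances; each column must sum to <= 1 (the remainder is
#'   unbinned community).  Default: even split over clusters totalling
#'   0.9 per sample.
#' @param depth_noise_model `"poisson"` (counts per 100-bp tile around
#'   the expected depth), `"lognormal-multiplier"` (mean-1 multiplicative
#'   noise) or `"none"`.
#' @param lognormal_sdlog sdlog of the lognormal multiplier.
#' @param total_depth expected community-wide sequencing depth (x); a
#'   cluster at fraction f is covered at `f * total_depth`.
#' @param tile_width depth tile width, bp.
#' @param plant_loci plant one PUL and one BMC locus per bin (plus the
#'   methyl-pentose pathway genes) and record them in the truth.
#' @param n_proteins_per_bin proteins emitted per bin for the
#'   metaproteome stage.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   communities.
#' @return a validated list of class `community_config`.
#' @export
community_config <- function(n_clusters = 3, bins_per_cluster = 2,
                             within_cluster_ani = 99.5,
                             between_cluster_ani = 80,
                             strains_per_cluster = 1, strain_ani = 96.5,
                             aligned_fraction = 0.85,
                             genome_length = 3e5,
                             min_contig_length = 25000,
                             n_samples = 4, true_abundances = NULL,
                             depth_noise_model = c("poisson",
                                                   "lognormal-multiplier",
                                                   "none"),
                             lognormal_sdlog = 0.2,
                             total_depth = 500, tile_width = 100,
                             plant_loci = TRUE, n_proteins_per_bin = 20,
                             seed = 1) {
  depth_noise_model <- match.arg(depth_noise_model)
  if (is.null(true_abundances))
    true_abundances <- matrix(0.9 / n_clusters, n_clusters, n_samples)
  true_abundances <- as.matrix(true_abundances)
  if (nrow(true_abundances) != n_clusters ||
      ncol(true_abundances) != n_samples)
    stop("invalid `true_abundances`: need a ", n_clusters, " x ",
         n_samples, " matrix", call. = FALSE)
  if (any(true_abundances < 0) || any(colSums(true_abundances) > 1 + 1e-12))
    stop("invalid `true_abundances`: per-sample fractions must be >= 0 ",
         "and sum to <= 1", call. = FALSE)
  if (within_cluster_ani <= between_cluster_ani)
    stop("invalid `within_cluster_ani`: must exceed `between_cluster_ani`",
         call. = FALSE)
  if (strains_per_cluster > 1 &&
      (strain_ani <= between_cluster_ani || strain_ani >= within_cluster_ani))
    stop("invalid `strain_ani`: must lie strictly between ",
         "`between_cluster_ani` and `within_cluster_ani`", call. = FALSE)
  if (min_contig_length < 2500)
    stop("invalid `min_contig_length`: must be >= 2500 bp", call. = FALSE)
  if (genome_length < 3 * min_contig_length && plant_loci)
    stop("invalid `genome_length`: locus planting needs >= 3 contigs",
         call. = FALSE)
  if (tile_width < 1 || min_contig_length %% tile_width != 0)
    stop("invalid `tile_width`: must divide `min_contig_length`",
         call. = FALSE)
  if (seed != as.integer(seed))
    stop("invalid `seed`: must be an integer", call. = FALSE)
  structure(list(
    n_clusters = n_clusters, bins_per_cluster = bins_per_cluster,
    within_cluster_ani = within_cluster_ani,
    between_cluster_ani = between_cluster_ani,
    strains_per_cluster = strains_per_cluster, strain_ani = strain_ani,
    aligned_fraction = aligned_fraction, genome_length = genome_length,
    min_contig_length = min_contig_length, n_samples = n_samples,
    true_abundances = true_abundances,
    depth_noise_model = depth_noise_model,
    lognormal_sdlog = lognormal_sdlog, total_depth = total_depth,
    tile_width = tile_width, plant_loci = plant_loci,
    n_proteins_per_bin = n_proteins_per_bin, seed = as.integer(seed)),
    class = "community_config")
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic mock community with planted ground truth
#'
#' Builds bins, gene tables, a checkM-style quality table, a directed
#' pairwise ANI table, per-sample tiled depth profiles, a protein set
#' with match evidence, and a `truth` record of everything planted.  ANI
#' values are emitted directly from the planted cluster structure:
#' within-strain pairs above `within_cluster_ani`, between-cluster pairs
#' below `between_cluster_ani`, so any clustering threshold in between
#' recovers the planted partition.  Depth profiles realise
#' `fraction * total_depth` per cluster under the configured noise model;
#' a community-wide rpoB pseudo-contig (the analogue of searching reads
#' against a curated rpoB database) carries the whole-community depth and
#' is the intended abundance normaliser.
#'
#' @param config a [community_config()].
#' @return list of class `synthetic_community` with elements `genes`,
#'   `quality`, `ani`, `depths` (per sample, per contig tile vectors),
#'   `rpob_regions`, `mag_contigs`, `truth`, and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  with_seed(config$seed, generate_community_impl(config))
}

generate_community_impl <- function(cfg) {
  n_bins <- cfg$n_clusters * cfg$strains_per_cluster * cfg$bins_per_cluster
  bins <- sprintf("bin%03d", seq_len(n_bins))
  cluster_of <- setNames(sprintf("sp%d", rep(seq_len(cfg$n_clusters),
    each = cfg$strains_per_cluster * cfg$bins_per_cluster)), bins)
  strain_of <- setNames(sprintf("%s_st%d", cluster_of,
    rep(rep(seq_len(cfg$strains_per_cluster), each = cfg$bins_per_cluster),
        times = cfg$n_clusters)), bins)

  n_contigs <- cfg$genome_length %/% cfg$min_contig_length
  genes_per_contig <- cfg$min_contig_length %/% 1000L
  contig_ids <- lapply(bins, function(b)
    sprintf("%s_c%02d", b, seq_len(n_contigs)))
  names(contig_ids) <- bins

  genes <- do.call(rbind, lapply(bins, function(b) {
    do.call(rbind, lapply(contig_ids[[b]], function(ctg) {
      r <- seq_len(genes_per_contig) - 1L
      data.frame(gene_id = sprintf("%s_g%03d", ctg, r),
                 bin_id = b, contig_id = ctg, rank = r,
                 start = r * 1000L + 51L, end = r * 1000L + 950L,
                 strand = sample(c("+", "-"), genes_per_contig,
                                 replace = TRUE),
                 tags = "", stringsAsFactors = FALSE)
    }))
  }))
  # one designated rpoB marker gene per bin
  first <- !duplicated(genes$bin_id)
  genes$tags[first] <- "rpoB"

  samples <- sprintf("s%02d", seq_len(cfg$n_samples))
  truth <- list(cluster_of = cluster_of, strain_of = strain_of,
                planted_abundance = structure(cfg$true_abundances,
                  dimnames = list(sprintf("sp%d", seq_len(cfg$n_clusters)),
                                  samples)),
                planted_loci = data.frame(bin = character(0),
                                          contig = character(0),
                                          anchor = character(0),
                                          label = character(0)),
                samples = samples, seed = cfg$seed)

  if (cfg$plant_loci) {
    enabled <- Filter(function(r) !isTRUE(r$disabled), pul_rules())
    types <- vapply(enabled, `[[`, character(1), "type")
    for (i in seq_along(bins)) {
      b <- bins[i]
      ty <- types[(i - 1L) %% length(types) + 1L]
      genes <- plant_pul(genes, b, ty, contig = contig_ids[[b]][2])
      truth$planted_loci <- rbind(truth$planted_loci,
                                  attr(genes, "planted"))
      genes <- plant_bmc(genes, b, contig = contig_ids[[b]][3])
      truth$planted_loci <- rbind(truth$planted_loci,
                                  attr(genes, "planted"))
      attr(genes, "planted") <- NULL
    }
  }

  quality <- data.frame(
    bin_id = bins,
    completion = round(runif(n_bins, 85, 99.5), 1),
    contamination = round(runif(n_bins, 0, 2.5), 2),
    n50 = cfg$min_contig_length,
    has_16s = runif(n_bins) < 0.5,
    n_trna = sample(20:45, n_bins, replace = TRUE),
    stringsAsFactors = FALSE)

  ani <- synth_ani_table(bins, cluster_of, strain_of, cfg)
  depths <- synth_depths(bins, contig_ids, cluster_of, cfg, samples)
  rpob_tiles <- 1000L %/% cfg$tile_width
  rpob_regions <- data.frame(contig_id = "rpoB_community", start = 1L,
                             end = rpob_tiles, stringsAsFactors = FALSE)

  proteins <- data.frame(
    protein_id = sprintf("%s_p%02d", rep(bins, each = cfg$n_proteins_per_bin),
                         seq_len(cfg$n_proteins_per_bin)),
    bin_id = rep(bins, each = cfg$n_proteins_per_bin),
    protein_length = sample(100:1000, n_bins * cfg$n_proteins_per_bin,
                            replace = TRUE),
    weight = runif(n_bins * cfg$n_proteins_per_bin, 0.2, 1),
    stringsAsFactors = FALSE)
  truth$planted_protein_origin <- setNames(proteins$bin_id,
                                           proteins$protein_id)
  truth$proteins <- proteins
  matches <- synth_protein_matches(proteins)

  structure(list(genes = genes, quality = quality, ani = ani,
                 depths = depths, rpob_regions = rpob_regions,
                 mag_contigs = contig_ids, matches = matches,
                 truth = truth, config = cfg),
            class = "synthetic_community")
}

# directed pairwise ANI records realising the planted cluster structure
synth_ani_table <- function(bins, cluster_of, strain_of, cfg) {
  pairs <- expand.grid(query_bin = bins, ref_bin = bins,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$query_bin != pairs$ref_bin, , drop = FALSE]
  n <- nrow(pairs)
  same_cluster <- cluster_of[pairs$query_bin] == cluster_of[pairs$ref_bin]
  same_strain <- strain_of[pairs$query_bin] == strain_of[pairs$ref_bin]
  ani <- numeric(n)
  af <- numeric(n)
  ani[same_strain] <- pmin(100, cfg$within_cluster_ani +
                             runif(sum(same_strain), 0, 0.3))
  ani[same_cluster & !same_strain] <- cfg$strain_ani +
    runif(sum(same_cluster & !same_strain), -0.3, 0)
  ani[!same_cluster] <- pmax(0, cfg$between_cluster_ani -
                               runif(sum(!same_cluster), 0, 3))
  af[same_cluster] <- pmin(1, cfg$aligned_fraction +
                             runif(sum(same_cluster), -0.05, 0.05))
  af[!same_cluster] <- runif(sum(!same_cluster), 0.1, 0.4)
  pairs$ani <- round(ani, 3)
  pairs$aligned_fraction <- round(af, 4)
  rownames(pairs) <- NULL
  pairs
}

# per-sample, per-contig tiled depth vectors under the configured noise
synth_depths <- function(bins, contig_ids, cluster_of, cfg, samples) {
  tiles_per_contig <- cfg$min_contig_length %/% cfg$tile_width
  rpob_tiles <- 1000L %/% cfg$tile_width
  noise <- function(lambda, n) {
    switch(cfg$depth_noise_model,
           none = rep(lambda, n),
           poisson = as.numeric(rpois(n, lambda)),
           `lognormal-multiplier` = lambda *
             rlnorm(n, -cfg$lognormal_sdlog^2 / 2, cfg$lognormal_sdlog))
  }
  out <- lapply(seq_along(samples), function(si) {
    per_contig <- list()
    for (b in bins) {
      lam <- cfg$true_abundances[match(cluster_of[b],
        sprintf("sp%d", seq_len(cfg$n_clusters))), si] * cfg$total_depth
      for (ctg in contig_ids[[b]])
        per_contig[[ctg]] <- noise(lam, tiles_per_contig)
    }
    per_contig[["rpoB_community"]] <- noise(cfg$total_depth, rpob_tiles)
    per_contig
  })
  names(out) <- samples
  out
}

# match evidence linking each protein to its origin bin (identity >= 99)
# plus lower-identity cross-bin decoys
synth_protein_matches <- function(proteins) {
  n <- nrow(proteins)
  true_m <- data.frame(
    mag_protein = proteins$protein_id,
    detected_protein = paste0("det_", proteins$protein_id),
    percent_identity = round(runif(n, 99, 100), 2),
    alignment_coverage = round(runif(n, 60, 100), 1),
    stringsAsFactors = FALSE)
  decoy_target <- sample(proteins$protein_id)
  keep <- decoy_target != proteins$protein_id
  decoys <- data.frame(
    mag_protein = decoy_target[keep],
    detected_protein = paste0("det_", proteins$protein_id)[keep],
    percent_identity = round(runif(sum(keep), 60, 98.5), 2),
    alignment_coverage = round(runif(sum(keep), 40, 100), 1),
    stringsAsFactors = FALSE)
  rbind(true_m, decoys)
}

#' Plant a PUL-type gene neighbourhood into a gene table
#'
#' Inserts, around a central anchor gene of the chosen contig, exactly
#' the features the rule table requires for `pul_type` (anchor GH29, the
#' inward-pointing partner where required, every `all_of` tag, one tag
#' per `any_of` group), clearing other tags in the 21-gene window so no
#' higher-precedence rule fires.  The planted window therefore satisfies
#' its own classification rule by construction.
#'
#' @param genes gene table (as produced by [generate_community()]).
#' @param bin bin id owning the target contig.
#' @param pul_type label of an enabled rule in `rules`.
#' @param rules rule table, default [pul_rules()].
#' @param contig target contig id; default: first contig of the bin with
#'   at least 21 genes.
#' @return the modified gene table, with attribute `"planted"` holding a
#'   one-row record (bin, contig, anchor, label).
#' @export
plant_pul <- function(genes, bin, pul_type, rules = pul_rules(),
                      contig = NULL) {
  types <- vapply(rules, `[[`, character(1), "type")
  if (!pul_type %in% types)
    stop("unknown pul_type `", pul_type, "`", call. = FALSE)
  rule <- rules[[match(pul_type, types)]]
  if (isTRUE(rule$disabled))
    stop("pul_type `", pul_type, "` is a disabled rule slot: it has no ",
         "feature signature to plant", call. = FALSE)
  if (is.null(contig)) {
    cand <- unique(genes$contig_id[genes$bin_id == bin])
    sizes <- vapply(cand, function(ct) sum(genes$contig_id == ct),
                    integer(1))
    contig <- cand[sizes >= 21][1]
    if (is.na(contig))
      stop("bin `", bin, "` has no contig with >= 21 genes", call. = FALSE)
  }
  idx <- which(genes$contig_id == contig)
  idx <- idx[order(genes$rank[idx])]
  if (length(idx) < 21)
    stop("contig `", contig, "` holds fewer than 21 gene slots",
         call. = FALSE)
  centre <- idx[ceiling(length(idx) / 2)]
  r0 <- genes$rank[centre]
  win <- idx[abs(genes$rank[idx] - r0) <= 10]
  genes$tags[win] <- ""  # clean slate so only planted features decide

  genes$tags[centre] <- "GH29"
  genes$strand[centre] <- "+"
  slots <- setdiff(win, centre)
  if (isTRUE(rule$inward_pair)) {
    partner <- idx[match(r0 + 1L, genes$rank[idx])]
    genes$tags[partner] <- "GH29"
    genes$strand[partner] <- "-"
    slots <- setdiff(slots, partner)
  }
  feats <- c(unlist(rule$all_of),
             vapply(rule$any_of %||% list(), function(g) unlist(g)[1],
                    character(1)))
  feats <- setdiff(unique(feats), "GH29")
  # fill slots nearest the anchor first: real PULs co-locate their
  # sulfatases and accessory GHs around the anchor fucosidase
  slots <- slots[order(abs(genes$rank[slots] - r0))]
  if (length(feats) > length(slots))
    stop("window too small for rule features", call. = FALSE)
  genes$tags[slots[seq_along(feats)]] <- feats
  attr(genes, "planted") <- data.frame(
    bin = bin, contig = contig, anchor = genes$gene_id[centre],
    label = pul_type, stringsAsFactors = FALSE)
  genes
}

#' Plant a PV-BMC shell locus into a gene table
#'
#' Inserts three BMC-H (PF00936) shell genes, one BMC-P (PF03319) gene,
#' the core enzymes (aldolase, aldehyde/alcohol dehydrogenases,
#' phosphotransacylase, kinase) and the methyl-pentose transport and
#' activation genes (fucP, fucI, fucU, rhaT, rhamA, rhaM, rhaB) into a
#' compact span of the chosen contig.
#'
#' @inheritParams plant_pul
#' @return the modified gene table, with attribute `"planted"` as in
#'   [plant_pul()].
#' @export
plant_bmc <- function(genes, bin, contig = NULL) {
  if (is.null(contig)) {
    cand <- unique(genes$contig_id[genes$bin_id == bin])
    sizes <- vapply(cand, function(ct) sum(genes$contig_id == ct),
                    integer(1))
    contig <- cand[sizes >= 16][1]
    if (is.na(contig))
      stop("bin `", bin, "` has no contig with >= 16 genes", call. = FALSE)
  }
  idx <- which(genes$contig_id == contig)
  idx <- idx[order(genes$rank[idx])]
  if (length(idx) < 16)
    stop("contig `", contig, "` holds fewer than 16 gene slots",
         call. = FALSE)
  feats <- c("PF00936", "PF00936", "PF00936", "PF03319", "aldolase",
             "aldehyde_dehydrogenase", "alcohol_dehydrogenase",
             "phosphotransacylase", "kinase",
             "fucP", "fucI", "fucU", "rhaT", "rhamA", "rhaM", "rhaB")
  span <- idx[seq_along(feats)]
  genes$tags[span] <- feats
  attr(genes, "planted") <- data.frame(
    bin = bin, contig = contig, anchor = genes$gene_id[span[1]],
    label = "BMC", stringsAsFactors = FALSE)
  genes
}

#' Simulate a replicated spectral-count table from planted truth
#'
#' For every planted protein and sample, draws `n_replicates` Poisson
#' spectral counts whose expectation scales with the protein's weight and
#' the planted abundance of its bin's cluster; a fraction `dropout_rate`
#' of the (protein, sample, replicate) slots is replaced by `NA`
#' (protein not identified in that run -- treated as zero downstream).
#'
#' @param truth the `truth` element of a [generate_community()] result.
#' @param n_replicates biological replicates per sample (>= 1).
#' @param dropout_rate fraction of protein-replicate slots dropped, in
#'   \[0, 1).
#' @param mean_count Poisson mean scale for a weight-1 protein in a
#'   cluster at fraction 1.
#' @param seed RNG seed (default: derived from the community seed).
#' @return data.frame with columns `protein_id`, `protein_length`,
#'   `sample_id`, `replicate_id`, `spectral_count` (`NA` = dropout).
#' @export
generate_spectra <- function(truth, n_replicates = 3, dropout_rate = 0.1,
                             mean_count = 200, seed = truth$seed + 1L) {
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  pr <- truth$proteins
  with_seed(seed, {
    grid <- expand.grid(protein_id = pr$protein_id,
                        sample_id = truth$samples,
                        replicate_id = sprintf("r%d",
                                               seq_len(n_replicates)),
                        stringsAsFactors = FALSE)
    i <- match(grid$protein_id, pr$protein_id)
    grid$protein_length <- pr$protein_length[i]
    frac <- truth$planted_abundance[
      cbind(truth$cluster_of[pr$bin_id[i]], grid$sample_id)]
    lambda <- mean_count * pr$weight[i] * pmax(frac, 0)
    grid$spectral_count <- rpois(nrow(grid), lambda)
    if (dropout_rate > 0) {
      drop <- runif(nrow(grid)) < dropout_rate
      grid$spectral_count[drop] <- NA_integer_
    }
    grid[, c("protein_id", "protein_length", "sample_id", "replicate_id",
             "spectral_count")]
  })
}
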