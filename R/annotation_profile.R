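#' CAZy family sets for fucosidase and rhamnosidase activity
#'
#' GH29, GH95, GH141, GH151 and GH139 impart alpha-L-fucosidase activity;
#' GH78, GH90 and GH106 alpha-L-rhamnosidase activity.
#'
#' @format character vectors of CAZy GH family labels.
#' @export
fucosidase_families <- c("GH29", "GH95", "GH141", "GH151", "GH139")

#' @rdname fucosidase_families
#' @export
rhamnosidase_families <- c("GH78", "GH90", "GH106")

#' Accept a similarity-search annotation
#'
#' BLASTp-style matches against MEROPS (peptidases) or TCDB (transporters)
#' are accepted when identity exceeds 40 percent and query coverage
#' exceeds 50 percent -- both strict inequalities.
#'
#' @param percent_identity percent identity of the match (0--100).
#' @param query_coverage percent of the query aligned (0--100).
#' @param min_identity,min_coverage acceptance thresholds (strict).
#' @return logical vector.
#' @examples
#' accept_similarity(41, 51)  # TRUE
#' accept_similarity(40, 80)  # FALSE (boundary is strict)
#' @export
accept_similarity <- function(percent_identity, query_coverage,
                              min_identity = 40, min_coverage = 50) {
  if (any(!is.finite(percent_identity)) || any(!is.finite(query_coverage)))
    stop("identity and coverage must be finite", call. = FALSE)
  percent_identity > min_identity & query_coverage > min_coverage
}

#' Accept a CAZyme annotation on dual evidence
#'
#' A CAZy assignment is accepted only when BLASTp and HMMER agree: the
#' similarity match passes [accept_similarity()], the HMM hit has
#' E-value below `max_evalue`, and both name the same CAZy family.
#'
#' @param sim_identity,sim_coverage BLASTp identity / query coverage
#'   (percent).
#' @param hmm_evalue HMMER E-value.
#' @param sim_family,hmm_family CAZy family labels named by each tool.
#' @param max_evalue HMM acceptance threshold (strict `<`).
#' @inheritParams accept_similarity
#' @return logical vector.
#' @examples
#' accept_cazy(45, 60, 1e-20, "GH29", "GH29")  # TRUE
#' accept_cazy(45, 60, 1e-10, "GH29", "GH29")  # FALSE (E-value)
#' accept_cazy(45, 60, 1e-20, "GH29", "GH95")  # FALSE (family mismatch)
#' @export
accept_cazy <- function(sim_identity, sim_coverage, hmm_evalue,
                        sim_family, hmm_family,
                        min_identity = 40, min_coverage = 50,
                        max_evalue = 1e-15) {
  if (any(hmm_evalue < 0)) stop("E-values must be >= 0", call. = FALSE)
  accept_similarity(sim_identity, sim_coverage, min_identity, min_coverage) &
    hmm_evalue < max_evalue &
    sim_family == hmm_family
}

#' Count genes carrying an accepted family tag
#'
#' @param genes gene table with a `tags` column (";"-separated labels).
#' @param families character vector of family labels (e.g.
#'   [fucosidase_families]).
#' @return number of genes with at least one tag in `families` (a gene
#'   tagged with two families of the set still counts once here; use the
#'   per-family breakdown of [mag_profiles()] for family-wise counts).
#' @export
count_family_genes <- function(genes, families) {
  if (length(families) == 0) return(0L)
  sum(vapply(strsplit(ifelse(is.na(genes$tags), "", genes$tags), ";",
                      fixed = TRUE),
             function(tt) any(tt %in% families), logical(1)))
}

#' Content fraction of a gene category
#'
#' @param n_category genes in the category.
#' @param total_genes total predicted genes (> 0).
#' @return percent, `100 * n / total`.
#' @export
content_fraction <- function(n_category, total_genes) {
  if (any(total_genes <= 0))
    stop("`total_genes` must be > 0", call. = FALSE)
  100 * n_category / total_genes
}

#' Flag MAGs with both high GH and high sulfatase content
#'
#' Degradation specialists devote an unusually large share of their
#' proteome to glycoside hydrolases and sulfatases; a MAG is flagged when
#' both contents reach `threshold` percent of total predicted genes
#' (inclusive boundary: 1.0 percent counts as high).
#'
#' @param gh_pct,sulfatase_pct content percents from [mag_profiles()].
#' @param threshold percent (default 1).
#' @return logical vector.
#' @export
flag_high_gh_sulfatase <- function(gh_pct, sulfatase_pct, threshold = 1.0) {
  gh_pct >= threshold & sulfatase_pct >= threshold
}

#' Per-MAG enzyme content profiles
#'
#' Counts glycoside hydrolases, sulfatases (S1 subfamilies), peptidases,
#' fucosidases and rhamnosidases per MAG from accepted gene tags and
#' expresses each as a percent of total predicted genes.
#'
#' GH tags are labels matching `GH<n>` (subfamily suffixes like GH43_12
#' included); sulfatases are `S1_<n>` tags; peptidases are tags prefixed
#' `MEROPS:`.
#'
#' @param genes gene table with columns `bin_id` and `tags`
#'   (";"-separated accepted labels).
#' @param mag_meta optional data.frame with `bin_id` and `phylum` (and any
#'   other metadata columns to carry through); `total_genes` is taken from
#'   the gene table.
#' @param high_threshold percent threshold for
#'   [flag_high_gh_sulfatase()].
#' @return data.frame, one row per MAG: counts, content percents and a
#'   `dual_high` flag.
#' @export
mag_profiles <- function(genes, mag_meta = NULL, high_threshold = 1.0) {
  split_genes <- split(genes, genes$bin_id)
  prof <- do.call(rbind, lapply(names(split_genes), function(m) {
    g <- split_genes[[m]]
    tags <- strsplit(ifelse(is.na(g$tags), "", g$tags), ";", fixed = TRUE)
    n_gh <- sum(vapply(tags, function(tt)
      any(grepl("^GH[0-9]+(_[0-9]+)?$", tt)), logical(1)))
    n_sulf <- sum(vapply(tags, function(tt)
      any(grepl("^S1_[0-9]+$", tt)), logical(1)))
    n_pep <- sum(vapply(tags, function(tt)
      any(startsWith(tt, "MEROPS:")), logical(1)))
    n_fuc <- count_family_genes(g, fucosidase_families)
    n_rha <- count_family_genes(g, rhamnosidase_families)
    data.frame(mag_id = m, total_genes = nrow(g),
               n_gh = n_gh, n_sulfatase = n_sulf, n_peptidase = n_pep,
               n_fucosidase = n_fuc, n_rhamnosidase = n_rha,
               stringsAsFactors = FALSE)
  }))
  prof$gh_pct <- content_fraction(prof$n_gh, prof$total_genes)
  prof$sulfatase_pct <- content_fraction(prof$n_sulfatase, prof$total_genes)
  prof$peptidase_pct <- content_fraction(prof$n_peptidase, prof$total_genes)
  prof$fucosidase_pct <- content_fraction(prof$n_fucosidase, prof$total_genes)
  prof$dual_high <- flag_high_gh_sulfatase(prof$gh_pct, prof$sulfatase_pct,
                                           high_threshold)
  if (!is.null(mag_meta))
    prof <- merge(prof, mag_meta, by.x = "mag_id", by.y = "bin_id",
                  all.x = TRUE, sort = FALSE)
  prof <- prof[order(prof$mag_id), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}

#' Group-level summary of fucosidase/rhamnosidase gene content
#'
#' Summarises MAG profiles by a grouping column (phylum by default):
#' family-gene totals, each group's share of the community total (percent,
#' also rounded to the nearest integer for reporting), MAG counts, mean
#' genes per MAG (reported at 1 decimal) and mean content percent
#' (2 decimals).  Full precision is retained in the `*_share_pct`,
#' `mean_*` columns; `report_*` columns carry the rounded views.
#'
#' @param profiles output of [mag_profiles()] (needs the grouping column).
#' @param group name of the grouping column (e.g. `"phylum"`,
#'   `"dual_high"`).
#' @return data.frame, one row per group.
#' @export
phylum_summary <- function(profiles, group = "phylum") {
  if (!group %in% names(profiles))
    stop("no grouping column `", group, "` in profiles", call. = FALSE)
  tot_fuc <- sum(profiles$n_fucosidase)
  tot_rha <- sum(profiles$n_rhamnosidase)
  out <- do.call(rbind, lapply(split(profiles, profiles[[group]]),
                               function(p) {
    data.frame(
      group = as.character(p[[group]][1]),
      n_mags = nrow(p),
      fucosidase_genes = sum(p$n_fucosidase),
      rhamnosidase_genes = sum(p$n_rhamnosidase),
      fucosidase_share_pct =
        if (tot_fuc > 0) 100 * sum(p$n_fucosidase) / tot_fuc else 0,
      rhamnosidase_share_pct =
        if (tot_rha > 0) 100 * sum(p$n_rhamnosidase) / tot_rha else 0,
      mean_fucosidases_per_mag = mean(p$n_fucosidase),
      mean_rhamnosidases_per_mag = mean(p$n_rhamnosidase),
      mean_fucosidase_content_pct = mean(p$fucosidase_pct),
      stringsAsFactors = FALSE)
  }))
  names(out)[1] <- group
  out$report_fucosidase_share <- round(out$fucosidase_share_pct)
  out$report_rhamnosidase_share <- round(out$rhamnosidase_share_pct)
  out$report_mean_fucosidases <- round(out$mean_fucosidases_per_mag, 1)
  out$report_mean_content <- round(out$mean_fucosidase_content_pct, 2)
  rownames(out) <- NULL
  out
}

#' Compare enzyme content between two MAG groups
#'
#' Two-sided Wilcoxon rank-sum test on content percents (e.g. fucosidase
#' content of Verrucomicrobiota vs Bacteroidota MAGs).  The exact null
#' distribution is enumerated for combined n <= 20 without ties; the
#' normal approximation with tie correction is used otherwise.
#'
#' @param group_a,group_b numeric vectors of content percents, each of
#'   length >= 3.
#' @return the p-value (degenerate all-equal input gives 1 with a
#'   warning).
#' @export
compare_content <- function(group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("both groups need >= 3 values", call. = FALSE)
  if (length(unique(c(group_a, group_b))) == 1L) {
    warning("all values identical; p = 1")
    return(1)
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b) <= 20) && !ties
  p <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
                exact = exact, correct = !exact)$p.value)
  min(p, 1)
}
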