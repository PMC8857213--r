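#' Read a tab-separated table, skipping `#` header comments
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# write a TSV atomically (tmp + rename) with optional "# ..." header lines
write_tsv <- function(df, path, header = character(0)) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read tiled depth profiles from a long TSV
#'
#' Expects columns `sample_id`, `contig_id`, `tile` (1-based index) and
#' `depth`; returns the nested list structure used by
#' [abundance_series()].
#'
#' @param path file path.
#' @return named list (sample) of named lists (contig) of depth vectors.
#' @export
read_depth_tsv <- function(path) {
  d <- read_tsv(path)
  lapply(split(d, d$sample_id), function(ds)
    lapply(split(ds, ds$contig_id), function(dc)
      dc$depth[order(dc$tile)]))
}

# flatten the nested depth list to the long format of read_depth_tsv()
depths_to_long <- function(depths) {
  do.call(rbind, lapply(names(depths), function(s)
    do.call(rbind, lapply(names(depths[[s]]), function(ctg)
      data.frame(sample_id = s, contig_id = ctg,
                 tile = seq_along(depths[[s]][[ctg]]),
                 depth = depths[[s]][[ctg]], stringsAsFactors = FALSE)))))
}

#' Write a synthetic community to disk
#'
#' Emits the TSV tables consumed by [run_pipeline()] (quality, ANI,
#' genes, depths, rpoB regions, protein matches), the planted truth as
#' JSON, placeholder contig FASTA and GFF3 gene calls (via Biostrings /
#' rtracklayer when available), and the generating seed in every header.
#'
#' @param community a [generate_community()] result.
#' @param dir output directory (created if missing).
#' @param spectra optional [generate_spectra()] table to include.
#' @param fasta_gff also write contig FASTA and GFF3 gene calls.
#' @return invisibly, the named vector of written paths.
#' @export
write_community <- function(community, dir, spectra = NULL,
                            fasta_gff = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("fucopul ", utils::packageVersion("fucopul"),
                " synthetic community | seed: ", community$config$seed)
  p <- c(quality = file.path(dir, "quality.tsv"),
         ani = file.path(dir, "ani.tsv"),
         genes = file.path(dir, "genes.tsv"),
         depths = file.path(dir, "depths.tsv"),
         rpob = file.path(dir, "rpob_regions.tsv"),
         matches = file.path(dir, "matches.tsv"),
         truth = file.path(dir, "truth.json"))
  write_tsv(community$quality, p["quality"], hdr)
  write_tsv(community$ani, p["ani"], hdr)
  write_tsv(community$genes, p["genes"], hdr)
  write_tsv(depths_to_long(community$depths), p["depths"], hdr)
  write_tsv(community$rpob_regions, p["rpob"], hdr)
  write_tsv(community$matches, p["matches"], hdr)
  tr <- community$truth
  jsonlite::write_json(list(
    cluster_of = as.list(tr$cluster_of),
    strain_of = as.list(tr$strain_of),
    planted_abundance = tr$planted_abundance,
    planted_loci = tr$planted_loci,
    samples = tr$samples, seed = tr$seed),
    p["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(spectra)) {
    p["spectra"] <- file.path(dir, "spectra.tsv")
    write_tsv(spectra, p["spectra"], hdr)
  }
  if (fasta_gff) p <- c(p, write_community_seq(community, dir))
  invisible(p)
}

# placeholder FASTA (N-filled contigs) + GFF3 gene calls
write_community_seq <- function(community, dir) {
  cfg <- community$config
  contigs <- unlist(community$mag_contigs, use.names = FALSE)
  fa <- file.path(dir, "contigs.fasta")
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::DNAStringSet(
      setNames(rep(strrep("N", cfg$min_contig_length), length(contigs)),
               contigs))
    Biostrings::writeXStringSet(seqs, fa)
  } else {
    con <- file(fa, "w")
    for (ctg in contigs)
      writeLines(c(paste0(">", ctg), strrep("N", cfg$min_contig_length)),
                 con)
    close(con)
  }
  gff <- file.path(dir, "genes.gff3")
  g <- community$genes
  if (requireNamespace("rtracklayer", quietly = TRUE) &&
      requireNamespace("GenomicRanges", quietly = TRUE) &&
      requireNamespace("IRanges", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = g$contig_id,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand, type = "gene", ID = g$gene_id, tags = g$tags)
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    con <- file(gff, "w")
    writeLines("##gff-version 3", con)
    attrs <- paste0("ID=", g$gene_id,
                    ifelse(nzchar(g$tags), paste0(";tags=", g$tags), ""))
    writeLines(paste(g$contig_id, "fucopul", "gene", g$start, g$end, ".",
                     g$strand, ".", attrs, sep = "\t"), con)
    close(con)
  }
  c(fasta = fa, gff3 = gff)
}

#' Read gene calls from GFF3
#'
#' Imports a GFF3 file of gene features (with `ID` and optional `tags`
#' attributes as written by [write_community()]) into the gene-table
#' layout used across the package, reconstructing per-contig ranks from
#' start order.
#'
#' @param path GFF3 file path.
#' @return gene data.frame (`gene_id`, `contig_id`, `rank`, `start`,
#'   `end`, `strand`, `tags`).
#' @export
read_gff_genes <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    g <- data.frame(gene_id = gr$ID,
                    contig_id = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    tags = if (is.null(gr$tags)) "" else
                      ifelse(is.na(gr$tags), "", gr$tags),
                    stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    get_attr <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))
      vapply(m, function(x) if (length(x)) x[3] else "", character(1))
    }
    attrs <- vapply(f, `[`, character(1), 9)
    g <- data.frame(gene_id = get_attr(attrs, "ID"),
                    contig_id = vapply(f, `[`, character(1), 1),
                    start = as.integer(vapply(f, `[`, character(1), 4)),
                    end = as.integer(vapply(f, `[`, character(1), 5)),
                    strand = vapply(f, `[`, character(1), 7),
                    tags = get_attr(attrs, "tags"),
                    stringsAsFactors = FALSE)
  }
  g <- g[order(g$contig_id, g$start), , drop = FALSE]
  g$rank <- unlist(lapply(split(seq_len(nrow(g)), g$contig_id),
                          seq_along), use.names = FALSE) - 1L
  # restore row order by contig then rank
  g <- g[order(g$contig_id, g$rank),
         c("gene_id", "contig_id", "rank", "start", "end", "strand",
           "tags")]
  rownames(g) <- NULL
  g
}
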