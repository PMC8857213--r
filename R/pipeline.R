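#' Build a pipeline configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()].  A
#' YAML config file with the same field names may be used instead; flags
#' given here override file values.
#'
#' @param quality,ani,genes,depths,rpob_regions,spectra,matches paths to
#'   the input TSV tables ([write_community()] emits all of them;
#'   `spectra`/`matches` may be `NULL` to skip the proteome stage).
#' @param out_dir output directory.
#' @param ani_threshold,af_threshold,prefer_16s dereplication parameters
#'   (see [dereplicate()]).
#' @param central_fraction TAD trim parameter (see
#'   [truncated_average_depth()]).
#' @param rules_path optional PUL rule YAML (default: the packaged
#'   table).
#' @param min_identity,min_coverage protein-to-MAG mapping thresholds
#'   (see [map_proteins_to_mag()]).
#' @param n_replicates replicates per proteome sample.
#' @param seed integer recorded in output headers (the pipeline itself
#'   is deterministic; the seed documents the provenance of generated
#'   inputs).
#' @param config_file optional YAML file whose fields fill any argument
#'   not supplied.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(quality = NULL, ani = NULL, genes = NULL,
                            depths = NULL, rpob_regions = NULL,
                            spectra = NULL, matches = NULL,
                            out_dir = ".", ani_threshold = 95,
                            af_threshold = 0.65, prefer_16s = FALSE,
                            central_fraction = 0.8, rules_path = NULL,
                            min_identity = 99, min_coverage = 50,
                            n_replicates = 3, seed = 1,
                            config_file = NULL) {
  cfg <- list(quality = quality, ani = ani, genes = genes,
              depths = depths, rpob_regions = rpob_regions,
              spectra = spectra, matches = matches, out_dir = out_dir,
              ani_threshold = ani_threshold, af_threshold = af_threshold,
              prefer_16s = prefer_16s,
              central_fraction = central_fraction,
              rules_path = rules_path, min_identity = min_identity,
              min_coverage = min_coverage, n_replicates = n_replicates,
              seed = seed)
  if (!is.null(config_file)) {
    fromfile <- yaml::read_yaml(config_file)
    given <- names(as.list(match.call())[-1])
    for (f in setdiff(names(fromfile), given)) cfg[[f]] <- fromfile[[f]]
  }
  for (f in c("quality", "ani", "genes", "depths", "rpob_regions")) {
    if (is.null(cfg[[f]]))
      stop("pipeline config lacks required input `", f, "`",
           call. = FALSE)
    if (!file.exists(cfg[[f]]))
      stop("input `", f, "` does not exist: ", cfg[[f]], call. = FALSE)
  }
  if (cfg$ani_threshold < 0 || cfg$ani_threshold > 100 ||
      cfg$af_threshold < 0 || cfg$af_threshold > 1 ||
      cfg$central_fraction <= 0 || cfg$central_fraction > 1)
    stop("pipeline config threshold out of range", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full genome-resolved pipeline
#'
#' Orchestrates QC, dereplication, abundance, content profiling, locus
#' detection and (when spectra/matches are configured) the metaproteome
#' stage, writing one TSV per stage into `out_dir`.  Every output header
#' records the package version, a config hash and the seed, and all
#' files are written atomically at the end of the run, so an aborted run
#' leaves no partial outputs.  A run in which no bin passes QC
#' terminates cleanly with a classed condition
#' (`fucopul_empty_result`).
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param stages subset of
#'   `c("qc", "derep", "abundance", "profile", "loci", "proteome")`;
#'   prerequisite stages are added automatically.
#' @return invisibly, a named list with the result tables and the
#'   written paths.
#' @export
run_pipeline <- function(config,
                         stages = c("qc", "derep", "abundance",
                                    "profile", "loci", "proteome")) {
  if (is.character(config)) config <- pipeline_config(config_file = config)
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("qc", "derep", "abundance", "profile", "loci",
                  "proteome")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # prerequisite closure: derep needs qc, abundance needs derep
  if ("abundance" %in% stages) stages <- c(stages, "derep")
  if ("derep" %in% stages) stages <- c(stages, "qc")
  stages <- intersect(all_stages, unique(stages))

  hdr <- paste0("fucopul ", utils::packageVersion("fucopul"),
                " | config_md5: ", config_hash(config),
                " | seed: ", config$seed)
  res <- list()
  out <- list()  # path -> data.frame, written at the end

  stage <- function(name, expr) {
    tryCatch(expr, fucopul_empty_result = function(e) stop(e),
             error = function(e)
               stop("stage ", name, " failed: ", conditionMessage(e),
                    call. = FALSE))
  }

  genes <- stage("input", read_tsv(config$genes))

  if ("qc" %in% stages) {
    q <- stage("qc", qc_table(read_tsv(config$quality)))
    message("[qc] bins in: ", nrow(q), ", passing: ", sum(q$pass))
    if (!any(q$pass))
      stop_fucopul("no bins pass QC", "fucopul_empty_result")
    res$qc <- q
    out[["qc.tsv"]] <- q
  }

  if ("derep" %in% stages) {
    keep <- res$qc$bin_id[res$qc$pass]
    ani <- read_tsv(config$ani)
    ani <- ani[ani$query_bin %in% keep & ani$ref_bin %in% keep, ,
               drop = FALSE]
    cl <- stage("derep", dereplicate(
      res$qc[res$qc$pass, , drop = FALSE], ani,
      ani_threshold = config$ani_threshold,
      af_threshold = config$af_threshold,
      prefer_16s = config$prefer_16s))
    message("[derep] bins in: ", length(keep), ", clusters: ",
            length(unique(cl$cluster_id)))
    res$clusters <- cl
    out[["clusters.tsv"]] <- cl
  }

  if ("abundance" %in% stages) {
    reps <- res$clusters$bin_id[res$clusters$is_representative]
    depths <- stage("abundance", read_depth_tsv(config$depths))
    rpob <- stage("abundance", read_tsv(config$rpob_regions))
    mag_contigs <- lapply(setNames(reps, reps), function(b)
      unique(genes$contig_id[genes$bin_id == b]))
    ab <- stage("abundance", abundance_series(
      mag_contigs, depths, rpob, config$central_fraction))
    message("[abundance] representatives: ", length(reps),
            ", samples: ", length(depths))
    res$abundance <- ab
    out[["abundance.tsv"]] <- ab
  }

  if ("profile" %in% stages) {
    prof <- stage("profile", mag_profiles(genes))
    message("[profile] MAGs profiled: ", nrow(prof))
    res$profiles <- prof
    out[["profiles.tsv"]] <- prof
  }

  if ("loci" %in% stages) {
    rules <- if (is.null(config$rules_path)) pul_rules()
             else pul_rules(config$rules_path)
    puls <- stage("loci", call_puls(genes, rules = rules))
    bmc <- stage("loci", detect_bmc_loci(genes))
    message("[loci] PUL anchors: ", nrow(puls), ", BMC loci: ",
            nrow(bmc))
    res$puls <- puls
    res$bmc <- bmc
    out[["puls.tsv"]] <- puls
    out[["bmc.tsv"]] <- bmc
  }

  if ("proteome" %in% stages && !is.null(config$spectra)) {
    spc <- stage("proteome", read_tsv(config$spectra))
    ns <- stage("proteome",
                nsaf_sample_means(spc, config$n_replicates))
    res$nsaf <- ns
    out[["nsaf.tsv"]] <- ns
    if (!is.null(config$matches)) {
      mm <- stage("proteome", map_proteins_to_mag(
        read_tsv(config$matches), config$min_identity,
        config$min_coverage))
      res$protein_map <- mm
      out[["protein_map.tsv"]] <- mm
    }
    message("[proteome] proteins quantified: ",
            length(unique(ns$protein_id)))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(out), function(f)
    write_tsv(out[[f]], file.path(config$out_dir, f), hdr), character(1))
  res$paths <- paths
  invisible(res)
}
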