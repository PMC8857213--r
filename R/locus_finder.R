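#' Extract the gene neighbourhood around an anchor gene
#'
#' Takes up to `k` genes on each side of the anchor by rank along its
#' contig (at most `2k + 1` genes).  The window is `complete` only when
#' exactly `k` genes exist on both sides; windows truncated by contig ends
#' (fragmented assemblies) are flagged incomplete.
#'
#' @param genes gene table with columns `gene_id`, `contig_id`, `rank`
#'   (0-based, consecutive per contig), `start`, `end`, `strand`, `tags`.
#' @param anchor gene id of the anchor (must be present in `genes`).
#' @param k genes per side (default 10).
#' @return list with elements `anchor` (gene id), `genes` (rank-ordered
#'   data.frame of the window) and `complete` (logical).
#' @export
extract_window <- function(genes, anchor, k = 10) {
  i <- which(genes$gene_id == anchor)
  if (length(i) != 1)
    stop("anchor gene `", anchor, "` not found (or not unique)",
         call. = FALSE)
  ctg <- genes$contig_id[i]
  g <- genes[genes$contig_id == ctg, , drop = FALSE]
  g <- g[order(g$rank), , drop = FALSE]
  r <- g$rank[g$gene_id == anchor]
  win <- g[g$rank >= r - k & g$rank <= r + k, , drop = FALSE]
  rownames(win) <- NULL
  list(anchor = anchor, genes = win,
       complete = sum(win$rank < r) == k && sum(win$rank > r) == k)
}

#' Detect a contiguous inward-pointing GH29 gene pair
#'
#' TRUE when some adjacent rank pair in the window consists of two GH29
#' genes whose 3' ends converge: the lower-rank gene on `+`, the next on
#' `-`.  This strand geometry is the signature of one PUL type.
#'
#' @param window a window from [extract_window()].
#' @return logical scalar.
#' @export
detect_inward_pair <- function(window) {
  g <- window$genes
  if (nrow(g) < 2) return(FALSE)
  gh29 <- has_tag(g$tags, "GH29")
  adjacent <- diff(g$rank) == 1
  any(adjacent & gh29[-nrow(g)] & gh29[-1] &
        g$strand[-nrow(g)] == "+" & g$strand[-1] == "-")
}

#' Default PUL classification rules
#'
#' Loads the rule table shipped with the package (see
#' `system.file("extdata", "pul_rules.yaml", package = "fucopul")`).
#' Rules are data: users may edit a copy and pass it to
#' [classify_pul()].  The PUL-2 slot is present but disabled -- it is a
#' recognised arrangement without a discriminating feature set, so it is
#' never auto-assigned.
#'
#' @param path optional path to an alternative YAML rule file.
#' @return list of rule definitions, in precedence order.
#' @export
pul_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pul_rules.yaml", package = "fucopul")
  yaml::read_yaml(path)$rules
}

#' Classify a gene neighbourhood as a PUL type
#'
#' Applies the rule table in precedence order to the tag content and
#' strand geometry of a +/- `k` gene window anchored on a fucosidase- or
#' rhamnosidase-family gene; the first matching rule wins.  Precedence
#' runs from the most specific signatures (the inward-pointing GH29 pair
#' with its sulfatase, dual-sulfatase fucoidan signatures) down to the
#' sulfatase-free hydrolase-domain arrangement, so that windows carrying
#' several signatures take the strongest label.  Windows whose anchor
#' belongs to ortholog group GH29-a with an adjacent GH43_12 xylosidase
#' get the extra annotation `"sulfated fucose/xylose"`.
#'
#' @inheritParams detect_inward_pair
#' @param rules rule list, default [pul_rules()].
#' @return list with `anchor`, `pul_type` (a rule label or
#'   `"unclassified"`), `matched_features` (character) and `annotation`
#'   (character, possibly empty).
#' @export
classify_pul <- function(window, rules = pul_rules()) {
  g <- window$genes
  anchor_tags <- split_tags(g$tags[g$gene_id == window$anchor])
  target <- c(fucosidase_families, rhamnosidase_families)
  if (!any(anchor_tags %in% target))
    stop("anchor is not a fucosidase/rhamnosidase-family gene",
         call. = FALSE)
  win_tags <- unique(unlist(split_tags(g$tags)))

  pul_type <- "unclassified"
  matched <- character(0)
  for (rule in rules) {
    if (isTRUE(rule$disabled)) next
    feats <- character(0)
    ok <- TRUE
    if (isTRUE(rule$inward_pair)) {
      if (!detect_inward_pair(window)) ok <- FALSE
      else feats <- c(feats, "inward_GH29_pair")
    }
    if (ok && !is.null(rule$all_of)) {
      req <- unlist(rule$all_of)
      if (!all(req %in% win_tags)) ok <- FALSE else feats <- c(feats, req)
    }
    if (ok && !is.null(rule$any_of)) {
      for (grp in rule$any_of) {
        hit <- intersect(unlist(grp), win_tags)
        if (length(hit) == 0) { ok <- FALSE; break }
        feats <- c(feats, hit)
      }
    }
    if (ok && isTRUE(rule$no_sulfatase) && any(has_sulfatase_tag(g$tags)))
      ok <- FALSE
    if (ok) {
      pul_type <- rule$type
      matched <- unique(c(feats,
                          intersect(unlist(rule$supporting), win_tags)))
      break
    }
  }

  annotation <- character(0)
  if ("GH29-a" %in% anchor_tags) {
    r <- g$rank[g$gene_id == window$anchor]
    adj <- g[abs(g$rank - r) == 1, , drop = FALSE]
    if (any(has_tag(adj$tags, "GH43_12")))
      annotation <- "sulfated fucose/xylose"
  }
  list(anchor = window$anchor, pul_type = pul_type,
       matched_features = matched, annotation = annotation)
}

#' Scan all anchor genes of a gene table and classify their PULs
#'
#' Convenience wrapper: every gene tagged with a fucosidase or
#' rhamnosidase family is used as an anchor, its +/- `k` window extracted
#' and classified.
#'
#' @inheritParams extract_window
#' @inheritParams classify_pul
#' @return data.frame with one row per anchor: `anchor`, `contig_id`,
#'   `pul_type`, `matched_features` (";"-joined), `annotation`,
#'   `complete`.
#' @export
call_puls <- function(genes, k = 10, rules = pul_rules()) {
  target <- c(fucosidase_families, rhamnosidase_families)
  anchors <- genes$gene_id[vapply(
    strsplit(ifelse(is.na(genes$tags), "", genes$tags), ";", fixed = TRUE),
    function(tt) any(tt %in% target), logical(1))]
  out <- do.call(rbind, lapply(anchors, function(a) {
    w <- extract_window(genes, a, k)
    cl <- classify_pul(w, rules)
    data.frame(anchor = a,
               contig_id = genes$contig_id[genes$gene_id == a],
               pul_type = cl$pul_type,
               matched_features = paste(cl$matched_features, collapse = ";"),
               annotation = paste(cl$annotation, collapse = ";"),
               complete = w$complete, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(anchor = character(0), contig_id = character(0),
                      pul_type = character(0),
                      matched_features = character(0),
                      annotation = character(0), complete = logical(0))
  out
}

#' Detect bacterial microcompartment (BMC) shell loci
#'
#' Scans each contig for rank intervals of at most `span` genes holding at
#' least three BMC-H shell genes (Pfam PF00936) and at least one BMC-P
#' gene (Pfam PF03319).  Qualifying intervals separated by at most
#' `merge_gap` genes are merged into one locus (BMC shell genes often sit
#' in two contiguous sub-loci).  Each reported locus is trimmed to its
#' outermost shell gene and annotated with the presence of the core
#' methyl-pentose enzymes; a locus is PV-BMC-like when it carries an
#' aldolase (the lactaldehyde-generating AraD-like enzyme the
#' compartment exists to contain).
#'
#' @param genes gene table of one or more contigs (columns as in
#'   [extract_window()]).
#' @param span maximum width of a qualifying interval, in genes.
#' @param merge_gap maximum separation (genes) between qualifying
#'   intervals merged into one locus.
#' @return data.frame, one row per locus: `contig_id`, `start_rank`,
#'   `end_rank`, `n_bmc_h`, `n_bmc_p`, logical columns `aldolase`,
#'   `aldehyde_dehydrogenase`, `alcohol_dehydrogenase`,
#'   `phosphotransacylase`, `kinase`, and `pv_bmc_like`.
#' @export
detect_bmc_loci <- function(genes, span = 25, merge_gap = 5) {
  enz <- c("aldolase", "aldehyde_dehydrogenase", "alcohol_dehydrogenase",
           "phosphotransacylase", "kinase")
  empty <- data.frame(contig_id = character(0), start_rank = integer(0),
                      end_rank = integer(0), n_bmc_h = integer(0),
                      n_bmc_p = integer(0))
  for (e in c(enz, "pv_bmc_like")) empty[[e]] <- logical(0)
  out <- lapply(split(genes, genes$contig_id), function(g) {
    g <- g[order(g$rank), , drop = FALSE]
    n <- nrow(g)
    is_h <- has_tag(g$tags, "PF00936")
    is_p <- has_tag(g$tags, "PF03319")
    if (sum(is_h) < 3 || !any(is_p)) return(NULL)
    w <- min(span, n)
    qual <- logical(n)  # gene positions covered by a qualifying window
    for (s in seq_len(n - w + 1)) {
      idx <- s:(s + w - 1)
      if (sum(is_h[idx]) >= 3 && any(is_p[idx])) qual[idx] <- TRUE
    }
    if (!any(qual)) return(NULL)
    # runs of covered positions -> candidate intervals (gene indices)
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    iv <- cbind(starts[r$values], ends[r$values])
    # merge intervals separated by <= merge_gap genes
    merged <- iv[1, , drop = FALSE]
    if (nrow(iv) > 1) for (j in 2:nrow(iv)) {
      gap <- iv[j, 1] - merged[nrow(merged), 2] - 1
      if (gap <= merge_gap) merged[nrow(merged), 2] <- iv[j, 2]
      else merged <- rbind(merged, iv[j, , drop = FALSE])
    }
    rows <- lapply(seq_len(nrow(merged)), function(j) {
      reg <- merged[j, 1]:merged[j, 2]  # merged candidate region
      shell <- reg[is_h[reg] | is_p[reg]]
      if (length(shell) == 0) return(NULL)
      idx <- min(shell):max(shell)  # reported span: outermost shell genes
      if (sum(is_h[idx]) < 3 || !any(is_p[idx])) return(NULL)
      row <- data.frame(contig_id = g$contig_id[1],
                        start_rank = g$rank[min(idx)],
                        end_rank = g$rank[max(idx)],
                        n_bmc_h = sum(is_h[idx]), n_bmc_p = sum(is_p[idx]),
                        stringsAsFactors = FALSE)
      # accessory enzymes are read from the whole merged region: they
      # flank the shell-gene core rather than sit inside it
      for (e in enz) row[[e]] <- any(has_tag(g$tags[reg], e))
      row$pv_bmc_like <- row$aldolase
      row
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          list(empty)))
  rownames(out) <- NULL
  out
}

#' Methyl-pentose catabolism pathway report for one genome
#'
#' Checks presence of the fucose and rhamnose utilisation genes --
#' symporters (fucP, rhaT), isomerases (fucI, rhamA), mutarotases (fucU,
#' rhaM), kinase (rhaB), the lactaldehyde-generating aldolase (AraD-like)
#' and the downstream aldehyde dehydrogenase -- and labels the genome
#' `fucose-capable` (fucP, fucI, fucU and aldolase all present) and/or
#' `rhamnose-capable` (rhaT, rhamA, rhaM, rhaB and aldolase present).
#'
#' @param tags character vector of all gene tags of the genome
#'   (";"-separated strings are split), or a gene table with a `tags`
#'   column.
#' @return list with `presence` (named logical), `fucose_capable`,
#'   `rhamnose_capable`, and `capabilities` (character vector of labels).
#' @export
methylpentose_pathway_report <- function(tags) {
  if (is.data.frame(tags)) tags <- tags$tags
  all_tags <- unique(unlist(split_tags(as.character(tags))))
  genes <- c("fucP", "fucI", "fucU", "rhaT", "rhamA", "rhaM", "rhaB",
             "aldolase", "aldehyde_dehydrogenase")
  presence <- setNames(genes %in% all_tags, genes)
  fuc <- all(presence[c("fucP", "fucI", "fucU", "aldolase")])
  rha <- all(presence[c("rhaT", "rhamA", "rhaM", "rhaB", "aldolase")])
  list(presence = presence, fucose_capable = fuc, rhamnose_capable = rha,
       capabilities = c(if (fuc) "fucose-capable",
                        if (rha) "rhamnose-capable"))
}
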