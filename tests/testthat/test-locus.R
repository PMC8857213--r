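test_that("window extraction takes k genes per side and flags completeness", {
  g <- make_contig(40)
  g <- set_tag(g, 15, "GH29")
  w <- extract_window(g, g$gene_id[16], k = 10)
  expect_equal(nrow(w$genes), 21)
  expect_true(w$complete)
  w2 <- extract_window(g, g$gene_id[4], k = 10)  # rank 3: only 3 upstream
  expect_equal(nrow(w2$genes), 14)
  expect_false(w2$complete)
  w3 <- extract_window(g, g$gene_id[16], k = 0)
  expect_equal(w3$genes$gene_id, g$gene_id[16])
  expect_error(extract_window(g, "nope"), "anchor")
})

test_that("inward pair requires adjacent GH29 genes on (+,-) strands", {
  combos <- list(c("+", "-"), c("+", "+"), c("-", "+"), c("-", "-"))
  for (st in combos) {
    g <- make_contig(5)
    g <- set_tag(g, 2, "GH29", strand = st[1])
    g <- set_tag(g, 3, "GH29", strand = st[2])
    w <- extract_window(g, g$gene_id[3], k = 2)
    expect_equal(detect_inward_pair(w), identical(st, c("+", "-")))
  }
  # non-adjacent GH29 genes never form the pair
  g <- make_contig(6)
  g <- set_tag(g, 1, "GH29", strand = "+")
  g <- set_tag(g, 3, "GH29", strand = "-")
  expect_false(detect_inward_pair(extract_window(g, g$gene_id[2], k = 3)))
})

pul_window <- function(tags_at, inward = FALSE) {
  g <- make_contig(21)
  g <- set_tag(g, 10, "GH29", strand = "+")
  if (inward) g <- set_tag(g, 11, "GH29", strand = "-")
  for (i in seq_along(tags_at)) g <- set_tag(g, i - 1, tags_at[i])
  extract_window(g, g$gene_id[11], k = 10)
}

test_that("rule table classifies each feature signature to its PUL type", {
  expect_equal(classify_pul(pul_window(c("S1_15"), inward = TRUE))$pul_type,
               "PUL-7")
  expect_equal(classify_pul(pul_window(c("S1_17", "S1_25")))$pul_type,
               "PUL-3")
  expect_equal(classify_pul(pul_window(c("S1_8", "GH141")))$pul_type,
               "PUL-4")
  expect_equal(classify_pul(pul_window(c("S1_22", "GH31")))$pul_type,
               "PUL-5")
  expect_equal(classify_pul(pul_window(c("S1_16", "GH36")))$pul_type,
               "PUL-6")
  expect_equal(classify_pul(pul_window(c("PF07859")))$pul_type, "PUL-1")
  # PUL-1 demands a sulfatase-free window
  expect_equal(classify_pul(pul_window(c("PF07859", "S1_40")))$pul_type,
               "unclassified")
  expect_equal(classify_pul(pul_window(character(0)))$pul_type,
               "unclassified")
  expect_error(classify_pul(extract_window(make_contig(5),
                                           make_contig(5)$gene_id[3])),
               "anchor")
})

test_that("precedence: the inward-pair signature outranks dual-sulfatase rules", {
  w <- pul_window(c("S1_15", "S1_17", "S1_25", "PF03629"), inward = TRUE)
  cl <- classify_pul(w)
  expect_equal(cl$pul_type, "PUL-7")
  expect_true("PF03629" %in% cl$matched_features)   # supporting evidence
  # without the inward pair the same tags fall through to PUL-3
  w2 <- pul_window(c("S1_15", "S1_17", "S1_25"))
  expect_equal(classify_pul(w2)$pul_type, "PUL-3")
  # PUL-3 outranks PUL-5 when both signatures are present
  w3 <- pul_window(c("S1_17", "S1_25", "S1_22", "GH2"))
  expect_equal(classify_pul(w3)$pul_type, "PUL-3")
})

test_that("GH29-a anchors with adjacent GH43_12 carry the fucose/xylose annotation", {
  g <- make_contig(21)
  g <- set_tag(g, 10, "GH29;GH29-a", strand = "+")
  g <- set_tag(g, 11, "GH43_12")
  cl <- classify_pul(extract_window(g, g$gene_id[11], k = 10))
  expect_equal(cl$annotation, "sulfated fucose/xylose")
  # not adjacent -> no annotation
  g2 <- make_contig(21)
  g2 <- set_tag(g2, 10, "GH29;GH29-a", strand = "+")
  g2 <- set_tag(g2, 13, "GH43_12")
  expect_length(classify_pul(extract_window(g2, g2$gene_id[11],
                                            k = 10))$annotation, 0)
})

test_that("PUL-2 stays a disabled rule slot under the default table", {
  types <- vapply(pul_rules(), `[[`, character(1), "type")
  expect_true("PUL-2" %in% types)
  expect_error(plant_pul(make_contig(21), "binA", "PUL-2"), "disabled")
  expect_error(plant_pul(make_contig(21), "binA", "PUL-9"), "unknown")
})

test_that("BMC loci need >= 3 BMC-H and >= 1 BMC-P within the span", {
  g <- make_contig(40)
  for (r in c(5, 7, 9)) g <- set_tag(g, r, "PF00936")
  g <- set_tag(g, 11, "PF03319")
  g <- set_tag(g, 12, "aldolase")
  g <- set_tag(g, 13, "aldehyde_dehydrogenase")
  loci <- detect_bmc_loci(g)
  expect_equal(nrow(loci), 1)
  expect_true(loci$pv_bmc_like)
  expect_true(loci$aldehyde_dehydrogenase)
  expect_equal(loci$n_bmc_h, 3)
  # only two shell genes: no locus
  g2 <- set_tag(set_tag(make_contig(40), 5, "PF00936"), 7, "PF00936")
  g2 <- set_tag(g2, 9, "PF03319")
  expect_equal(nrow(detect_bmc_loci(g2)), 0)
  # no aldolase: a shell locus, but not PV-BMC-like
  g3 <- make_contig(40)
  for (r in c(5, 6, 7)) g3 <- set_tag(g3, r, "PF00936")
  g3 <- set_tag(g3, 8, "PF03319")
  expect_false(detect_bmc_loci(g3)$pv_bmc_like)
})

test_that("two qualifying shell clusters a few genes apart merge into one locus", {
  g <- make_contig(60)
  for (r in c(5, 6, 7)) g <- set_tag(g, r, "PF00936")
  g <- set_tag(g, 8, "PF03319")
  for (r in c(14, 15, 16)) g <- set_tag(g, r, "PF00936")
  g <- set_tag(g, 17, "PF03319")
  loci <- detect_bmc_loci(g, span = 6, merge_gap = 5)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start_rank, 5)
  expect_equal(loci$end_rank, 17)
  expect_equal(loci$n_bmc_h, 6)
  # far apart beyond the merge gap: two loci
  g2 <- make_contig(120)
  for (r in c(5, 6, 7)) g2 <- set_tag(g2, r, "PF00936")
  g2 <- set_tag(g2, 8, "PF03319")
  for (r in c(80, 81, 82)) g2 <- set_tag(g2, r, "PF00936")
  g2 <- set_tag(g2, 83, "PF03319")
  expect_equal(nrow(detect_bmc_loci(g2, span = 6, merge_gap = 5)), 2)
})

test_that("BMC detection agrees with a brute-force window scan on random scatters", {
  set.seed(12)
  for (i in 1:20) {
    g <- make_contig(50)
    for (r in sample(0:49, sample(0:5, 1))) g <- set_tag(g, r, "PF00936")
    for (r in sample(0:49, sample(0:2, 1)))
      g$tags[g$rank == r] <- paste0(g$tags[g$rank == r], ";PF03319")
    loci <- detect_bmc_loci(g, span = 10, merge_gap = 3)
    expect_equal(nrow(loci) > 0, oracle_bmc_exists(g$tags, 10))
    if (nrow(loci)) {
      expect_true(all(loci$n_bmc_h >= 3))
      expect_true(all(loci$n_bmc_p >= 1))
    }
  }
})

test_that("pathway capability labels match their presence predicates", {
  fuc_set <- c("fucP", "fucI", "fucU", "aldolase")
  rha_set <- c("rhaT", "rhamA", "rhaM", "rhaB", "aldolase")
  all_genes <- c("fucP", "fucI", "fucU", "rhaT", "rhamA", "rhaM", "rhaB",
                 "aldolase", "aldehyde_dehydrogenase")
  expect_true(methylpentose_pathway_report(fuc_set)$fucose_capable)
  expect_false(methylpentose_pathway_report(
    setdiff(fuc_set, "fucI"))$fucose_capable)
  r <- methylpentose_pathway_report(rha_set)
  expect_equal(r$capabilities, "rhamnose-capable")
  # enumeration over random presence subsets
  set.seed(13)
  for (i in 1:30) {
    sub <- sample(all_genes, sample(0:9, 1))
    rep <- methylpentose_pathway_report(sub)
    expect_equal(rep$fucose_capable, all(fuc_set %in% sub))
    expect_equal(rep$rhamnose_capable, all(rha_set %in% sub))
    expect_equal(unname(rep$presence), all_genes %in% sub)
  }
})
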