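test_that("ANI edges require both gates in at least one direction", {
  rec <- function(ani_ab, af_ab, ani_ba = NULL, af_ba = NULL) {
    r <- data.frame(query_bin = "a", ref_bin = "b", ani = ani_ab,
                    aligned_fraction = af_ab)
    if (!is.null(ani_ba))
      r <- rbind(r, data.frame(query_bin = "b", ref_bin = "a",
                               ani = ani_ba, aligned_fraction = af_ba))
    r
  }
  expect_equal(nrow(build_ani_graph(rec(96, 0.70), 95, 0.65)), 1)
  expect_equal(nrow(build_ani_graph(rec(96, 0.60, 96, 0.60), 95, 0.65)), 0)
  # all four direction-pass combinations against the either-direction rule
  pass_dir <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                   c(FALSE, FALSE))
  for (pd in pass_dir) {
    r <- rec(ifelse(pd[1], 97, 90), 0.8, ifelse(pd[2], 97, 90), 0.8)
    expect_equal(nrow(build_ani_graph(r, 95, 0.65)) == 1, any(pd))
  }
  expect_error(build_ani_graph(rec(101, 0.7), 95, 0.65), "row 1")
  expect_error(build_ani_graph(
    data.frame(query_bin = "a", ref_bin = "a", ani = 99,
               aligned_fraction = 1), 95, 0.65), "row 1")
})

test_that("clusters are connected components with singletons preserved", {
  no_edges <- data.frame(a = character(0), b = character(0))
  cl <- cluster_bins(letters[1:5], no_edges)
  expect_equal(length(unique(cl$cluster_id)), 5)
  chain <- data.frame(a = c("a", "b"), b = c("b", "c"))
  cl <- cluster_bins(c("a", "b", "c", "d"), chain)
  expect_equal(sort(cl$bin_id[cl$cluster_id == cl$cluster_id[1]]),
               c("a", "b", "c"))
  expect_error(cluster_bins(c("a"), chain), "endpoint")
})

test_that("clustering matches brute-force transitive closure on random instances", {
  set.seed(101)
  for (rep in 1:15) {
    inst <- random_ani_instance(sample(4:12, 1))
    t_ani <- runif(1, 90, 99)
    t_af <- runif(1, 0.5, 0.9)
    got <- cluster_bins(inst$bins,
                        build_ani_graph(inst$records, t_ani, t_af))
    expect_true(same_partition(
      partition_of(got),
      oracle_partition(inst$bins, inst$records, t_ani, t_af)))
  }
})

test_that("representative selection honours score and the 16S preference", {
  q <- data.frame(bin_id = c("a", "b", "c"),
                  completion = c(90, 95, 85), contamination = 0,
                  n50 = 1e5, has_16s = c(TRUE, FALSE, FALSE))
  expect_equal(select_representative(c("a", "b"), q, prefer_16s = FALSE),
               "b")
  # a higher-scoring MAG lacking 16S is not selected over a 16S bearer
  expect_equal(select_representative(c("a", "b"), q, prefer_16s = TRUE),
               "a")
  q$has_16s <- FALSE
  expect_equal(select_representative(c("a", "b"), q, prefer_16s = TRUE),
               "b")
  expect_error(select_representative(character(0), q), "empty")
})

test_that("16S preference equals brute-force rule over all flag combinations", {
  members <- c("a", "b", "c")
  scores <- c(a = 90, b = 95, c = 92)
  for (mask in 0:7) {
    flags <- as.logical(bitwAnd(mask, c(1, 2, 4)))
    q <- data.frame(bin_id = members, completion = scores,
                    contamination = 0, n50 = 1, has_16s = flags)
    # oracle: restrict to 16S bearers when any, then argmax score
    pool <- if (any(flags)) members[flags] else members
    want <- pool[which.max(scores[pool])]
    expect_equal(select_representative(members, q, prefer_16s = TRUE),
                 want)
  }
})

test_that("dereplication partitions bins and is idempotent", {
  set.seed(7)
  com <- generate_community(community_config(seed = 7))
  d <- dereplicate(com$quality, com$ani, 95)
  expect_setequal(d$bin_id, com$quality$bin_id)
  expect_equal(anyDuplicated(d$bin_id), 0)
  # one representative per cluster
  expect_equal(as.vector(tapply(d$is_representative, d$cluster_id, sum)),
               rep(1L, length(unique(d$cluster_id))))
  # re-running on representatives yields singletons
  reps <- d$bin_id[d$is_representative]
  q2 <- com$quality[com$quality$bin_id %in% reps, ]
  ani2 <- com$ani[com$ani$query_bin %in% reps &
                    com$ani$ref_bin %in% reps, ]
  d2 <- dereplicate(q2, ani2, 95)
  expect_equal(length(unique(d2$cluster_id)), length(reps))
  # single bin input
  d3 <- dereplicate(q2[1, ], ani2[0, ], 95)
  expect_true(d3$is_representative)
})

test_that("cluster count is non-increasing as the ANI threshold decreases", {
  cfg <- community_config(strains_per_cluster = 2, seed = 11)
  com <- generate_community(cfg)
  n_at <- function(t) length(unique(
    dereplicate(com$quality, com$ani, t)$cluster_id))
  counts <- vapply(c(99.9, 99, 97, 95, 90, 75), n_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
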