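ranked_fixture <- function(genes, metric) {
  ord <- order(-metric, genes)
  structure(list(genes = genes[ord],
                 metric = stats::setNames(metric[ord], genes[ord])),
            class = "ranked_list")
}

test_that("signal-to-noise ranking is deterministic and zero for flat genes", {
  m <- tiny_expr(12, seed = 61, extra = c("AAA", "ZZZ"))
  m["AAA", ] <- 5; m["ZZZ", ] <- 5  # identical in both groups
  grp <- factor(rep(c("low", "high"), 6), levels = c("low", "high"))
  rl <- rank_genes(m, grp)
  expect_equal(unname(rl$metric[c("AAA", "ZZZ")]), c(0, 0))
  # equal metrics resolve lexicographically, stable across runs
  pos <- match(c("AAA", "ZZZ"), rl$genes)
  expect_lt(pos[1], pos[2])
  expect_identical(rl, rank_genes(m, grp))
  expect_error(rank_genes(m, factor(c("high", rep("low", 11)), c("low", "high"))),
               class = "immunocyt_degenerate_input_error")
})

test_that("enrichment score hits the boundary cases exactly", {
  rl <- ranked_fixture(paste0("G", 1:4), c(4, 3, 2, 1))
  # single hit at rank 1, weight 0: walk peaks at +1 before any miss
  es1 <- enrichment_score(rl, "G1", weight = 0)
  expect_equal(es1$es, 1)
  expect_equal(es1$leading_edge, "G1")
  # set = entire list: no misses, running sum peaks at 1
  esall <- enrichment_score(rl, paste0("G", 1:4), weight = 0)
  expect_equal(esall$es, 1)
  expect_error(enrichment_score(rl, c("X1", "X2")),
               class = "immunocyt_no_overlap_error")
})

test_that("running sum matches a hand-enumerated walk oracle", {
  genes <- sprintf("G%02d", 1:10)  # zero-padded so ties sort in rank order
  rl <- ranked_fixture(genes, rep(1, 10))  # uniform metric
  set <- c("G02", "G05")
  es <- enrichment_score(rl, set, weight = 0)
  walk <- oracle_walk(rl$genes, set)
  expect_equal(es$running_sum, walk, tolerance = 1e-12)
  # +1/2 at hits (ranks 2 and 5), -1/8 at misses; extremum after rank 5
  expect_equal(es$es, -1/8 + 1/2 - 1/8 - 1/8 + 1/2, tolerance = 1e-12)
  expect_equal(es$es, max(abs(walk)) * sign(walk[which.max(abs(walk))]),
               tolerance = 1e-12)
  expect_equal(es$leading_edge, c("G02", "G05"))
})

test_that("walk ends at zero and ES stays within [-1, 1] on random inputs", {
  set.seed(62)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    rl <- ranked_fixture(paste0("g", seq_len(n)), rnorm(n))
    set <- sample(rl$genes, sample(2:10, 1))
    w <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(rl, set, weight = w)
    expect_lt(abs(es$running_sum[n]), 1e-12)
    expect_gte(es$es, -1); expect_lte(es$es, 1)
  }
})

test_that("reversing the ranked list negates the unweighted ES", {
  set.seed(63)
  n <- 40
  metric <- sort(rnorm(n), decreasing = TRUE)
  genes <- paste0("g", seq_len(n))
  rl <- ranked_fixture(genes, metric)
  rev_rl <- structure(list(genes = rev(rl$genes),
                           metric = rev(rl$metric)), class = "ranked_list")
  for (i in 1:10) {
    set <- sample(genes, 6)
    a <- enrichment_score(rl, set, weight = 0)$es
    b <- enrichment_score(rev_rl, set, weight = 0)$es
    expect_equal(a, -b, tolerance = 1e-10)
  }
})

test_that("weighted ES agrees with the fgsea statistic", {
  skip_if_not_installed("fgsea")
  set.seed(64)
  n <- 50
  stats_vec <- sort(rnorm(n), decreasing = TRUE)
  names(stats_vec) <- paste0("g", seq_len(n))
  rl <- ranked_fixture(names(stats_vec), unname(stats_vec))
  for (i in 1:10) {
    set <- sample(names(stats_vec), 7)
    mine <- enrichment_score(rl, set, weight = 1)$es
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = which(names(stats_vec) %in% set),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("permutation testing is deterministic and respects its guards", {
  co <- generate_cohort(sim_config(n_samples = 60, seed = 65, n_decoy = 60))
  grp <- dichotomize_by_median(cyt_score(co$expression))
  rl <- rank_genes(co$expression, grp)
  set <- sprintf("PLANT%03d", 1:30)
  r1 <- normalize_and_test(rl, set, n_perm = 200, seed = 9)
  r2 <- normalize_and_test(rl, set, n_perm = 200, seed = 9)
  expect_identical(r1[c("es", "nes", "nominal_p")], r2[c("es", "nes", "nominal_p")])
  expect_error(normalize_and_test(rl, set, n_perm = 50),
               class = "immunocyt_config_error")
  # NES carries the sign of ES; p in (0, 1]
  expect_equal(sign(r1$nes), sign(r1$es))
  expect_true(r1$nominal_p > 0 && r1$nominal_p <= 1)
})

test_that("random gene sets are calibrated uniform under the gene-set null", {
  co <- generate_cohort(null_config(60, 66))
  grp <- dichotomize_by_median(cyt_score(co$expression))
  rl <- rank_genes(co$expression, grp)
  set.seed(67)
  pvals <- vapply(1:100, function(i) {
    set <- sample(rl$genes, 15)
    normalize_and_test(rl, set, n_perm = 150)$nominal_p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("collection-level analysis detects the planted set and orders p by |NES|", {
  cfg <- sim_config(n_samples = 200, seed = 68)
  co <- generate_cohort(cfg)
  grp <- dichotomize_by_median(cyt_score(co$expression))
  sets <- c(planted_gene_set(cfg),
            list(RANDOM_A = sprintf("DECOY%03d", 1:25),
                 RANDOM_B = sprintf("DECOY%03d", 26:55)))
  tab <- gsea_analysis(co$expression, grp, sets, n_perm = 200,
                       perm_mode = "gene_set", seed = 69)
  expect_s3_class(tab, "gsea_table")
  planted <- tab[tab$set == "PLANTED_IMMUNE_RESPONSE", ]
  expect_lt(planted$nominal_p, 0.05)
  expect_gt(planted$nes, 1)
  # q defined exactly where NES is defined, and bounded
  expect_identical(is.na(tab$fdr_q), is.na(tab$nes))
  q <- tab$fdr_q[!is.na(tab$fdr_q)]
  expect_true(all(q >= 0 & q <= 1))
  # within a run, smaller p goes with larger |NES|
  ok <- !is.na(tab$nes)
  ord <- order(-abs(tab$nes[ok]))
  expect_true(all(diff(tab$nominal_p[ok][ord]) >= -1e-9))
  # leading edge is a subset of the set members present in the ranking
  le <- strsplit(planted$leading_edge, ",")[[1]]
  expect_true(all(le %in% sets$PLANTED_IMMUNE_RESPONSE))
})

test_that("phenotype permutation mode runs and flags its mode", {
  cfg <- sim_config(n_samples = 40, seed = 70, n_decoy = 40)
  co <- generate_cohort(cfg)
  grp <- dichotomize_by_median(cyt_score(co$expression))
  tab <- gsea_analysis(co$expression, grp, planted_gene_set(cfg),
                       n_perm = 100, perm_mode = "auto", seed = 71)
  expect_equal(unique(tab$perm_mode), "phenotype")  # both groups >= 7
  expect_lt(tab$nominal_p[1], 0.05)
})

test_that("set members absent from the matrix are dropped with a message", {
  co <- generate_cohort(sim_config(n_samples = 30, seed = 72, n_decoy = 30))
  grp <- dichotomize_by_median(cyt_score(co$expression))
  sets <- list(S = c("GZMA", "PRF1", "NOT_A_GENE"))
  expect_message(tab <- gsea_analysis(co$expression, grp, sets, n_perm = 100,
                                      perm_mode = "gene_set", seed = 73),
                 "absent")
  expect_equal(tab$size, 2)
})
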