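test_that("CYT is the geometric mean of GZMA and PRF1", {
  m <- matrix(c(4, 9), nrow = 2, dimnames = list(c("GZMA", "PRF1"), "S1"))
  expect_equal(unname(cyt_score(m, pseudocount = 0)), 6)
  # identity: equal expression returns itself
  for (g in c(0, 0.5, 7, 123)) {
    mg <- matrix(c(g, g), nrow = 2, dimnames = list(c("GZMA", "PRF1"), "S1"))
    expect_equal(unname(cyt_score(mg, pseudocount = 0)), g)
  }
  # pseudocount case against a direct log-space oracle
  oracle <- exp(0.5 * (log(4.01) + log(9.01)))
  expect_equal(unname(cyt_score(m, pseudocount = 0.01)), oracle)
  # zero TPM with zero pseudocount gives exactly 0
  m0 <- matrix(c(0, 9), nrow = 2, dimnames = list(c("GZMA", "PRF1"), "S1"))
  expect_identical(unname(cyt_score(m0, pseudocount = 0)), 0)
  expect_error(cyt_score(m[1, , drop = FALSE]), class = "immunocyt_missing_gene_error")
})

test_that("CYT is scale-equivariant at pseudocount 0", {
  m <- tiny_expr(6, seed = 1)
  base <- cyt_score(m, pseudocount = 0)
  for (c_mult in c(0.5, 3, 10)) {
    m2 <- m
    m2[c("GZMA", "PRF1"), ] <- m2[c("GZMA", "PRF1"), ] * c_mult
    expect_equal(cyt_score(m2, pseudocount = 0), base * c_mult)
  }
})

test_that("log-average panel score matches exact dyadic cases", {
  m <- matrix(rep(1, 7), ncol = 1, dimnames = list(apobec3_panel(), "S1"))
  expect_equal(unname(log_average_score(m, apobec3_panel(), 1)), 1)
  m0 <- matrix(rep(0, 7), ncol = 1, dimnames = list(apobec3_panel(), "S1"))
  expect_equal(unname(log_average_score(m0, apobec3_panel(), 1)), 0)
  m2 <- matrix(c(3, 7), ncol = 1, dimnames = list(c("A", "B"), "S1"))
  expect_equal(unname(log_average_score(m2, c("A", "B"), 1)), 2.5)
  expect_error(log_average_score(m2, c("A", "MISSING")),
               class = "immunocyt_missing_gene_error")
})

test_that("log-average score shifts by exactly delta under panel-wide scaling", {
  m <- tiny_expr(5, seed = 2)
  pc <- 1
  base <- log_average_score(m, apobec3_panel(), pc)
  delta <- 1.5
  m2 <- m
  # shift every log2(TPM + pc) by delta: TPM' = 2^delta (TPM + pc) - pc
  m2[apobec3_panel(), ] <- 2^delta * (m2[apobec3_panel(), ] + pc) - pc
  expect_equal(log_average_score(m2, apobec3_panel(), pc), base + delta)
})

test_that("checkpoint panel aliases resolve to HGNC symbols", {
  m <- tiny_expr(3, seed = 3)
  direct <- log_average_score(m, c("PDCD1", "CD274"))
  aliased <- log_average_score(m, c("PD-1", "PD-L1"))
  expect_equal(unname(direct), unname(aliased))
})

test_that("median dichotomization follows the strict-greater rule", {
  g <- dichotomize_by_median(c(a = 1, b = 2, c = 3))
  expect_equal(as.character(g), c("low", "low", "high"))
  # 371 tie-free values split 185 high / 186 low
  set.seed(10)
  g371 <- dichotomize_by_median(sample(seq_len(371)))
  expect_equal(sum(g371 == "high"), 185)
  expect_equal(sum(g371 == "low"), 186)
  # all equal values: strict-greater sends everything low
  gall <- dichotomize_by_median(rep(5, 10))
  expect_equal(sum(gall == "high"), 0)
  expect_error(dichotomize_by_median(3), class = "immunocyt_degenerate_input_error")
  expect_error(dichotomize_by_median(c(1, NA, 2)), class = "immunocyt_degenerate_input_error")
})

test_that("tie-free split sizes obey the parity rule", {
  set.seed(4)
  for (n in c(4, 5, 100, 101, 371)) {
    g <- dichotomize_by_median(rnorm(n))
    if (n %% 2 == 0) {
      expect_equal(sum(g == "high"), n / 2)
    } else {
      expect_equal(sum(g == "high"), (n - 1) / 2)
      expect_equal(sum(g == "low"), (n + 1) / 2)
    }
  }
})

test_that("HLA extraction returns raw TPM and single-gene panel identity holds", {
  m <- tiny_expr(4, seed = 5)
  hla <- hla_expression(m)
  expect_equal(hla$hla_a, unname(m["HLA-A", ]))
  expect_equal(hla$hla_b, unname(m["HLA-B", ]))
  expect_equal(unname(log_average_score(m, "HLA-A", 1)),
               unname(log2(m["HLA-A", ] + 1)))
  m2 <- m[setdiff(rownames(m), "HLA-B"), ]
  expect_error(hla_expression(m2), class = "immunocyt_missing_gene_error")
})

test_that("score frame joins all modalities and tolerates missing ones", {
  co <- generate_cohort(sim_config(n_samples = 10, seed = 6, n_decoy = 5, n_planted = 2))
  frame <- build_score_frame(co$expression, co$segments, co$repertoire)
  cols <- c("cyt", "apobec3", "checkpoint_index", "hla_a", "hla_b",
            "scna_events", "tcr_richness", "bcr_richness", "cpk")
  expect_true(all(cols %in% names(frame)))
  expect_false(anyNA(frame[cols]))
  expect_s3_class(frame$cyt_group, "factor")

  # sample without a segment profile: scna missing, everything else present
  frame2 <- build_score_frame(co$expression, co$segments[-1], co$repertoire)
  expect_true(is.na(frame2$scna_events[1]))
  expect_false(anyNA(frame2$cyt))

  # no overlap at all is an alignment error
  segs <- co$segments
  names(segs) <- paste0("X", names(segs))
  expect_error(build_score_frame(co$expression, segs, co$repertoire),
               class = "immunocyt_alignment_error")
})

test_that("score frame is invariant to input sample order", {
  co <- generate_cohort(sim_config(n_samples = 8, seed = 7, n_decoy = 4, n_planted = 2))
  f1 <- build_score_frame(co$expression, co$segments, co$repertoire)
  perm <- sample(ncol(co$expression))
  f2 <- build_score_frame(co$expression, co$segments[perm],
                          co$repertoire[rev(seq_len(nrow(co$repertoire))), ])
  attr(f1, "provenance") <- attr(f2, "provenance") <- NULL
  expect_equal(f1, f2)
  f3 <- build_score_frame(co$expression, co$segments, co$repertoire)
  attr(f3, "provenance") <- NULL
  expect_identical(f1, f3)  # pure function of its inputs
})

test_that("score frame TSV records provenance in its header", {
  co <- generate_cohort(sim_config(n_samples = 5, seed = 8, n_decoy = 3, n_planted = 2))
  frame <- build_score_frame(co$expression, co$segments, co$repertoire)
  p <- tempfile()
  write_score_frame(frame, p)
  head_lines <- readLines(p, n = 4)
  expect_match(head_lines[1], "log_base=2")
  expect_match(head_lines[2], "APOBEC3A")
})
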