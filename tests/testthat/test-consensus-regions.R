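# The three consensus stages: merge into potential CNVRs, representativeness
# filtering, cross-caller intersection, cross-type specificity, summaries.

meta <- toy_metadata()

test_that("overlapping calls merge; book-ended calls do not", {
  calls <- rbind(make_call("s01", 1, 100, 200, 3),
                 make_call("s02", 1, 150, 300, 1))
  pot <- merge_calls_to_potential(calls, meta)
  expect_equal(nrow(pot), 1L)
  expect_equal(pot$start_bp, 100)
  expect_equal(pot$end_bp, 300)
  expect_equal(pot$n_samples, 2L)
  expect_equal(pot$samples, "s01,s02")
  expect_equal(pot$n_gain, 1L)
  expect_equal(pot$n_loss, 1L)

  booked <- rbind(make_call("s01", 1, 100, 200, 3),
                  make_call("s02", 1, 201, 300, 3))
  expect_equal(nrow(merge_calls_to_potential(booked, meta)), 2L)

  expect_error(
    merge_calls_to_potential(calls, meta, chromosomes = c("2", "3")),
    "unknown chromosome"
  )
})

test_that("merged regions equal the overlap-connectivity oracle on random inputs", {
  set.seed(42)
  for (rep in 1:40) {
    m <- sample(5:50, 1)
    start <- sample.int(5000, m, replace = TRUE)
    end <- start + sample.int(300, m, replace = TRUE)
    calls <- make_call(sample(meta$sample_id[1:6], m, replace = TRUE),
                       1, start, end, sample(c(1L, 3L), m, replace = TRUE))
    pot <- merge_calls_to_potential(calls, meta, cattle_type = "taurine",
                                    caller_id = "viterbi")
    spans <- oracle_overlap_components(start, end)
    expect_equal(pot$start_bp, spans[, 1])
    expect_equal(pot$end_bp, spans[, 2])

    # order invariance and idempotence
    shuffled <- calls[sample.int(m), ]
    pot2 <- merge_calls_to_potential(shuffled, meta,
                                     cattle_type = "taurine",
                                     caller_id = "viterbi")
    expect_equal(pot2[, -1], pot[, -1])
    as_calls <- make_call("s01", 1, pot$start_bp, pot$end_bp, 3L)
    re <- merge_calls_to_potential(as_calls, meta)
    expect_equal(re$start_bp, pot$start_bp)
    expect_equal(re$end_bp, pot$end_bp)
  }
})

test_that("representativeness keeps >=3 individuals OR >=2 populations", {
  base <- merge_calls_to_potential(
    rbind(make_call("s01", 1, 100, 200, 3),
          make_call("s02", 1, 150, 250, 3),
          make_call("s03", 1, 180, 300, 3),   # 3 samples, 1 population
          make_call("s01", 1, 1000, 1100, 3),
          make_call("s04", 1, 1050, 1200, 3), # 2 samples, 2 populations
          make_call("s02", 1, 2000, 2100, 3),
          make_call("s03", 1, 2050, 2200, 3)  # 2 samples, 1 population
    ), meta)
  kept <- representativeness_filter(base)
  expect_equal(kept$start_bp, c(100, 1000))
  expect_equal(nrow(representativeness_filter(base, 2, 2)), 3L)
})

test_that("cross-caller intersection matches the per-base oracle and stays inside parents", {
  a <- make_region_df(1, 100, 250, caller_id = "viterbi")
  b <- make_region_df(1, 200, 300, caller_id = "bayes", prefix = "B")
  cand <- intersect_callers(a, b)
  expect_equal(cand$start_bp, 200)
  expect_equal(cand$end_bp, 250)

  expect_equal(nrow(intersect_callers(make_region_df(1, 100, 200),
                                      make_region_df(1, 300, 400, prefix = "B"))),
               0L)

  a2 <- make_region_df(1, c(100, 400), c(250, 500))
  b2 <- make_region_df(1, 200, 450, prefix = "B")
  cand2 <- intersect_callers(a2, b2)
  expect_equal(cand2$start_bp, c(200, 400))
  expect_equal(cand2$end_bp, c(250, 450))
  expect_equal(cand2$provenance_b, c("B001", "B001"))

  set.seed(7)
  for (rep in 1:40) {
    na <- sample(3:20, 1); nb <- sample(3:20, 1)
    # representative regions within a caller are disjoint by construction
    ra <- draw_merged_spans(na, 3000, 400)
    rb <- draw_merged_spans(nb, 3000, 400)
    cand <- intersect_callers(
      make_region_df(1, ra[, 1], ra[, 2]),
      make_region_df(1, rb[, 1], rb[, 2], prefix = "B")
    )
    oracle <- oracle_perbase_intersect(ra[, 1], ra[, 2], rb[, 1], rb[, 2],
                                       4000L)
    expect_equal(cand$start_bp, oracle[, 1])
    expect_equal(cand$end_bp, oracle[, 2])
    # every candidate is contained in a representative region of each caller
    for (i in seq_len(nrow(cand))) {
      expect_true(any(ra[, 1] <= cand$start_bp[i] & ra[, 2] >= cand$end_bp[i]))
      expect_true(any(rb[, 1] <= cand$start_bp[i] & rb[, 2] >= cand$end_bp[i]))
    }
  }
})

test_that("union bounds mode spans each cross-caller overlap component", {
  a <- make_region_df(1, c(100, 400), c(250, 500))
  b <- make_region_df(1, 200, 450, prefix = "B")
  cand <- intersect_callers(a, b, bounds = "union")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start_bp, 100)
  expect_equal(cand$end_bp, 500)
})

test_that("specificity labels and shared spans follow the overlap graph", {
  a <- make_region_df(1, 10, 100, cattle_type = "taurine", prefix = "A")
  names(a)[1] <- "candidate_id"
  b <- make_region_df(1, 500, 600, cattle_type = "zebu", prefix = "B")
  names(b)[1] <- "candidate_id"
  cls <- classify_specificity(a, b)
  expect_equal(sort(cls$final$label), c("taurine_specific", "zebu_specific"))
  expect_equal(cls$accounting$shared, 0L)

  b2 <- make_region_df(1, 50, 150, cattle_type = "zebu", prefix = "B")
  names(b2)[1] <- "candidate_id"
  cls2 <- classify_specificity(a, b2)
  expect_equal(cls2$final$label, "shared")
  expect_equal(cls2$final$start_bp, 10)
  expect_equal(cls2$final$end_bp, 150)
})

test_that("specificity equals the bipartite-components oracle and accounting balances", {
  set.seed(11)
  for (rep in 1:40) {
    na <- sample(2:15, 1); nb <- sample(2:15, 1)
    ra <- draw_merged_spans(na, 2000, 300)
    rb <- draw_merged_spans(nb, 2000, 300)
    a <- make_region_df(1, ra[, 1], ra[, 2], cattle_type = "taurine",
                        prefix = "A")
    b <- make_region_df(1, rb[, 1], rb[, 2], cattle_type = "zebu",
                        prefix = "B")
    names(a)[1] <- names(b)[1] <- "candidate_id"
    cls <- classify_specificity(a, b)
    memb <- oracle_bipartite_components(ra[, 1], ra[, 2], rb[, 1], rb[, 2])
    sizes <- table(memb)
    n_shared_oracle <- sum(sizes > 1)
    n_specific_oracle <- sum(sizes == 1)
    expect_equal(cls$accounting$shared, n_shared_oracle)
    expect_equal(sum(cls$final$label != "shared"), n_specific_oracle)
    # accounting identities
    acc <- cls$accounting
    expect_equal(sum(acc$per_type$specific) + acc$shared, acc$final)
    expect_equal(acc$per_type$specific + acc$per_type$absorbed,
                 acc$per_type$candidates)
    # final set is pairwise non-overlapping
    f <- cls$final[order(cls$final$start_bp), ]
    if (nrow(f) > 1) expect_true(all(f$start_bp[-1] > f$end_bp[-nrow(f)]))
  }
})

test_that("region summaries bin lengths and report coverage", {
  regs <- data.frame(chrom = c("1", "1", "2"),
                     start_bp = c(1, 100001, 1),
                     end_bp = c(40000, 160000, 2000000))
  s <- summarize_regions(regs)
  expect_equal(s$count, 3L)
  expect_equal(unname(s$length_class_counts), c(1L, 1L, 0L, 0L, 1L))
  expect_equal(s$mean_length_bp, 700000)
  expect_equal(s$total_bp, 2100000)
  expect_equal(sum(s$length_class_counts), s$count)

  # a 165.2 kb region falls in the 100-500 kb class
  s2 <- summarize_regions(data.frame(chrom = "1", start_bp = 1,
                                     end_bp = 165200))
  expect_equal(unname(s2$length_class_counts), c(0L, 0L, 1L, 0L, 0L))

  s0 <- summarize_regions(regs[0, ])
  expect_equal(s0$count, 0L)
  expect_true(is.na(s0$mean_length_bp))
})
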