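test_that("tag assignment picks the best anchored tag and rejects ties", {
  tpa <- make_tpa()
  read <- build_read(rand_dna(50), tag = FIX_TAGS[["A"]])

  tg <- assign_tags(read, tpa, 0)
  expect_equal(tg$fwd_tag, "A")
  expect_equal(tg$fwd_hit$start, 0)

  # one substitution inside the tag: found at 1 edit, not at 0
  read1 <- paste0("AAGTACGT", substr(read, 9, nchar(read)))
  expect_equal(assign_tags(read1, tpa, 1)$fwd_tag, "A")
  expect_true(is.na(assign_tags(read1, tpa, 0)$fwd_tag))

  # two tags equidistant from the prefix: ambiguous, no assignment
  tie_tpa <- make_tpa(tags = c(X = "AAAACCCC", Y = "AAAACCGG"))
  tie_read <- paste0("AAAACCCG", rand_dna(40))  # 1 edit from both
  tg <- assign_tags(tie_read, tie_tpa, 1)
  expect_true(is.na(tg$fwd_tag))
  expect_true(tg$ambiguous)
})

test_that("end-tag compatibility distinguishes pass, fail, not applicable", {
  expect_equal(check_tag_compatibility("A", "A"), "pass")
  expect_equal(check_tag_compatibility("A", "B"), "fail")
  expect_equal(check_tag_compatibility("A", NA), "not_applicable")
})

test_that("primer detection honours mode, mismatch allowance, degeneracy", {
  target <- rand_dna(200)
  full <- build_read(target)
  partial <- paste0(FIX_TAGS[["A"]], FIX_FP, target)  # never sequenced to RP

  pr <- detect_primers(partial, FIX_FP, FIX_RP, "FP_AND_RP", 0, fp_from = 8)
  expect_equal(pr$status, "no_primer")
  pr <- detect_primers(partial, FIX_FP, FIX_RP, "FP_ONLY", 0, fp_from = 8)
  expect_equal(pr$status, "pass")

  # forward primer with 2 substitutions
  fp2 <- mutate_subs(FIX_FP, 2)
  read2 <- paste0(FIX_TAGS[["A"]], fp2, target, revcomp(FIX_RP))
  expect_equal(detect_primers(read2, FIX_FP, FIX_RP, "FP_AND_RP", 2,
                              fp_from = 8, rp_window_extra = 8)$status, "pass")
  expect_equal(detect_primers(read2, FIX_FP, FIX_RP, "FP_AND_RP", 0,
                              fp_from = 8, rp_window_extra = 8)$status, "no_primer")

  # degenerate primer position matches either base without cost
  dfp <- paste0("GGAAGTARAA", substr(FIX_FP, 11, nchar(FIX_FP)))  # R at pos 8
  read3 <- paste0(FIX_TAGS[["A"]], FIX_FP, target)
  expect_equal(detect_primers(read3, dfp, NULL, "FP_ONLY", 0,
                              fp_from = 8)$status, "pass")
})

test_that("ambiguity and length screens apply in order with defaults", {
  expect_equal(screen_sequence(paste0("ACGTN", rand_dna(200)), 0, 150), "ambiguous")
  expect_equal(screen_sequence(paste0("ACGTR", rand_dna(200)), 0, 150), "ambiguous")
  expect_equal(screen_sequence(rand_dna(149), 0, 150), "too_short")
  expect_equal(screen_sequence(rand_dna(150), 0, 150), "pass")
  expect_equal(screen_sequence(strrep("ACGT", 50), 0, 150), "pass")
  # a short read containing an N is rejected as ambiguous first
  expect_equal(screen_sequence("ACGTN", 0, 150), "ambiguous")
  expect_equal(screen_sequence(paste0("ACGTN", rand_dna(200)), 1, 150), "pass")
})

test_that("homopolymer collapsing truncates long runs and is idempotent", {
  r <- collapse_homopolymers("AAAAAAAA", 6)
  expect_equal(r$sequence, "AAAAAA")
  expect_equal(nrow(r$events), 1)
  expect_equal(r$events$original_run, 8)
  expect_equal(r$events$collapsed_run, 6)

  r <- collapse_homopolymers("ACGT", 6)
  expect_equal(r$sequence, "ACGT")
  expect_equal(nrow(r$events), 0)

  expect_equal(collapse_homopolymers("AAATTTTTTTTGGC", 6)$sequence,
               "AAATTTTTTGGC")

  set.seed(21)
  for (i in 1:20) {
    # plant runs of random lengths between random spacers
    parts <- unlist(lapply(1:6, function(k)
      c(rand_dna(sample(1:5, 1)),
        strrep(sample(c("A", "C", "G", "T"), 1), sample(1:12, 1)))))
    seq <- paste(parts, collapse = "")
    limit <- sample(2:6, 1)
    out <- collapse_homopolymers(seq, limit)$sequence
    expect_false(grepl(sprintf("(.)\\1{%d,}", limit), out))
    expect_equal(collapse_homopolymers(out, limit)$sequence, out)
    # never lengthens, and runs at or below the limit are untouched
    expect_lte(nchar(out), nchar(seq))
  }
})

test_that("trimming recovers the exact target from a full-layout read", {
  target <- rand_dna(180)
  read <- build_read(target)
  tg <- assign_tags(read, make_tpa(), 0)
  pr <- detect_primers(read, FIX_FP, FIX_RP, "FP_AND_RP", 0,
                       fp_from = tg$fwd_hit$end, rp_window_extra = 31)
  tg2 <- assign_tags(read, make_tpa(), 0, rev_from = pr$rp_hit$end)
  tg$rev_hit <- tg2$rev_hit

  tr <- trim_read(read, tg, pr, FIX_ADAPTOR, "tags_and_primers")
  expect_equal(tr$sequence, target)

  # tags_only keeps the primers but strips both tags
  tr2 <- trim_read(read, tg, pr, FIX_ADAPTOR, "tags_only")
  expect_equal(tr2$sequence, paste0(FIX_FP, target, revcomp(FIX_RP)))
})

test_that("adaptor trimming removes exact and partial 3' adaptor sequence", {
  target <- rand_dna(120)
  base <- paste0(FIX_TAGS[["A"]], FIX_FP, target)
  no_hits <- list(fwd_hit = list(start = 0, end = 8), rev_hit = NULL)
  pr <- list(fp_hit = list(start = 8, end = 30), rp_hit = NULL)

  # read ends in the first 7 bases of the adaptor
  read <- paste0(base, substr(FIX_ADAPTOR, 1, 7))
  tr <- trim_read(read, no_hits, pr, FIX_ADAPTOR, "tags_and_primers",
                  trim_adaptor = TRUE, min_partial_overlap = 5)
  expect_equal(tr$sequence, target)

  # below the overlap floor the suffix is kept
  read4 <- paste0(base, substr(FIX_ADAPTOR, 1, 4))
  tr <- trim_read(read4, no_hits, pr, FIX_ADAPTOR, "tags_and_primers",
                  trim_adaptor = TRUE, min_partial_overlap = 5)
  expect_equal(tr$sequence, paste0(target, substr(FIX_ADAPTOR, 1, 4)))

  # a full internal adaptor occurrence truncates from its start
  read_full <- paste0(base, FIX_ADAPTOR, "AC")
  tr <- trim_read(read_full, no_hits, pr, FIX_ADAPTOR, "tags_and_primers")
  expect_equal(tr$sequence, target)

  # no adaptor present: unchanged
  tr <- trim_read(base, no_hits, pr, FIX_ADAPTOR, "tags_and_primers")
  expect_equal(tr$sequence, target)
})

test_that("dereplication conserves abundance and keeps first-seen reps", {
  recs <- seq_records(c("r1", "r2", "r3"), c("ACGTACGT", "ACGTACGT", "GGGGCCCC"))
  d <- dereplicate(recs)
  expect_equal(nrow(d$uniques), 2)
  expect_equal(d$uniques$unique_id, c("r1", "r3"))
  expect_equal(d$uniques$abundance, c(2L, 1L))

  distinct <- seq_records(paste0("u", 1:5),
                          vapply(rep(30, 5), rand_dna, character(1)))
  d <- dereplicate(distinct)
  expect_equal(d$uniques$abundance, rep(1L, 5))

  set.seed(31)
  templates <- vapply(rep(40, 10), rand_dna, character(1))
  draw <- sample(1:10, 1000, replace = TRUE)
  reads <- seq_records(sprintf("r%04d", 1:1000), templates[draw])
  d <- dereplicate(reads, samples = sprintf("s%d", draw %% 2))
  expect_equal(nrow(d$uniques), 10)
  expect_equal(sum(d$uniques$abundance), 1000)
  expect_equal(sort(d$uniques$abundance), sort(as.integer(table(draw))))
  expect_equal(sum(d$tallies$count), 1000)
})

test_that("the cascade accepts clean reads and accounts planted defects", {
  tpa <- make_tpa()
  set.seed(41)
  clean <- seq_records(sprintf("c%02d", 1:20),
                       vapply(1:20, function(i) build_read(rand_dna(200)),
                              character(1)))
  fr <- run_filter_step(clean, tpa, NULL, filter_params(dereplicate = FALSE))
  expect_equal(nrow(fr$accepted), 20)
  expect_true(all(fr$stats$rejected == 0))

  # 10 reads: 2 without tags, 1 with an N, under FP-only filtering
  seqs <- c(vapply(1:7, function(i) build_read(rand_dna(200)), character(1)),
            paste0(rand_dna(8), "CCCCGGGG", rand_dna(200)),          # no tag
            paste0("GTCAGTCA", rand_dna(208)),                       # no tag
            build_read(paste0(rand_dna(100), "N", rand_dna(100))))   # one N
  mixed <- seq_records(sprintf("m%02d", 1:10), seqs)
  fr <- run_filter_step(mixed, tpa, NULL,
                        filter_params(primer_mode = "FP_ONLY",
                                      dereplicate = FALSE))
  expect_equal(fr$stats$step[1:3], c("Tags", "Primers (FP)", "Ns"))
  expect_equal(fr$stats$considered[1:3], c(10L, 8L, 8L))
  expect_equal(fr$stats$rejected[1:3], c(2L, 0L, 1L))

  # a single tag-chimera read is caught only when both ends are assessed
  chim <- seq_records(
    sprintf("x%02d", 1:5),
    c(vapply(1:4, function(i) build_read(rand_dna(200)), character(1)),
      build_read(rand_dna(200), tag = FIX_TAGS[["A"]], tag3 = FIX_TAGS[["B"]])))
  fr <- run_filter_step(chim, tpa, NULL, filter_params(dereplicate = FALSE))
  expect_equal(sum(fr$rejected$reason == "incompatible_tags"), 1)
  expect_equal(fr$rejected$id, "x05")
  fr2 <- run_filter_step(chim, tpa, NULL,
                         filter_params(primer_mode = "FP_ONLY",
                                       dereplicate = FALSE))
  expect_equal(nrow(fr2$accepted), 5)
  expect_false("Incompatible tags combination" %in% fr2$stats$step)
})

test_that("cascade rows always chain and conserve counts", {
  tpa <- make_tpa()
  cfgs <- list(filter_params(),
               filter_params(primer_mode = "FP_ONLY"),
               filter_params(dereplicate = FALSE, homopolymer_limit = 6),
               filter_params(max_edits_tag = 1, max_edits_primer = 2))
  set.seed(51)
  seqs <- c(vapply(1:15, function(i) build_read(rand_dna(sample(120:220, 1))),
                   character(1)),
            paste0(rand_dna(30)),                              # garbage
            build_read(rand_dna(40)),                          # too short
            build_read(paste0("NN", rand_dna(200))),           # ambiguous
            paste0(FIX_TAGS[["B"]], FIX_FP, rand_dna(180)),    # truncated
            build_read(rand_dna(200), tag = FIX_TAGS[["C"]],
                       tag3 = FIX_TAGS[["D"]]))                # chimera
  recs <- seq_records(sprintf("r%02d", seq_along(seqs)), seqs)
  for (params in cfgs) {
    fr <- run_filter_step(recs, tpa, NULL, params)
    s <- fr$stats
    expect_equal(s$considered, s$accepted + s$rejected)
    if (nrow(s) > 1)
      expect_equal(s$considered[-1], s$accepted[-nrow(s)])
    expect_equal(nrow(fr$accepted) + nrow(fr$rejected), nrow(recs))
    expect_equal(s$accepted[nrow(s)], nrow(fr$accepted))
  }

  # empty input: zero-count stats, no error
  fr0 <- run_filter_step(recs[0, ], tpa, NULL, filter_params())
  expect_equal(nrow(fr0$accepted), 0)
  expect_true(all(fr0$stats$considered == 0))
})

test_that("mismatch allowance and FP-only mode are monotone in acceptance", {
  tpa <- make_tpa()
  set.seed(61)
  # reads with 0-3 substitutions scattered over the whole read
  seqs <- vapply(1:40, function(i) {
    r <- build_read(rand_dna(sample(160:240, 1)),
                    tag = FIX_TAGS[[sample(4, 1)]],
                    tag3 = FIX_TAGS[[sample(4, 1)]])
    mutate_subs(r, sample(0:3, 1))
  }, character(1))
  recs <- seq_records(sprintf("n%02d", 1:40), seqs)
  counts <- sapply(c(0, 1, 2), function(me) {
    fr <- run_filter_step(recs, tpa, NULL,
                          filter_params(max_edits_primer = me,
                                        max_edits_tag = me,
                                        dereplicate = FALSE))
    nrow(fr$accepted)
  })
  expect_true(all(diff(counts) >= 0))

  fr_both <- run_filter_step(recs, tpa, NULL,
                             filter_params(dereplicate = FALSE))
  fr_fp <- run_filter_step(recs, tpa, NULL,
                           filter_params(primer_mode = "FP_ONLY",
                                         dereplicate = FALSE))
  expect_true(all(fr_both$accepted$id %in% fr_fp$accepted$id))
})
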