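# 13-column BLAST tabular rows built in code.
blast_row <- function(q, s, evalue, bits, desc = "", pident = 97.5, len = 200) {
  paste(q, s, pident, len, 3, 1, 1, len, 1, len,
        format(evalue, scientific = TRUE), bits, desc, sep = "\t")
}

write_blast_fixture <- function(rows) {
  p <- tempfile(fileext = ".txt")
  writeLines(rows, p)
  p
}

test_that("tabular parsing applies E-value and per-query caps in order", {
  p <- write_blast_fixture(c(
    blast_row("q1", "sub1", 1e-50, 500, "Fusarium oxysporum strain Y"),
    blast_row("q1", "sub2", 1e-3, 100, "Cortinarius sp."),
    blast_row("q1", "sub3", 5, 40, "junk hit")))
  hits <- parse_blast_tabular(p, e_value_max = 1e-2)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$subject_id, c("sub1", "sub2"))
  expect_equal(hits$percent_identity, rep(0.975, 2))

  # empty file parses to an empty frame
  p0 <- tempfile(); file.create(p0)
  expect_equal(nrow(parse_blast_tabular(p0)), 0)

  # 10 rows across 4 queries capped at 2 per query, best first
  rows <- unlist(lapply(1:4, function(q)
    vapply(1:c(4, 3, 2, 1)[q], function(i)
      blast_row(paste0("q", q), sprintf("s%d_%d", q, i), 10^-(20 - i), 100 + i),
      character(1))))
  hits <- parse_blast_tabular(write_blast_fixture(rows), 1, max_descriptions = 2)
  expect_true(all(table(hits$query_id) <= 2))
  h1 <- hits[hits$query_id == "q1", ]
  expect_equal(h1$e_value, sort(h1$e_value))

  # 12-column rows (no subject title) are accepted
  p12 <- write_blast_fixture(paste(
    "q1", "s1", 98, 150, 2, 0, 1, 150, 1, 150, "1e-40", 280, sep = "\t"))
  hits <- parse_blast_tabular(p12)
  expect_equal(hits$subject_description, "")

  expect_error(parse_blast_tabular(write_blast_fixture("q1\tonly\tthree")),
               "line 1")
  expect_error(parse_blast_tabular(write_blast_fixture(
    paste("q1", "s1", "NA%", 150, 2, 0, 1, 150, 1, 150, "xx", 280, sep = "\t"))),
    "line 1")
})

test_that("uncultured-keyword filtering removes uninformative subjects", {
  p <- write_blast_fixture(c(
    blast_row("q1", "s1", 1e-50, 500, "Uncultured fungus clone X"),
    blast_row("q1", "s2", 1e-40, 400, "Fusarium oxysporum strain Y"),
    blast_row("q2", "s3", 1e-30, 300, "uncultured environmental sample"),
    blast_row("q2", "s4", 1e-20, 200, "Amanita muscaria"),
    blast_row("q3", "s5", 1e-10, 100, "Cortinarius croceus")))
  hits <- parse_blast_tabular(p)
  fu <- filter_uncultured(hits)
  expect_equal(fu$n_removed, 2)
  expect_equal(nrow(fu$hits), 3)
  expect_false(any(grepl("[Uu]ncultured", fu$hits$subject_description)))

  # filtering order invariance: E-value cut then keyword cut commutes
  loose <- parse_blast_tabular(p, e_value_max = 1)
  a <- filter_uncultured(loose)$hits
  a <- a[a$e_value <= 1e-3, ]
  b <- filter_uncultured(loose[loose$e_value <= 1e-3, ])$hits
  expect_equal(a, b)
})

test_that("top-hit selection breaks ties by bit score and handles no-hits", {
  otus <- data.frame(otu_index = 1:3,
                     representative_id = c("q1", "q2", "q3"),
                     stringsAsFactors = FALSE)
  p <- write_blast_fixture(c(
    blast_row("q1", "weak", 1e-10, 100, "weak hit"),
    blast_row("q1", "strong", 1e-80, 300, "strong hit"),
    blast_row("q2", "tieA", 1e-30, 180, "tie low bits"),
    blast_row("q2", "tieB", 1e-30, 200, "tie high bits")))
  hits <- parse_blast_tabular(p, e_value_max = 1)
  ann <- select_top_hits(hits, otus)
  expect_equal(ann$subject_id[1], "strong")
  expect_equal(ann$subject_id[2], "tieB")
  expect_false(ann$has_hit[3])
  expect_equal(ann$n_hits_reported, c(2L, 2L, 0L))
})

test_that("best-hit sharing statistics count subject multiplicity", {
  ann <- data.frame(otu_index = 1:3, has_hit = TRUE,
                    subject_id = c("X", "X", "Y"), stringsAsFactors = FALSE)
  st <- hit_overlap_stats(ann)
  expect_equal(st$n_otus_with_hit, 3L)
  expect_equal(st$n_distinct_best_subjects, 2L)
  expect_equal(st$max_otus_sharing_one_subject, 2L)
  expect_equal(st$per_subject$subject_id[1], "X")

  ann2 <- data.frame(otu_index = 1:3, has_hit = TRUE,
                     subject_id = c("X", "Y", "Z"), stringsAsFactors = FALSE)
  expect_equal(hit_overlap_stats(ann2)$max_otus_sharing_one_subject, 1L)

  none <- data.frame(otu_index = 1:2, has_hit = FALSE,
                     subject_id = NA_character_, stringsAsFactors = FALSE)
  st0 <- hit_overlap_stats(none)
  expect_equal(st0$n_otus_with_hit, 0L)
  expect_equal(st0$n_distinct_best_subjects, 0L)
  expect_equal(st0$max_otus_sharing_one_subject, 0L)
})

test_that("matrix annotation appends a top-hit column, numbers unchanged", {
  reads <- seq_records(paste0("r", 1:6),
                       rep(c(strrep("ACGT", 40), strrep("GGTA", 40),
                             strrep("CATG", 40)), 2))
  d <- dereplicate(reads, samples = rep(c("s1", "s2"), 3))
  ol <- order_and_label(
    cluster_single_linkage(seq_records(d$uniques$unique_id, d$uniques$sequence),
                           cluster_params()), d)
  m <- build_otu_matrix(ol$clustering, d)
  otus <- data.frame(
    otu_index = vapply(ol$clustering$clusters, `[[`, integer(1), "index"),
    representative_id = vapply(ol$clustering$clusters, `[[`, character(1),
                               "representative_id"))
  p <- write_blast_fixture(blast_row(otus$representative_id[1], "sub1", 1e-42,
                                     333, "Russula sp."))
  ann <- select_top_hits(parse_blast_tabular(p), otus)
  ext <- annotate_matrix(m, ann)
  expect_equal(ext$top_hit[1], "sub1 Russula sp. (evalue=1e-42)")
  expect_true(all(ext$top_hit[-1] == "no_hit"))
  base <- as.data.frame(m)
  expect_equal(ext[names(base)], base)
})

test_that("the external blastn wrapper produces parseable output", {
  # tiny database and queries, run through the real blastn binary
  set.seed(71)
  db_seqs <- seq_records(paste0("ref", 1:5),
                         vapply(rep(300, 5), rand_dna, character(1)))
  d <- tempfile(); dir.create(d)
  dbf <- file.path(d, "db.fas")
  write_fasta(db_seqs, dbf)
  status <- system2("makeblastdb",
                    c("-in", dbf, "-dbtype", "nucl", "-out",
                      file.path(d, "refdb")),
                    stdout = TRUE, stderr = TRUE)
  queries <- seq_records(c("q1", "q2", "q3"),
                         c(substr(db_seqs$sequence[1], 1, 200),
                           mutate_subs(db_seqs$sequence[2], 5),
                           rand_dna(250)))
  qf <- file.path(d, "q.fas")
  write_fasta(queries, qf)
  outf <- file.path(d, "blastout.txt")
  run_blastn_external(qf, file.path(d, "refdb"), outf, e_value = 1e-5)
  hits <- parse_blast_tabular(outf, e_value_max = 1e-5)
  expect_true(all(c("q1", "q2") %in% hits$query_id))
  ann <- select_top_hits(hits, data.frame(otu_index = 1:3,
                                          representative_id = c("q1", "q2", "q3")))
  expect_equal(ann$subject_id[1:2], c("ref1", "ref2"))
})
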