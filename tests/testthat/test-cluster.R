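# Build a triple of equal-length sequences with pairwise identities
# A~B = 0.98, B~C = 0.98, A~C = 0.96 (identities verified by construction:
# substitutions at disjoint positions of a 100-mer).
make_chain_triple <- function() {
  set.seed(17)
  a <- rand_dna(100)
  chars <- strsplit(a, "")[[1]]
  flip <- function(chars, pos) {
    for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    chars
  }
  b <- paste(flip(chars, c(10, 30)), collapse = "")
  c <- paste(flip(strsplit(b, "")[[1]], c(50, 70)), collapse = "")
  seq_records(c("otuA", "otuB", "otuC"), c(a, b, c))
}

test_that("single linkage groups by transitivity of the similarity graph", {
  recs <- make_chain_triple()
  s_ab <- pairwise_similarity(recs$sequence[1], recs$sequence[2])
  s_bc <- pairwise_similarity(recs$sequence[2], recs$sequence[3])
  s_ac <- pairwise_similarity(recs$sequence[1], recs$sequence[3])
  expect_equal(s_ab$identity, 0.98)
  expect_equal(s_bc$identity, 0.98)
  expect_equal(s_ac$identity, 0.96)

  raw <- cluster_single_linkage(recs, cluster_params(identity_threshold = 0.97))
  expect_equal(clusters_as_partition(raw), list(c("otuA", "otuB", "otuC")))

  # at 0.99 nothing joins
  raw99 <- cluster_single_linkage(recs, cluster_params(identity_threshold = 0.99))
  expect_length(raw99$clusters, 3)

  # n identical sequences form one cluster
  same <- seq_records(paste0("i", 1:6), rep(strrep("ACGGT", 30), 6))
  expect_length(cluster_single_linkage(same, cluster_params())$clusters, 1)
})

test_that("greedy clustering refines the chain that single linkage merges", {
  recs <- make_chain_triple()
  raw <- cluster_greedy(recs, cluster_params(method = "greedy",
                                             identity_threshold = 0.97))
  expect_equal(clusters_as_partition(raw),
               list(c("otuA", "otuB"), "otuC"))

  same <- seq_records(paste0("i", 1:4), rep(strrep("ACGGT", 30), 4))
  expect_length(cluster_greedy(same, cluster_params(method = "greedy"))$clusters, 1)

  distinct <- seq_records(paste0("d", 1:5),
                          vapply(rep(60, 5), rand_dna, character(1)))
  raw100 <- cluster_greedy(distinct,
                           cluster_params(method = "greedy",
                                          identity_threshold = 1,
                                          coverage_threshold = 1))
  expect_length(raw100$clusters, 5)
})

test_that("representatives are the longest members, ties by smallest id", {
  recs <- seq_records(c("zed", "abc", "mmm"),
                      c(strrep("ACGT", 20), strrep("ACGT", 20),
                        paste0(strrep("ACGT", 20), "ACGTA")))
  raw <- cluster_single_linkage(recs, cluster_params(identity_threshold = 0.9))
  expect_length(raw$clusters, 1)
  expect_equal(raw$clusters[[1]]$representative_id, "mmm")

  recs2 <- seq_records(c("zed", "abc"), rep(strrep("ACGT", 20), 2))
  raw2 <- cluster_single_linkage(recs2, cluster_params())
  expect_equal(raw2$clusters[[1]]$representative_id, "abc")
})

test_that("ordering folds duplicates, sorts by abundance, splits singletons", {
  seqs <- c(a1 = strrep("AAAC", 30), b1 = strrep("GGGT", 30),
            c1 = strrep("CCAT", 30))
  recs <- seq_records(names(seqs), unname(seqs))
  # abundances via a dereplication table: a1 x5, b1 x9, c1 x1
  reads <- seq_records(sprintf("r%02d", 1:15),
                       c(rep(seqs[["a1"]], 5), rep(seqs[["b1"]], 9), seqs[["c1"]]))
  d <- dereplicate(reads)
  raw <- cluster_single_linkage(d$uniques |>
                                  (\(u) seq_records(u$unique_id, u$sequence))(),
                                cluster_params())
  ol <- order_and_label(raw, d)
  ab <- vapply(ol$clustering$clusters, `[[`, integer(1), "total_abundance")
  expect_equal(ab, c(9L, 5L, 1L))
  expect_equal(vapply(ol$clustering$clusters, `[[`, integer(1), "index"), 1:3)
  expect_length(ol$singletons, 0)

  ol2 <- order_and_label(raw, d, exclude_singletons = TRUE)
  expect_length(ol2$clustering$clusters, 2)
  expect_equal(vapply(ol2$clustering$clusters, `[[`, integer(1), "index"), 1:2)
  expect_equal(ol2$singletons, "r15")

  # abundance ties order by representative id
  tie <- seq_records(c("otuB", "otuA"),
                     c(rand_dna(80), rand_dna(80)))
  raw_t <- cluster_single_linkage(tie, cluster_params())
  ol_t <- order_and_label(raw_t, NULL)
  expect_equal(vapply(ol_t$clustering$clusters, `[[`, character(1),
                      "representative_id"), c("otuA", "otuB"))
})

test_that("the OTU matrix reports unique and total counts per sample", {
  # one cluster, one sample, one unique seen three times
  reads <- seq_records(c("r1", "r2", "r3"), rep(strrep("ACGT", 40), 3))
  d <- dereplicate(reads, samples = rep("soil1", 3))
  raw <- cluster_single_linkage(seq_records("r1", strrep("ACGT", 40)),
                                cluster_params())
  m <- build_otu_matrix(order_and_label(raw, d)$clustering, d)
  expect_equal(m$unique_counts["OTU_1", "soil1"], 1L)
  expect_equal(m$total_counts["OTU_1", "soil1"], 3L)

  # a sample with no accepted reads still gets an all-zero column
  smap <- sample_map(data.frame(file = c("f", "f"), tag = c("A", "B"),
                                sample = c("soil1", "empty")))
  m2 <- build_otu_matrix(order_and_label(raw, d)$clustering, d, smap)
  expect_true("empty" %in% m2$samples)
  expect_equal(sum(m2$total_counts[, "empty"]), 0L)
})

test_that("matrix invariants hold on a simulated multi-sample run", {
  cfg <- simulation_config(n_templates = 6, samples = sprintf("s%d", 1:4),
                           reads_per_sample = 60, seed = 23)
  comm <- generate_community(cfg)
  sim <- simulate_reads(comm$templates, comm$tpa, cfg)
  fr <- run_filter_step(sim$reads, comm$tpa, sim$sample_map, filter_params())
  ol <- order_and_label(cluster_single_linkage(fr$accepted, cluster_params()),
                        fr$derep)
  m <- build_otu_matrix(ol$clustering, fr$derep, sim$sample_map)
  ab <- vapply(ol$clustering$clusters, `[[`, integer(1), "total_abundance")
  expect_equal(unname(rowSums(m$total_counts)), ab)
  per_sample <- tapply(fr$derep$tallies$count, fr$derep$tallies$sample, sum)
  expect_equal(unname(colSums(m$total_counts)[names(per_sample)]),
               as.vector(per_sample))
  expect_equal(sum(m$unique_counts), nrow(fr$accepted))
})

test_that("cluster reports round-trip counts and one FASTA per cluster", {
  cfg <- simulation_config(n_templates = 4, samples = c("sA", "sB"),
                           reads_per_sample = 30, seed = 29)
  comm <- generate_community(cfg)
  sim <- simulate_reads(comm$templates, comm$tpa, cfg)
  fr <- run_filter_step(sim$reads, comm$tpa, sim$sample_map, filter_params())
  ol <- order_and_label(cluster_single_linkage(fr$accepted, cluster_params()),
                        fr$derep)
  m <- build_otu_matrix(ol$clustering, fr$derep, sim$sample_map)
  out <- tempfile()
  files <- write_cluster_reports(ol$clustering, m, fr$accepted, out)
  expect_true(all(file.exists(files)))

  reps <- read_fasta(file.path(out, "cluster_out.fas"))
  expect_equal(nrow(reps), length(ol$clustering$clusters))
  expect_match(reps$id[1], "^OTU_1_size_\\d+$")

  info <- read.delim(file.path(out, "cluster_info.txt"), comment.char = "#")
  expect_equal(sum(info$total_abundance), sum(sim$abundance))

  members <- unzip(file.path(out, "SeqInEachCluster.zip"),
                   exdir = tempfile())
  expect_length(members, length(ol$clustering$clusters))
  expect_setequal(basename(members),
                  sprintf("OTU_%d.fas", seq_along(ol$clustering$clusters)))
  # per-cluster FASTA member counts sum to the unique sequence count
  n_members <- sum(vapply(members, function(f) nrow(read_fasta(f)), integer(1)))
  expect_equal(n_members, nrow(fr$accepted))
})
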