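# Step 2: OTU construction. Two de novo algorithms over the same
# identity/coverage measure: single-linkage (clusters are the connected
# components of the thresholded similarity graph, BLASTCLUST-style) and
# greedy incremental (length-sorted reads join the earliest-seeded
# sufficiently similar representative, CD-HIT-style). Clusters are ordered
# by duplicate-inclusive abundance, singletons optionally split out, and an
# OTU-by-sample matrix derived.

#' Clustering parameters
#'
#' @param method `"single_linkage"` or `"greedy"`.
#' @param identity_threshold minimum pairwise identity in `(0, 1]`
#'   (e.g. 0.97).
#' @param coverage_threshold minimum pairwise coverage of the shorter
#'   sequence in `(0, 1]` (e.g. 0.50).
#' @param exclude_singletons drop clusters of total abundance one and report
#'   them separately.
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(method = c("single_linkage", "greedy"),
                           identity_threshold = 0.97,
                           coverage_threshold = 0.50,
                           exclude_singletons = FALSE) {
  method <- match.arg(method)
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      coverage_threshold <= 0 || coverage_threshold > 1)
    stop("identity_threshold and coverage_threshold must lie in (0, 1]")
  structure(list(method = method,
                 identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 exclude_singletons = isTRUE(exclude_singletons)),
            class = "cluster_params")
}

# Deterministic raw-cluster construction from a member partition:
# members sorted by length desc then id; representative = longest member,
# ties towards the lexicographically smallest id.
raw_clusters_from_partition <- function(groups, records, method, params,
                                        reps = NULL) {
  len <- setNames(nchar(records$sequence), records$id)
  clusters <- lapply(seq_along(groups), function(k) {
    ids <- groups[[k]]
    ids <- ids[order(-len[ids], ids)]
    list(member_ids = ids,
         representative_id = if (is.null(reps)) ids[1] else reps[k])
  })
  # deterministic raw ordering: size desc, then representative id
  sizes <- vapply(clusters, function(cl) length(cl$member_ids), integer(1))
  repid <- vapply(clusters, `[[`, character(1), "representative_id")
  clusters <- clusters[order(-sizes, repid)]
  structure(list(clusters = clusters, method = method, params = params),
            class = "raw_clusters")
}

#' Single-linkage OTU clustering
#'
#' Builds the graph with an edge between every pair of reads whose
#' similarity satisfies both thresholds, and returns its connected
#' components; a pair in the same cluster need not itself be similar
#' (transitivity).
#'
#' @param records a [seq_records] data frame (normally dereplicated unique
#'   reads).
#' @param params a [cluster_params] list.
#' @return an object of class `raw_clusters`; pass to [order_and_label()].
#' @export
cluster_single_linkage <- function(records, params = cluster_params()) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  n <- nrow(records)
  sim <- cpp_similarity_matrix(toupper(records$sequence))
  adj <- (sim$identity >= params$identity_threshold) &
    (sim$coverage >= params$coverage_threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(records$id, comp)
  raw_clusters_from_partition(groups, records, "single_linkage", params)
}

#' Greedy incremental OTU clustering
#'
#' Reads are processed by decreasing length (ties by id); the first seeds
#' cluster 1, and each subsequent read joins the earliest-seeded cluster
#' whose seed it matches at both thresholds, otherwise it seeds a new
#' cluster. Each cluster's representative is its seed (the longest member
#' by construction). Greedy clusters always refine the single-linkage
#' partition at equal thresholds, so the greedy cluster count is at least
#' the single-linkage count.
#'
#' @inheritParams cluster_single_linkage
#' @return an object of class `raw_clusters`; pass to [order_and_label()].
#' @export
cluster_greedy <- function(records, params = cluster_params(method = "greedy")) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  ord <- order(-nchar(records$sequence), records$id)
  ids <- records$id[ord]
  seqs <- toupper(records$sequence[ord])
  seed_seq <- character(0)
  groups <- list()
  for (i in seq_along(ids)) {
    joined <- FALSE
    for (k in seq_along(seed_seq)) {
      s <- pairwise_similarity(seqs[i], seed_seq[k])
      if (s$identity >= params$identity_threshold &&
          s$coverage >= params$coverage_threshold) {
        groups[[k]] <- c(groups[[k]], ids[i])
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      groups[[length(groups) + 1]] <- ids[i]
      seed_seq <- c(seed_seq, seqs[i])
    }
  }
  reps <- vapply(groups, `[[`, character(1), 1)  # seeds
  raw_clusters_from_partition(groups, records, "greedy", params, reps = reps)
}

#' Order, number and optionally de-singleton clusters
#'
#' Duplicate-inclusive abundances are computed by folding each unique read's
#' duplicates (from the dereplication table) into its cluster; clusters are
#' then sorted by total abundance (descending, ties by representative id)
#' and numbered from 1. When singletons (total abundance one) are excluded
#' they are split out and the remaining clusters renumbered.
#'
#' @param raw a `raw_clusters` object from either clustering function.
#' @param derep a [dereplicate()] table, or `NULL` (every read then counts
#'   once).
#' @param exclude_singletons overrides the flag in the raw object's params
#'   when not `NULL`.
#' @return list with `clustering` (class `otu_clustering`: `clusters`, each
#'   with `index`, `member_ids`, `representative_id`, `unique_size`,
#'   `total_abundance`; plus `method` and `params`) and `singletons`
#'   (character vector of singleton member ids).
#' @export
order_and_label <- function(raw, derep = NULL, exclude_singletons = NULL) {
  stopifnot(inherits(raw, "raw_clusters"))
  excl <- exclude_singletons %||% raw$params$exclude_singletons
  ab <- function(ids) {
    if (is.null(derep)) length(ids)
    else sum(derep$uniques$abundance[match(ids, derep$uniques$unique_id)])
  }
  clusters <- lapply(raw$clusters, function(cl) {
    cl$unique_size <- length(cl$member_ids)
    cl$total_abundance <- as.integer(ab(cl$member_ids))
    cl
  })
  repid <- vapply(clusters, `[[`, character(1), "representative_id")
  abund <- vapply(clusters, `[[`, integer(1), "total_abundance")
  clusters <- clusters[order(-abund, repid)]
  singleton <- vapply(clusters, function(cl) cl$total_abundance == 1L,
                      logical(1))
  singleton_ids <- unlist(lapply(clusters[singleton & excl], `[[`,
                                 "member_ids"))
  if (excl) clusters <- clusters[!singleton]
  for (i in seq_along(clusters)) clusters[[i]]$index <- i
  structure_out <- structure(list(clusters = clusters, method = raw$method,
                                  params = raw$params),
                             class = "otu_clustering")
  list(clustering = structure_out,
       singletons = as.character(singleton_ids %||% character(0)))
}

#' @export
print.otu_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, `[[`, integer(1), "total_abundance")
  cat(sprintf("OTU clustering (%s, identity >= %.2f, coverage >= %.2f): %d clusters\n",
              x$method, x$params$identity_threshold,
              x$params$coverage_threshold, length(x$clusters)))
  if (length(sizes))
    cat(sprintf("  total abundance %d, largest cluster %d\n",
                sum(sizes), max(sizes)))
  invisible(x)
}

#' Build the OTU-by-sample abundance matrix
#'
#' For each cluster and sample, the matrix reports the number of unique
#' reads whose representative came from that sample and the total read
#' count including duplicates (folded in through the dereplication
#' tallies). Row sums of the total counts equal cluster abundances; column
#' sums equal per-sample accepted read counts.
#'
#' @param clustering an `otu_clustering` from [order_and_label()].
#' @param derep a [dereplicate()] table, or `NULL`.
#' @param sample_map optional [sample_map] whose samples define the column
#'   set (samples with no accepted reads appear as all-zero columns).
#' @return an object of class `otu_matrix`: list with integer matrices
#'   `unique_counts` and `total_counts` (rows `OTU_<index>`, columns
#'   samples) and the `samples` vector.
#' @export
build_otu_matrix <- function(clustering, derep = NULL, sample_map = NULL) {
  stopifnot(inherits(clustering, "otu_clustering"))
  uniques <- if (!is.null(derep)) derep$uniques else NULL
  member_ids <- unlist(lapply(clustering$clusters, `[[`, "member_ids"))
  samples <- character(0)
  if (!is.null(derep)) samples <- unique(derep$tallies$sample)
  if (!is.null(sample_map)) samples <- union(samples, sample_map$entries$sample)
  if (is.null(derep) || length(samples) == 0)
    samples <- union(samples, "unassigned")
  samples <- sort(samples)
  k <- length(clustering$clusters)
  u <- matrix(0L, nrow = k, ncol = length(samples),
              dimnames = list(paste0("OTU_", seq_len(k)), samples))
  tot <- u
  for (i in seq_len(k)) {
    ids <- clustering$clusters[[i]]$member_ids
    if (is.null(derep)) {
      # without dereplication info every member counts once in "unassigned"
      u[i, "unassigned"] <- length(ids)
      tot[i, "unassigned"] <- length(ids)
    } else {
      rep_samples <- uniques$sample[match(ids, uniques$unique_id)]
      tu <- table(factor(rep_samples, levels = samples))
      u[i, ] <- as.integer(tu)
      tal <- derep$tallies[derep$tallies$unique_id %in% ids, ]
      tt <- tapply(tal$count, factor(tal$sample, levels = samples), sum,
                   default = 0L)
      tot[i, ] <- as.integer(tt)
    }
  }
  structure(list(unique_counts = u, total_counts = tot, samples = samples),
            class = "otu_matrix")
}

#' Render an OTU matrix as a data frame
#'
#' One row per OTU with a `<sample>_unique` and `<sample>_total` column
#' pair per sample; this is the layout written to `matrix_table_1.tsv`.
#'
#' @param x an `otu_matrix`.
#' @param ... unused.
#' @return a data frame.
#' @method as.data.frame otu_matrix
#' @export
as.data.frame.otu_matrix <- function(x, ...) {
  out <- data.frame(otu = rownames(x$unique_counts),
                    stringsAsFactors = FALSE)
  for (s in x$samples) {
    out[[paste0(s, "_unique")]] <- x$unique_counts[, s]
    out[[paste0(s, "_total")]] <- x$total_counts[, s]
  }
  rownames(out) <- NULL
  out
}

#' Write the clustering report files
#'
#' Writes `cluster_out.fas` (one representative per cluster, headers
#' `OTU_<index>_size_<total_abundance>`), `cluster_info.txt` (per-cluster
#' sizes plus whole-dataset totals, tab-separated), `matrix_table_1.tsv`,
#' and `SeqInEachCluster.zip` containing one FASTA per cluster
#' (`OTU_<index>.fas`).
#'
#' @param clustering an `otu_clustering`.
#' @param matrix an `otu_matrix` (or `NULL` to skip `matrix_table_1.tsv`).
#' @param records a [seq_records] frame resolving member ids to sequences.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_cluster_reports <- function(clustering, matrix, records, out_dir) {
  stopifnot(inherits(clustering, "otu_clustering"), is.data.frame(records))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seq_of <- setNames(records$sequence, records$id)
  k <- length(clustering$clusters)

  reps <- vapply(clustering$clusters, `[[`, character(1), "representative_id")
  sizes <- vapply(clustering$clusters, `[[`, integer(1), "total_abundance")
  usizes <- vapply(clustering$clusters, `[[`, integer(1), "unique_size")
  rep_recs <- seq_records(sprintf("OTU_%d_size_%d", seq_len(k), sizes),
                          unname(seq_of[reps]),
                          description = reps)
  out_fas <- file.path(out_dir, "cluster_out.fas")
  write_fasta(rep_recs, out_fas)

  info <- file.path(out_dir, "cluster_info.txt")
  info_df <- data.frame(otu = paste0("OTU_", seq_len(k)),
                        representative = reps, unique_size = usizes,
                        total_abundance = sizes, stringsAsFactors = FALSE)
  con <- file(info, "w")
  writeLines(sprintf("# clusters\t%d", k), con)
  writeLines(sprintf("# unique sequences\t%d", sum(usizes)), con)
  writeLines(sprintf("# total abundance\t%d", sum(sizes)), con)
  write.table(info_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  files <- c(cluster_out = out_fas, cluster_info = info)

  if (!is.null(matrix)) {
    mt <- file.path(out_dir, "matrix_table_1.tsv")
    write.table(as.data.frame(matrix), mt, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, matrix_table_1 = mt)
  }

  tmp <- tempfile("clusters")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  member_files <- character(k)
  for (i in seq_len(k)) {
    ids <- clustering$clusters[[i]]$member_ids
    member_files[i] <- file.path(tmp, sprintf("OTU_%d.fas", i))
    write_fasta(seq_records(ids, unname(seq_of[ids])), member_files[i])
  }
  zip_path <- file.path(out_dir, "SeqInEachCluster.zip")
  if (k > 0) {
    write_zip_store(setNames(member_files, basename(member_files)), zip_path)
    files <- c(files, seq_in_each_cluster = zip_path)
  }
  invisible(files)
}
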