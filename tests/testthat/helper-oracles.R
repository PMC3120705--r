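# Independent oracles used to verify the package's alignment and clustering
# code. These deliberately avoid the package's own DP kernels: edit
# distances come from base R's adist() (generalised Levenshtein), motif
# search from exhaustive substring enumeration, and connected components
# from a hand-rolled breadth-first search.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

lev_oracle <- function(a, b) drop(adist(a, b))

# Exhaustive approximate motif search: minimum edit distance between the
# motif and any substring of the window; ties towards the smallest start,
# then smallest end. Plain ACGT motifs only.
brute_find_motif <- function(read, motif, max_edits, window = NULL,
                             anchored = FALSE) {
  n <- nchar(read)
  if (is.null(window)) window <- c(0L, n)
  text <- substr(read, window[1] + 1, window[2])
  m <- nchar(text)
  best <- NULL
  starts <- if (anchored) 0L else 0:(m - 1)
  for (s in starts) {
    for (e in s:m) {
      sub <- substr(text, s + 1, e)
      d <- if (nzchar(sub)) lev_oracle(sub, motif) else nchar(motif)
      if (is.null(best) || d < best$edits) {
        best <- list(start = window[1] + s, end = window[1] + e, edits = d)
      }
    }
  }
  if (best$edits > max_edits) NULL else best
}

# Connected components by BFS over an explicit adjacency matrix.
components_oracle <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Brute-force single-linkage partition at the given thresholds, with the
# edge predicate evaluated pair by pair through pairwise_similarity().
brute_single_linkage <- function(seqs, ids, identity, coverage) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { adj[i, j] <- TRUE; next }
      if (j < i) { adj[i, j] <- adj[j, i]; next }
      s <- pairwise_similarity(seqs[i], seqs[j])
      adj[i, j] <- s$identity >= identity && s$coverage >= coverage
    }
  }
  comp <- components_oracle(adj)
  unname(split(ids, comp))
}

# Canonical form of a partition: sorted list of sorted member vectors.
canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, character(1), 1))]
}

clusters_as_partition <- function(x) {
  groups <- if (inherits(x, "raw_clusters") || inherits(x, "otu_clustering"))
    lapply(x$clusters, `[[`, "member_ids") else x
  canonical_partition(groups)
}

# Random mutation helpers for constructing related sequences.
mutate_subs <- function(seq, k) {
  n <- nchar(seq)
  pos <- sample.int(n, min(k, n))
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}
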