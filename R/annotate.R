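# Step 3: taxonomic annotation bookkeeping. Parses BLAST tabular output for
# the OTU representatives, drops hits above the E-value threshold and
# (optionally) hits whose subject is only environmental material, selects
# the top hit per OTU, summarises how often different OTUs share a best
# database sequence, and extends the OTU-by-sample matrix with the top hit.

DEFAULT_UNCULTURED_KEYWORDS <- c("uncultured", "environmental sample",
                                 "unidentified")

#' Parse BLAST tabular output
#'
#' Reads the standard 12-column tabular format (`-outfmt 6`), optionally
#' with a 13th subject-title column (`stitle`). Hits with an E-value above
#' `e_value_max` are dropped, and at most `max_descriptions` hits are kept
#' per query, best first (ascending E-value, then descending bit score,
#' then file order).
#'
#' @param path path to the tabular file.
#' @param e_value_max E-value threshold (default `1e-3`).
#' @param max_descriptions maximum hits retained per query (default 10).
#' @return a data frame of hits with columns `query_id`, `subject_id`,
#'   `subject_description`, `percent_identity` (as a fraction in `[0, 1]`),
#'   `alignment_length`, `e_value`, `bit_score` and `line` (input line
#'   number, used for deterministic tie-breaking).
#' @export
parse_blast_tabular <- function(path, e_value_max = 1e-3,
                                max_descriptions = 10L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  stopifnot(e_value_max >= 0, max_descriptions >= 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(query_id = character(), subject_id = character(),
                      subject_description = character(),
                      percent_identity = numeric(),
                      alignment_length = integer(), e_value = numeric(),
                      bit_score = numeric(), line = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (!(length(f) %in% c(12L, 13L)))
      stop(sprintf("malformed BLAST tabular row at line %d: %d columns (expected 12 or 13)",
                   i, length(f)))
    num <- suppressWarnings(as.numeric(f[c(3, 4, 11, 12)]))
    if (anyNA(num))
      stop(sprintf("malformed BLAST tabular row at line %d: non-numeric pident/length/evalue/bitscore",
                   i))
    data.frame(query_id = f[1], subject_id = f[2],
               subject_description = if (length(f) == 13) f[13] else "",
               percent_identity = num[1] / 100,
               alignment_length = as.integer(num[2]),
               e_value = num[3], bit_score = num[4], line = i,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$e_value <= e_value_max, , drop = FALSE]
  hits <- hits[order(hits$query_id, hits$e_value, -hits$bit_score, hits$line), ]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id),
                        head, n = max_descriptions))
  hits <- hits[sort(as.integer(keep)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Remove uninformative environmental hits
#'
#' A hit is removed when its subject description contains any of the
#' keywords, case-insensitively. Database entries from environmental
#' surveys ("uncultured ... clone") carry no taxonomic information and can
#' drown out informative matches.
#'
#' @param hits a hit data frame from [parse_blast_tabular()].
#' @param keywords character vector of keywords (non-empty).
#' @return list with `hits` (the surviving rows), `removed` (the removed
#'   rows) and `n_removed`.
#' @export
filter_uncultured <- function(hits, keywords = DEFAULT_UNCULTURED_KEYWORDS) {
  stopifnot(is.data.frame(hits), length(keywords) >= 1)
  drop <- rep(FALSE, nrow(hits))
  for (kw in keywords)
    drop <- drop | grepl(kw, hits$subject_description, ignore.case = TRUE,
                         fixed = FALSE)
  list(hits = hits[!drop, , drop = FALSE],
       removed = hits[drop, , drop = FALSE],
       n_removed = sum(drop))
}

#' Select the top hit for each OTU
#'
#' The top hit per OTU representative is the surviving hit with the lowest
#' E-value (ties towards the highest bit score, then file order). OTUs
#' without a surviving hit are annotated with no hit. Singleton clusters,
#' when retained, are annotated identically to any other cluster.
#'
#' @param hits surviving hits (after E-value and any uncultured filtering).
#' @param otus either an `otu_clustering` or a data frame with columns
#'   `otu_index` and `representative_id`.
#' @param removed optionally the removed-hit data frame from
#'   [filter_uncultured()], used to report `n_uncultured_removed` per OTU.
#' @return a data frame with one row per OTU: `otu_index`, `query_id`,
#'   `has_hit`, `subject_id`, `subject_description`, `e_value`,
#'   `bit_score`, `n_hits_reported`, `n_uncultured_removed`.
#' @export
select_top_hits <- function(hits, otus, removed = NULL) {
  if (inherits(otus, "otu_clustering")) {
    otus <- data.frame(
      otu_index = vapply(otus$clusters, `[[`, integer(1), "index"),
      representative_id = vapply(otus$clusters, `[[`, character(1),
                                 "representative_id"),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("otu_index", "representative_id") %in% names(otus)))
  out <- lapply(seq_len(nrow(otus)), function(i) {
    q <- otus$representative_id[i]
    h <- hits[hits$query_id == q, , drop = FALSE]
    h <- h[order(h$e_value, -h$bit_score, h$line), , drop = FALSE]
    n_unc <- if (!is.null(removed)) sum(removed$query_id == q) else 0L
    if (nrow(h) == 0)
      data.frame(otu_index = otus$otu_index[i], query_id = q, has_hit = FALSE,
                 subject_id = NA_character_,
                 subject_description = NA_character_, e_value = NA_real_,
                 bit_score = NA_real_, n_hits_reported = 0L,
                 n_uncultured_removed = n_unc, stringsAsFactors = FALSE)
    else
      data.frame(otu_index = otus$otu_index[i], query_id = q, has_hit = TRUE,
                 subject_id = h$subject_id[1],
                 subject_description = h$subject_description[1],
                 e_value = h$e_value[1], bit_score = h$bit_score[1],
                 n_hits_reported = nrow(h), n_uncultured_removed = n_unc,
                 stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Best-hit sharing statistics
#'
#' Counts how many OTUs share the same best database sequence. Many OTUs
#' resolving to one reference sequence can indicate over-strict clustering
#' parameters.
#'
#' @param annotations data frame from [select_top_hits()].
#' @return list with `n_otus_with_hit`, `n_distinct_best_subjects`,
#'   `max_otus_sharing_one_subject` and `per_subject` (data frame of
#'   `subject_id`, `n_otus`, `otus`).
#' @export
hit_overlap_stats <- function(annotations) {
  withhit <- annotations[annotations$has_hit, , drop = FALSE]
  if (nrow(withhit) == 0)
    return(list(n_otus_with_hit = 0L, n_distinct_best_subjects = 0L,
                max_otus_sharing_one_subject = 0L,
                per_subject = data.frame(subject_id = character(),
                                         n_otus = integer(),
                                         otus = character(),
                                         stringsAsFactors = FALSE)))
  grp <- split(withhit$otu_index, withhit$subject_id)
  per <- data.frame(subject_id = names(grp),
                    n_otus = vapply(grp, length, integer(1)),
                    otus = vapply(grp, function(x)
                      paste(sort(x), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  per <- per[order(-per$n_otus, per$subject_id), ]
  rownames(per) <- NULL
  list(n_otus_with_hit = nrow(withhit),
       n_distinct_best_subjects = nrow(per),
       max_otus_sharing_one_subject = max(per$n_otus),
       per_subject = per)
}

#' Extend the OTU matrix with top BLAST hits
#'
#' Appends one `top_hit` column to the [as.data.frame.otu_matrix()] layout;
#' all numeric cells are unchanged. OTUs without a hit get `"no_hit"`.
#'
#' @param matrix an `otu_matrix`.
#' @param annotations data frame from [select_top_hits()]; its `otu_index`
#'   values must match the matrix rows.
#' @return the extended data frame (the `matrix_table_2.tsv` layout).
#' @export
annotate_matrix <- function(matrix, annotations) {
  stopifnot(inherits(matrix, "otu_matrix"))
  df <- as.data.frame(matrix)
  idx <- match(df$otu, paste0("OTU_", annotations$otu_index))
  if (anyNA(idx))
    stop("annotation OTU indices do not match the matrix rows")
  ann <- annotations[idx, ]
  df$top_hit <- ifelse(
    ann$has_hit,
    sprintf("%s %s (evalue=%g)", ann$subject_id,
            ifelse(nzchar(ann$subject_description) &
                     !is.na(ann$subject_description),
                   ann$subject_description, "-"),
            ann$e_value),
    "no_hit")
  df
}

#' Run blastn against a formatted database
#'
#' Thin wrapper over an external NCBI BLAST+ `blastn` executable producing
#' the 13-column tabular file consumed by [parse_blast_tabular()]. The rest
#' of the toolkit never requires this: a pre-computed tabular file can be
#' supplied instead.
#'
#' @param query_fasta FASTA of OTU representatives.
#' @param database path to a formatted BLAST database.
#' @param out output path for the tabular result.
#' @param e_value E-value cut-off forwarded to blastn.
#' @param max_descriptions forwarded as `-max_target_seqs`.
#' @return `out`, invisibly.
#' @export
run_blastn_external <- function(query_fasta, database, out,
                                e_value = 1e-3, max_descriptions = 10L) {
  exe <- Sys.which("blastn")
  if (!nzchar(exe))
    stop("blastn executable not found on PATH; run the annotation stage from ",
         "an existing BLAST tabular file instead (see parse_blast_tabular)")
  status <- system2(exe, c("-query", shQuote(query_fasta),
                           "-db", shQuote(database),
                           "-evalue", format(e_value),
                           "-max_target_seqs", max_descriptions,
                           "-outfmt", shQuote(paste(
                             "6 qseqid sseqid pident length mismatch gapopen",
                             "qstart qend sstart send evalue bitscore stitle")),
                           "-out", shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0)
    stop(sprintf("blastn failed (exit %d): %s", code,
                 paste(status, collapse = "\n")))
  invisible(out)
}
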