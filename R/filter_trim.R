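# Step 1 of the pipeline: the ordered quality filter cascade with per-step
# accounting, tag/primer location and trimming, homopolymer collapsing and
# dereplication with abundance tracking.
#
# Cascade order (one row per active filter, each row's considered count
# equal to the previous row's accepted count):
#   tags -> primers -> incompatible tags -> [trim + homopolymer collapse]
#   -> ambiguous bases (Ns) -> minimum length -> identical sequences

#' Filter cascade parameters
#'
#' @param primer_mode `"FP_AND_RP"` rejects reads lacking either primer
#'   (retains only fully sequenced amplicons); `"FP_ONLY"` requires just the
#'   forward primer, retaining partially sequenced fragments.
#' @param max_edits_tag,max_edits_primer mismatch allowance (edit distance,
#'   substitutions and indels) for tag and primer matching.
#' @param max_ambiguous maximum tolerated count of ambiguous (non-ACGT)
#'   bases in the trimmed read.
#' @param min_length minimum trimmed read length.
#' @param homopolymer_limit collapse single-base runs longer than this to
#'   exactly this length; `NULL` disables collapsing.
#' @param trim `"tags_and_primers"` leaves only the target region;
#'   `"tags_only"` removes just the terminal tags.
#' @param trim_adaptor remove exact or partial adaptor sequence at the 3'
#'   end of reads whose 3' side was not already cut at the reverse primer.
#' @param min_partial_overlap minimum length for a read suffix to be
#'   recognised as a partial adaptor prefix.
#' @param dereplicate remove exact duplicate trimmed sequences, keeping
#'   per-sample abundance tallies.
#' @param check_incompatible_tags reject reads whose 5' and 3' tags differ
#'   (applies only in `FP_AND_RP` mode, where the 3' end is assessed).
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(primer_mode = c("FP_AND_RP", "FP_ONLY"),
                          max_edits_tag = 0L, max_edits_primer = 0L,
                          max_ambiguous = 0L, min_length = 150L,
                          homopolymer_limit = NULL,
                          trim = c("tags_and_primers", "tags_only"),
                          trim_adaptor = TRUE, min_partial_overlap = 5L,
                          dereplicate = TRUE, check_incompatible_tags = TRUE) {
  primer_mode <- match.arg(primer_mode)
  trim <- match.arg(trim)
  if (min_length <= 0) stop("min_length must be positive")
  if (max_edits_tag < 0 || max_edits_primer < 0 || max_ambiguous < 0)
    stop("edit and ambiguity allowances must be non-negative")
  if (!is.null(homopolymer_limit) && homopolymer_limit < 2)
    stop("homopolymer_limit must be at least 2 (or NULL to disable)")
  structure(list(primer_mode = primer_mode,
                 max_edits_tag = as.integer(max_edits_tag),
                 max_edits_primer = as.integer(max_edits_primer),
                 max_ambiguous = as.integer(max_ambiguous),
                 min_length = as.integer(min_length),
                 homopolymer_limit = if (!is.null(homopolymer_limit)) as.integer(homopolymer_limit),
                 trim = trim, trim_adaptor = isTRUE(trim_adaptor),
                 min_partial_overlap = as.integer(min_partial_overlap),
                 dereplicate = isTRUE(dereplicate),
                 check_incompatible_tags = isTRUE(check_incompatible_tags)),
            class = "filter_params")
}

tag_table <- function(tags) {
  if (inherits(tags, "tpa_config")) tags$tags else tags
}

#' Assign sample tags to a read
#'
#' The forward tag is the tag with the fewest anchored edits at the read's
#' 5' terminus; a tie between distinct tags leaves the read unassigned (and
#' flagged ambiguous) rather than picking arbitrarily. When `rev_from` is
#' given, the reverse-complemented tags are searched anchored at that
#' position (normally the end of the reverse primer hit) for the 3' tag.
#'
#' @param sequence read sequence (a string).
#' @param tags a [tpa_config] or a data frame with `name` and `sequence`.
#' @param max_edits mismatch allowance for tag matching.
#' @param rev_from 0-based position where the 3' reverse-complement tag is
#'   expected to start, or `NULL` to skip the reverse-end search.
#' @return list with `fwd_tag`, `rev_tag` (names or `NA`), `ambiguous`
#'   (logical, 5' tie), `fwd_hit`, `rev_hit` (motif hits or `NULL`).
#' @export
assign_tags <- function(sequence, tags, max_edits = 0L, rev_from = NULL) {
  tab <- tag_table(tags)
  stopifnot(nrow(tab) >= 1)
  n <- nchar(sequence)

  best_of <- function(motifs, from, anchored) {
    hits <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      wend <- min(n, from + nchar(motifs[i]) + max_edits)
      if (from >= wend) next
      hits[[i]] <- find_motif(sequence, motifs[i], max_edits,
                              window = c(from, wend),
                              anchored_start = anchored,
                              motif_name = tab$name[i])
    }
    found <- !vapply(hits, is.null, logical(1))
    if (!any(found)) return(list(tag = NA_character_, hit = NULL, tie = FALSE))
    edits <- vapply(hits[found], `[[`, numeric(1), "edits")
    idx <- which(found)[edits == min(edits)]
    if (length(idx) > 1)
      return(list(tag = NA_character_, hit = NULL, tie = TRUE))
    list(tag = tab$name[idx], hit = hits[[idx]], tie = FALSE)
  }

  fwd <- best_of(tab$sequence, 0L, TRUE)
  rev <- if (!is.null(rev_from))
    best_of(revcomp(tab$sequence), rev_from, TRUE)
  else list(tag = NA_character_, hit = NULL, tie = FALSE)
  list(fwd_tag = fwd$tag, rev_tag = rev$tag, ambiguous = fwd$tie,
       fwd_hit = fwd$hit, rev_hit = rev$hit)
}

#' Check end-tag compatibility
#'
#' Reads carry the same tag on both ends; differing end tags indicate an
#' artifact formed during sample pooling. A read whose 3' tag was not found
#' (e.g. a partially sequenced amplicon) cannot be checked and passes.
#'
#' @param fwd_tag,rev_tag tag names or `NA`.
#' @return `"pass"`, `"fail"`, or `"not_applicable"`.
#' @export
check_tag_compatibility <- function(fwd_tag, rev_tag) {
  if (is.na(rev_tag) || is.na(fwd_tag)) return("not_applicable")
  if (identical(fwd_tag, rev_tag)) "pass" else "fail"
}

#' Locate the primers in a read
#'
#' The forward primer is searched in a bounded window right of the 5' tag;
#' the reverse primer is searched as its reverse complement in the read's 3'
#' region (the window leaves room for the trailing reverse-complement tag
#' and adaptor). Degenerate primer letters match their IUPAC expansion sets.
#' When present in the configuration, the reverse primer is located even in
#' `FP_ONLY` mode (its coordinates are used for trimming), but its absence
#' rejects the read only in `FP_AND_RP` mode.
#'
#' @param sequence read sequence.
#' @param forward_primer forward primer string.
#' @param reverse_primer reverse primer string or `NULL`.
#' @param mode `"FP_AND_RP"` or `"FP_ONLY"`.
#' @param max_edits mismatch allowance.
#' @param fp_from 0-based window start for the forward primer (normally the
#'   end of the 5' tag hit).
#' @param rp_window_extra extra 3' window width (room for trailing tag and
#'   adaptor) added when locating the reverse primer.
#' @return list with `fp_hit`, `rp_hit` (motif hits or `NULL`) and `status`
#'   (`"pass"` or `"no_primer"`).
#' @export
detect_primers <- function(sequence, forward_primer, reverse_primer = NULL,
                           mode = c("FP_AND_RP", "FP_ONLY"), max_edits = 0L,
                           fp_from = 0L, rp_window_extra = 0L) {
  mode <- match.arg(mode)
  stopifnot(nzchar(forward_primer))
  if (mode == "FP_AND_RP" && is.null(reverse_primer))
    stop("primer_mode FP_AND_RP requires a reverse primer in the TPA configuration")
  n <- nchar(sequence)
  fp_hit <- NULL
  fend <- min(n, fp_from + nchar(forward_primer) + max_edits + 5L)
  if (fp_from < fend)
    fp_hit <- find_motif(sequence, forward_primer, max_edits,
                         window = c(fp_from, fend), motif_name = "FP")
  rp_hit <- NULL
  if (!is.null(reverse_primer)) {
    w0 <- max(if (is.null(fp_hit)) fp_from else fp_hit$end,
              n - (nchar(reverse_primer) + max_edits + rp_window_extra + 5L))
    if (w0 < n)
      rp_hit <- find_motif(sequence, revcomp(reverse_primer), max_edits,
                           window = c(w0, n), motif_name = "RP")
  }
  missing_fp <- is.null(fp_hit)
  missing_rp <- is.null(rp_hit)
  status <- if (missing_fp || (mode == "FP_AND_RP" && missing_rp))
    "no_primer" else "pass"
  list(fp_hit = fp_hit, rp_hit = rp_hit, status = status)
}

#' Screen a trimmed read for ambiguous bases and length
#'
#' Every non-ACGT IUPAC letter counts as ambiguous (N is just the common
#' case). The ambiguity filter is applied before the length filter.
#'
#' @param sequence trimmed read sequence.
#' @param max_ambiguous maximum tolerated ambiguous bases.
#' @param min_length minimum length.
#' @return `"pass"`, `"ambiguous"`, or `"too_short"`.
#' @export
screen_sequence <- function(sequence, max_ambiguous = 0L, min_length = 150L) {
  n_amb <- nchar(gsub("[ACGT]", "", toupper(sequence)))
  if (n_amb > max_ambiguous) return("ambiguous")
  if (nchar(sequence) < min_length) return("too_short")
  "pass"
}

#' Collapse over-long homopolymer runs
#'
#' Every maximal single-base run longer than `limit` is truncated to exactly
#' `limit` bases (e.g. with limit 6, all runs longer than six are reduced to
#' six). The operation is idempotent.
#'
#' @param sequence nucleotide string.
#' @param limit maximum run length retained (at least 2).
#' @return list with the collapsed `sequence` and an `events` data frame
#'   (`position` = 0-based run start in the input, `base`, `original_run`,
#'   `collapsed_run`).
#' @export
collapse_homopolymers <- function(sequence, limit) {
  stopifnot(limit >= 2)
  empty <- data.frame(position = integer(), base = character(),
                      original_run = integer(), collapsed_run = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(list(sequence = sequence, events = empty))
  r <- rle(strsplit(sequence, "")[[1]])
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  long <- which(r$lengths > limit)
  if (length(long) == 0) return(list(sequence = sequence, events = empty))
  events <- data.frame(position = starts[long], base = r$values[long],
                       original_run = r$lengths[long],
                       collapsed_run = rep.int(as.integer(limit), length(long)),
                       stringsAsFactors = FALSE)
  r$lengths[long] <- as.integer(limit)
  list(sequence = paste(inverse.rle(r), collapse = ""), events = events)
}

#' Trim tags, primers and adaptor from a read
#'
#' With `trim = "tags_and_primers"` only the target region between the
#' primers remains; with `"tags_only"` the terminal tags are removed and the
#' primers kept. Adaptor trimming applies when the 3' side was not already
#' cut at a located motif: a full adaptor occurrence removes everything from
#' its start, and a read suffix equal to an adaptor prefix of length at
#' least `min_partial_overlap` is removed (partially sequenced adaptor).
#' Trimming that empties the read returns an empty string (rejected
#' downstream as too short), never an error.
#'
#' @param sequence read sequence.
#' @param tag_hits list with `fwd_hit` and `rev_hit` as from [assign_tags()].
#' @param primer_hits list with `fp_hit` and `rp_hit` as from
#'   [detect_primers()].
#' @param adaptors character vector of adaptor sequences.
#' @param trim `"tags_and_primers"` or `"tags_only"`.
#' @param trim_adaptor logical.
#' @param min_partial_overlap minimum suffix length for partial adaptor
#'   recognition.
#' @return list with the trimmed `sequence` and the retained 0-based
#'   half-open interval `span` on the input read.
#' @export
trim_read <- function(sequence, tag_hits, primer_hits, adaptors = character(),
                      trim = c("tags_and_primers", "tags_only"),
                      trim_adaptor = TRUE, min_partial_overlap = 5L) {
  trim <- match.arg(trim)
  n <- nchar(sequence)
  fwd <- tag_hits$fwd_hit; rev <- tag_hits$rev_hit
  fp <- primer_hits$fp_hit; rp <- primer_hits$rp_hit
  if (trim == "tags_and_primers") {
    start <- if (!is.null(fp)) fp$end else if (!is.null(fwd)) fwd$end else 0L
    end <- if (!is.null(rp)) rp$start else n
  } else {
    start <- if (!is.null(fwd)) fwd$end else 0L
    end <- if (!is.null(rev)) rev$start else n
  }
  if (end < start) end <- start
  region <- substr(sequence, start + 1, end)

  if (isTRUE(trim_adaptor) && end == n && length(adaptors) > 0 &&
      nzchar(region)) {
    cut <- nchar(region)
    for (ad in adaptors) {
      # full occurrence: everything from the last occurrence on is adaptor
      occ <- gregexpr(ad, region, fixed = TRUE)[[1]]
      if (occ[1] != -1) cut <- min(cut, occ[length(occ)] - 1L)
      # partial adaptor at the very end of the read, longest suffix first
      maxk <- min(nchar(ad), nchar(region))
      if (maxk >= min_partial_overlap) {
        for (k in seq(maxk, min_partial_overlap)) {
          if (substr(region, nchar(region) - k + 1, nchar(region)) ==
              substr(ad, 1, k)) {
            cut <- min(cut, nchar(region) - k)
            break
          }
        }
      }
    }
    region <- substr(region, 1, cut)
    end <- start + cut
  }
  list(sequence = region, span = c(start, end))
}

#' Dereplicate exact duplicate sequences
#'
#' Uniqueness is exact string equality of the (trimmed) sequences; the
#' representative of each unique is the first-seen record. Per-sample
#' tallies are kept so the OTU-by-sample matrix can report both unique and
#' duplicate-inclusive counts. The abundances always sum to the input count.
#'
#' @param records a [seq_records] data frame (trimmed reads).
#' @param samples character vector of sample ids parallel to `records`
#'   (defaults to a `sample` column if present, else `"unassigned"`).
#' @return an object of class `derep_table`: list with `uniques` (columns
#'   `unique_id`, `sequence`, `sample`, `abundance`, `n_duplicates`),
#'   `members` (`id`, `unique_id`, `sample`) and `tallies`
#'   (`unique_id`, `sample`, `count`).
#' @export
dereplicate <- function(records, samples = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    empty <- data.frame(unique_id = character(), sequence = character(),
                        sample = character(), abundance = integer(),
                        n_duplicates = integer(), stringsAsFactors = FALSE)
    return(structure(list(uniques = empty,
                          members = data.frame(id = character(),
                                               unique_id = character(),
                                               sample = character()),
                          tallies = data.frame(unique_id = character(),
                                               sample = character(),
                                               count = integer())),
                     class = "derep_table"))
  }
  if (is.null(samples))
    samples <- records$sample %||% rep("unassigned", nrow(records))
  samples <- rep_len(as.character(samples), nrow(records))
  first <- !duplicated(records$sequence)
  uid <- records$id[first][match(records$sequence, records$sequence[first])]
  members <- data.frame(id = records$id, unique_id = uid, sample = samples,
                        stringsAsFactors = FALSE)
  counts <- table(factor(uid, levels = records$id[first]))
  uniques <- data.frame(unique_id = records$id[first],
                        sequence = records$sequence[first],
                        sample = samples[first],
                        abundance = as.integer(counts),
                        stringsAsFactors = FALSE)
  uniques$n_duplicates <- uniques$abundance - 1L
  tal <- as.data.frame(table(unique_id = uid, sample = samples),
                       stringsAsFactors = FALSE)
  names(tal)[3] <- "count"
  tal <- tal[tal$count > 0, ]
  tal <- tal[order(match(tal$unique_id, uniques$unique_id), tal$sample), ]
  rownames(tal) <- NULL
  structure(list(uniques = uniques, members = members, tallies = tal),
            class = "derep_table")
}

#' Run the full filtering and trimming cascade
#'
#' Applies the filters in cascade order (tags, primers, incompatible tags,
#' trimming and optional homopolymer collapsing, ambiguous bases, minimum
#' length, identical sequences), producing per-step accounting in which
#' every row satisfies considered = accepted + rejected and each row's
#' considered count is the previous row's accepted count.
#'
#' @param records a [seq_records] data frame of raw reads.
#' @param tpa a [tpa_config].
#' @param sample_map a [sample_map] or `NULL` (tag names then serve as
#'   sample ids).
#' @param params a [filter_params] list.
#' @return an object of class `filter_result`: list with `accepted` (trimmed
#'   unique reads, with `sample` and `tag` columns), `rejected` (raw reads
#'   with a `reason` column), `stats` (the cascade table), `derep` (a
#'   [dereplicate()] table or `NULL`), `outcomes` (per-read decisions),
#'   `homopolymer_events` and `params`.
#' @export
run_filter_step <- function(records, tpa, sample_map = NULL,
                            params = filter_params()) {
  stopifnot(is.data.frame(records), inherits(tpa, "tpa_config"),
            inherits(params, "filter_params"))
  if (is.null(tpa$forward_primer))
    stop("primer filtering requires a forward primer (FP) in the TPA configuration")
  if (params$primer_mode == "FP_AND_RP" && is.null(tpa$reverse_primer))
    stop("primer_mode = FP_AND_RP requires a reverse primer (RP) in the TPA configuration")

  n <- nrow(records)
  taglen_max <- if (nrow(tpa$tags)) max(nchar(tpa$tags$sequence)) else 0L
  adlen_max <- if (length(tpa$adaptors)) max(nchar(tpa$adaptors)) else 0L
  check_incomp <- params$check_incompatible_tags &&
    params$primer_mode == "FP_AND_RP"

  reason <- rep(NA_character_, n)
  fwd_tag <- rep(NA_character_, n)
  rev_tag <- rep(NA_character_, n)
  trimmed <- rep(NA_character_, n)
  hp_events <- list()

  for (i in seq_len(n)) {
    seq_i <- records$sequence[i]

    tg <- assign_tags(seq_i, tpa, params$max_edits_tag)
    if (is.na(tg$fwd_tag)) { reason[i] <- "no_tag"; next }
    fwd_tag[i] <- tg$fwd_tag

    pr <- detect_primers(seq_i, tpa$forward_primer, tpa$reverse_primer,
                         params$primer_mode, params$max_edits_primer,
                         fp_from = tg$fwd_hit$end,
                         rp_window_extra = taglen_max + adlen_max)
    if (pr$status == "no_primer") { reason[i] <- "no_primer"; next }

    if (!is.null(pr$rp_hit)) {
      tg2 <- assign_tags(seq_i, tpa, params$max_edits_tag,
                         rev_from = pr$rp_hit$end)
      tg$rev_hit <- tg2$rev_hit
      rev_tag[i] <- tg2$rev_tag
      if (check_incomp &&
          check_tag_compatibility(tg$fwd_tag, tg2$rev_tag) == "fail") {
        reason[i] <- "incompatible_tags"
        next
      }
    }

    tr <- trim_read(seq_i, tg, pr, tpa$adaptors, params$trim,
                    params$trim_adaptor, params$min_partial_overlap)
    target <- tr$sequence

    if (!is.null(params$homopolymer_limit)) {
      hp <- collapse_homopolymers(target, params$homopolymer_limit)
      target <- hp$sequence
      if (nrow(hp$events)) {
        hp$events$id <- records$id[i]
        hp_events[[length(hp_events) + 1]] <- hp$events
      }
    }

    sc <- screen_sequence(target, params$max_ambiguous, params$min_length)
    if (sc != "pass") {
      reason[i] <- if (sc == "ambiguous") "ambiguous" else "too_short"
      next
    }
    trimmed[i] <- target
  }

  passed <- is.na(reason)
  samples <- sample_lookup(sample_map, records$source_file, fwd_tag)

  derep <- NULL
  if (params$dereplicate && any(passed)) {
    acc <- records[passed, , drop = FALSE]
    acc$sequence <- trimmed[passed]
    derep <- dereplicate(acc, samples[passed])
    dup <- !(acc$id %in% derep$uniques$unique_id)
    reason[which(passed)[dup]] <- "duplicate"
    passed <- is.na(reason)
  }

  steps <- c("Tags",
             if (params$primer_mode == "FP_AND_RP") "Primers (FP+RP)" else "Primers (FP)",
             if (check_incomp) "Incompatible tags combination",
             "Ns",
             sprintf("Length (<%d)", params$min_length),
             if (params$dereplicate) "Identical sequences")
  step_reason <- c("no_tag", "no_primer",
                   if (check_incomp) "incompatible_tags",
                   "ambiguous", "too_short",
                   if (params$dereplicate) "duplicate")
  considered <- integer(length(steps))
  rejected_n <- integer(length(steps))
  remaining <- n
  for (k in seq_along(steps)) {
    considered[k] <- remaining
    rejected_n[k] <- sum(reason == step_reason[k], na.rm = TRUE)
    remaining <- remaining - rejected_n[k]
  }
  stats <- data.frame(step = steps, considered = considered,
                      accepted = considered - rejected_n,
                      rejected = rejected_n, stringsAsFactors = FALSE)

  accepted <- records[passed, , drop = FALSE]
  accepted$sequence <- trimmed[passed]
  accepted$sample <- samples[passed]
  accepted$tag <- fwd_tag[passed]
  rownames(accepted) <- NULL
  class(accepted) <- c("seq_records", "data.frame")

  rejected <- records[!passed, , drop = FALSE]
  rejected$reason <- reason[!passed]
  rownames(rejected) <- NULL

  outcomes <- data.frame(id = records$id,
                         status = ifelse(passed, "accepted", "rejected"),
                         reject_reason = reason,
                         fwd_tag = fwd_tag, rev_tag = rev_tag,
                         sample = samples, stringsAsFactors = FALSE)

  hp_df <- if (length(hp_events)) do.call(rbind, hp_events) else
    data.frame(position = integer(), base = character(),
               original_run = integer(), collapsed_run = integer(),
               id = character(), stringsAsFactors = FALSE)

  structure(list(accepted = accepted, rejected = rejected, stats = stats,
                 derep = derep, outcomes = outcomes,
                 homopolymer_events = hp_df, params = params),
            class = "filter_result")
}
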