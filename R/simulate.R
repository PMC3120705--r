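# Synthetic amplicon read generator. Emulates tagged amplicon reads with the
# layout  tag + forward primer + target + rc(reverse primer) + rc(tag) +
# adaptor  and plants defects (substitutions, N injection, homopolymer
# expansion, 3' truncation, tag dropout, end-tag chimeras, exact
# duplicates) with full per-read ground truth, so every pipeline stage can
# be verified without external data.

SIM_FORWARD_PRIMER <- "GGAAGTAAAAGTCGTAACAAGG"  # ITS5
SIM_REVERSE_PRIMER <- "GCTGCGTTCTTCATCGATGC"    # ITS2
SIM_ADAPTOR <- "CTGAGACTGCCAAGGCACACAGG"

#' Simulation configuration
#'
#' Rates are probabilities in `[0, 1]`. In `"one_per_read"` mode (the
#' default) each read receives at most one defect class, drawn with the
#' given per-read probabilities, so per-filter rejection counts are exactly
#' predictable from the ground truth; `"free"` mode applies substitution
#' and N rates per base and the other defects independently.
#'
#' @param n_templates number of template (target) sequences.
#' @param template_length length range `c(min, max)` for templates.
#' @param min_template_divergence minimum pairwise divergence between
#'   templates (pairwise identity at most `1 -` this value).
#' @param samples sample identifiers; each sample gets one tag, used on
#'   both ends of its reads.
#' @param reads_per_sample reads drawn per sample (templates uniform).
#' @param substitution_rate,n_rate per-base rates in `"free"` mode,
#'   per-read probabilities in `"one_per_read"` mode.
#' @param homopolymer_expansion_rate per-run (free) or per-read
#'   (one-per-read) probability of expanding a homopolymer run by 1-3
#'   bases.
#' @param truncation_rate per-read probability of dropping a 3' portion
#'   (removing adaptor, trailing tag and reverse primer; the retained
#'   target is never shorter than `min_truncated_target`).
#' @param tag_chimera_rate per-read probability of replacing the 3' tag
#'   with a different sample's tag (incompatible end tags).
#' @param tag_dropout_rate per-read probability of replacing the 5' tag
#'   with a decoy at least 3 edits from every real tag (undetectable tag).
#' @param duplicate_fraction fraction of extra reads appended as exact
#'   duplicates of already generated reads.
#' @param tag_length tag length in bases.
#' @param min_truncated_target minimum retained target length after a
#'   planted truncation.
#' @param defect_mode `"one_per_read"` or `"free"`.
#' @param seed mandatory integer seed; all outputs are byte-reproducible.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_templates = 10L,
                              template_length = c(250L, 300L),
                              min_template_divergence = 0.05,
                              samples = sprintf("sample%02d", 1:8),
                              reads_per_sample = 250L,
                              substitution_rate = 0, n_rate = 0,
                              homopolymer_expansion_rate = 0,
                              truncation_rate = 0, tag_chimera_rate = 0,
                              tag_dropout_rate = 0, duplicate_fraction = 0,
                              tag_length = 8L, min_truncated_target = 150L,
                              defect_mode = c("one_per_read", "free"),
                              seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  defect_mode <- match.arg(defect_mode)
  rates <- c(substitution_rate, n_rate, homopolymer_expansion_rate,
             truncation_rate, tag_chimera_rate, tag_dropout_rate,
             duplicate_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (defect_mode == "one_per_read" &&
      sum(substitution_rate, n_rate, homopolymer_expansion_rate,
          truncation_rate, tag_chimera_rate, tag_dropout_rate) > 1)
    stop("in one_per_read mode the defect-class probabilities must sum to at most 1")
  stopifnot(n_templates >= 1, length(template_length) == 2,
            template_length[1] <= template_length[2],
            length(samples) >= 1, !anyDuplicated(samples),
            reads_per_sample >= 1, tag_length >= 4)
  structure(list(n_templates = as.integer(n_templates),
                 template_length = as.integer(template_length),
                 min_template_divergence = min_template_divergence,
                 samples = as.character(samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 substitution_rate = substitution_rate, n_rate = n_rate,
                 homopolymer_expansion_rate = homopolymer_expansion_rate,
                 truncation_rate = truncation_rate,
                 tag_chimera_rate = tag_chimera_rate,
                 tag_dropout_rate = tag_dropout_rate,
                 duplicate_fraction = duplicate_fraction,
                 tag_length = as.integer(tag_length),
                 min_truncated_target = as.integer(min_truncated_target),
                 defect_mode = defect_mode, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate templates and the matching TPA configuration
#'
#' Templates are i.i.d. random sequences regenerated until every pair's
#' identity is at most `1 - min_template_divergence` (verified with the
#' package's own similarity measure). Tags are random sequences of
#' `tag_length` bases, mutually at least 2 edits apart, one per sample;
#' primers and the adaptor are fixed constants.
#'
#' @param config a [simulation_config].
#' @return list with `templates` (a [seq_records] frame, ids
#'   `template01`, ...) and `tpa` (a [tpa_config]).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    tags <- character(0)
    tries <- 0
    while (length(tags) < length(config$samples)) {
      cand <- random_dna(config$tag_length)
      ok <- all(vapply(tags, function(t)
        global_align(cand, t)$edits >= 2, logical(1)))
      if (ok) tags <- c(tags, cand)
      tries <- tries + 1
      if (tries > 1000 * length(config$samples))
        stop("could not generate mutually distinct tags; increase tag_length")
    }
    max_id <- 1 - config$min_template_divergence
    templates <- NULL
    for (attempt in 1:50) {
      lens <- sample(config$template_length[1]:config$template_length[2],
                     config$n_templates, replace = TRUE)
      seqs <- random_dna(lens)
      if (config$n_templates == 1) { templates <- seqs; break }
      sim <- cpp_similarity_matrix(seqs)
      diag(sim$identity) <- 0
      if (max(sim$identity) <= max_id) { templates <- seqs; break }
    }
    if (is.null(templates))
      stop("could not satisfy the template divergence constraint; ",
           "use longer templates or lower min_template_divergence")
    list(templates = seq_records(sprintf("template%02d",
                                         seq_len(config$n_templates)),
                                 templates),
         tpa = tpa_config(data.frame(name = config$samples,
                                     sequence = tags,
                                     stringsAsFactors = FALSE),
                          forward_primer = SIM_FORWARD_PRIMER,
                          reverse_primer = SIM_REVERSE_PRIMER,
                          adaptors = SIM_ADAPTOR))
  })
}

# A 5' decoy that no real tag matches within 2 anchored edits, even
# accounting for read context following it.
make_decoy <- function(tags, tag_length, context) {
  for (i in 1:2000) {
    cand <- random_dna(tag_length)
    probe <- paste0(cand, substr(context, 1, tag_length))
    hit <- FALSE
    for (t in tags) {
      if (!is.null(find_motif(probe, t, 2L, anchored_start = TRUE))) {
        hit <- TRUE; break
      }
    }
    if (!hit) return(cand)
  }
  stop("could not generate a tag decoy; increase tag_length")
}

mutate_substitute <- function(seq, pos) {
  base <- substr(seq, pos, pos)
  repl <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
  paste0(substr(seq, 1, pos - 1), repl, substr(seq, pos + 1, nchar(seq)))
}

expand_random_run <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  runs <- which(r$lengths >= 2)
  if (length(runs) == 0) runs <- seq_along(r$lengths)
  k <- if (length(runs) == 1) runs else sample(runs, 1)
  r$lengths[k] <- r$lengths[k] + sample(1:3, 1)
  paste(inverse.rle(r), collapse = "")
}

#' Simulate tagged amplicon reads with ground truth
#'
#' Each read is assembled as `tag + FP + target + rc(RP) + rc(tag) +
#' adaptor` and then defect classes are applied according to the
#' configuration. The returned ground truth records, per read, the source
#' template, sample and planted defect, plus the template-by-sample
#' abundance table; [expected_fate()] translates defects into the fate a
#' filtering run should assign.
#'
#' @param templates [seq_records] from [generate_community()].
#' @param tpa [tpa_config] from [generate_community()].
#' @param config the same [simulation_config].
#' @param out_dir when not `NULL`, per-sample FASTA files, `tpa.tsv`,
#'   `metadata.tsv`, `truth.tsv` and `abundance.tsv` are written there.
#' @return list with `reads` (pooled [seq_records]; `source_file` names the
#'   per-sample FASTA), `truth` (per-read data frame: `id`, `sample`,
#'   `template`, `defect`, `duplicate_of`), `abundance` (template-by-sample
#'   integer matrix, duplicates included), `sample_map`, and `files`
#'   (named paths, or `NULL`).
#' @export
simulate_reads <- function(templates, tpa, config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(tpa, "tpa_config"))
  with_seed(config$seed + 1L, {
    tags <- setNames(tpa$tags$sequence, tpa$tags$name)
    fp <- tpa$forward_primer
    rp_rc <- revcomp(tpa$reverse_primer)
    adaptor <- if (length(tpa$adaptors)) tpa$adaptors[1] else ""
    decoy <- make_decoy(unname(tags), config$tag_length, fp)

    classes <- c("substitution", "n_injection", "homopolymer_expansion",
                 "truncation", "tag_chimera", "tag_dropout")
    probs <- c(config$substitution_rate, config$n_rate,
               config$homopolymer_expansion_rate, config$truncation_rate,
               config$tag_chimera_rate, config$tag_dropout_rate)

    all_reads <- list(); all_truth <- list()
    for (s in config$samples) {
      tag <- tags[[s]]
      n <- config$reads_per_sample
      tmpl_idx <- sample.int(nrow(templates), n, replace = TRUE)
      ids <- sprintf("%s_r%04d", s, seq_len(n))
      seqs <- character(n); defect <- character(n)
      for (j in seq_len(n)) {
        target <- templates$sequence[tmpl_idx[j]]
        tag5 <- tag; tag3rc <- revcomp(tag)
        trailing <- TRUE
        d <- "none"
        if (config$defect_mode == "one_per_read") {
          if (sum(probs) > 0) {
            u <- stats::runif(1)
            cum <- cumsum(probs)
            k <- which(u <= cum)[1]
            if (!is.na(k)) d <- classes[k]
          }
          if (d == "substitution") {
            target <- mutate_substitute(target, sample.int(nchar(target), 1))
          } else if (d == "n_injection") {
            p <- sample.int(nchar(target), 1)
            target <- paste0(substr(target, 1, p - 1), "N",
                             substr(target, p + 1, nchar(target)))
          } else if (d == "homopolymer_expansion") {
            target <- expand_random_run(target)
          } else if (d == "truncation") {
            lo <- min(config$min_truncated_target, nchar(target) - 1L)
            keep <- if (lo >= nchar(target) - 1L) nchar(target) - 1L
                    else sample(lo:(nchar(target) - 1L), 1)
            target <- substr(target, 1, keep)
            trailing <- FALSE
          } else if (d == "tag_chimera") {
            other <- sample(setdiff(unname(tags), tag), 1)
            tag3rc <- revcomp(other)
          } else if (d == "tag_dropout") {
            tag5 <- decoy
          }
        } else {
          # free mixing: per-read defects first, then per-base noise
          if (stats::runif(1) < config$tag_dropout_rate) {
            tag5 <- decoy; d <- "tag_dropout"
          }
          if (stats::runif(1) < config$tag_chimera_rate) {
            other <- sample(setdiff(unname(tags), tag), 1)
            tag3rc <- revcomp(other)
            d <- if (d == "none") "tag_chimera" else paste(d, "tag_chimera", sep = "+")
          }
          if (stats::runif(1) < config$truncation_rate) {
            lo <- min(config$min_truncated_target, nchar(target) - 1L)
            keep <- if (lo >= nchar(target) - 1L) nchar(target) - 1L
                    else sample(lo:(nchar(target) - 1L), 1)
            target <- substr(target, 1, keep)
            trailing <- FALSE
            d <- if (d == "none") "truncation" else paste(d, "truncation", sep = "+")
          }
          if (config$homopolymer_expansion_rate > 0 &&
              stats::runif(1) < config$homopolymer_expansion_rate) {
            target <- expand_random_run(target)
            d <- if (d == "none") "homopolymer_expansion" else paste(d, "homopolymer_expansion", sep = "+")
          }
          nt <- nchar(target)
          nsub <- stats::rbinom(1, nt, config$substitution_rate)
          if (nsub > 0) {
            for (p in sample.int(nt, nsub)) target <- mutate_substitute(target, p)
            d <- if (d == "none") "substitution" else paste(d, "substitution", sep = "+")
          }
          nn <- stats::rbinom(1, nchar(target), config$n_rate)
          if (nn > 0) {
            for (p in sample.int(nchar(target), nn)) {
              target <- paste0(substr(target, 1, p - 1), "N",
                               substr(target, p + 1, nchar(target)))
            }
            d <- if (d == "none") "n_injection" else paste(d, "n_injection", sep = "+")
          }
        }
        seqs[j] <- if (trailing)
          paste0(tag5, fp, target, rp_rc, tag3rc, adaptor)
        else paste0(tag5, fp, target)
        defect[j] <- d
      }
      all_reads[[s]] <- data.frame(id = ids, description = "",
                                   sequence = seqs,
                                   source_file = paste0(s, ".fas"),
                                   stringsAsFactors = FALSE)
      all_truth[[s]] <- data.frame(id = ids, sample = s,
                                   template = templates$id[tmpl_idx],
                                   defect = defect,
                                   duplicate_of = NA_character_,
                                   stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, all_reads)
    truth <- do.call(rbind, all_truth)

    n_dup <- round(config$duplicate_fraction * nrow(reads))
    if (n_dup > 0) {
      src <- sample.int(nrow(reads), n_dup, replace = TRUE)
      dup_reads <- reads[src, ]
      dup_truth <- truth[src, ]
      dup_truth$duplicate_of <- dup_reads$id
      dup_ids <- sprintf("%s_dup%04d", dup_reads$id, seq_len(n_dup))
      dup_reads$id <- dup_ids
      dup_truth$id <- dup_ids
      reads <- rbind(reads, dup_reads)
      truth <- rbind(truth, dup_truth)
    }
    rownames(reads) <- rownames(truth) <- NULL
    class(reads) <- c("seq_records", "data.frame")

    abundance <- unclass(table(factor(truth$template, levels = templates$id),
                               factor(truth$sample, levels = config$samples)))
    smap <- sample_map(data.frame(file = paste0(config$samples, ".fas"),
                                  tag = config$samples,
                                  sample = config$samples,
                                  stringsAsFactors = FALSE))
    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fasta_files <- character(0)
      for (s in config$samples) {
        p <- file.path(out_dir, paste0(s, ".fas"))
        write_fasta(reads[reads$source_file == paste0(s, ".fas"), ], p)
        fasta_files <- c(fasta_files, p)
      }
      tpa_path <- file.path(out_dir, "tpa.tsv")
      write_tpa(tpa, tpa_path)
      meta_path <- file.path(out_dir, "metadata.tsv")
      write_metadata(smap, meta_path)
      truth_path <- file.path(out_dir, "truth.tsv")
      write.table(truth, truth_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      ab_path <- file.path(out_dir, "abundance.tsv")
      write.table(data.frame(template = rownames(abundance), abundance,
                             check.names = FALSE),
                  ab_path, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(setNames(fasta_files, paste0(config$samples, ".fas")),
                 tpa = tpa_path, metadata = meta_path, truth = truth_path,
                 abundance = ab_path)
    }
    list(reads = reads, truth = truth, abundance = abundance,
         sample_map = smap, files = files)
  })
}

#' Expected filtering fate of simulated reads
#'
#' Translates the planted defect of each read in a ground-truth table into
#' the outcome a filtering run should produce (valid for one-defect-per-read
#' simulations; duplicates inherit the fate of their source read).
#'
#' @param truth the `truth` data frame from [simulate_reads()].
#' @param primer_mode `"FP_AND_RP"` or `"FP_ONLY"`.
#' @return character vector: `"accepted"` or a rejection reason, parallel
#'   to `truth` rows (dereplication not considered).
#' @export
expected_fate <- function(truth, primer_mode = c("FP_AND_RP", "FP_ONLY")) {
  primer_mode <- match.arg(primer_mode)
  fate_of <- function(defect) {
    switch(defect,
           tag_dropout = "no_tag",
           tag_chimera = if (primer_mode == "FP_AND_RP")
             "incompatible_tags" else "accepted",
           n_injection = "ambiguous",
           truncation = if (primer_mode == "FP_AND_RP")
             "no_primer" else "accepted",
           "accepted")
  }
  fates <- vapply(truth$defect, fate_of, character(1), USE.NAMES = FALSE)
  dup <- !is.na(truth$duplicate_of)
  if (any(dup))
    fates[dup] <- fates[match(truth$duplicate_of[dup], truth$id)]
  fates
}
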