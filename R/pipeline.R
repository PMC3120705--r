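# End-to-end orchestration of the three stages (filter -> cluster ->
# annotate) with the report-file conventions of the toolkit: accepted.fas,
# rejected.fas, summary.txt, stats_log.txt, cluster_out.fas,
# cluster_info.txt, singletons.fas, SeqInEachCluster.zip,
# matrix_table_1.tsv, outfile_bp.tsv, matrix_table_2.tsv.
#
# Stages can be run separately: each stage reads its inputs from the prior
# stage's files on disk when that stage was not run in the same invocation,
# and running stages separately produces byte-identical outputs to a single
# full run. No output file contains timestamps.

#' Pipeline run configuration
#'
#' Validates paths and parameter combinations before any file is touched.
#'
#' @param sequences FASTA file(s) or one ZIP archive of FASTA files
#'   (required for the filter stage).
#' @param tpa path to the TPA (tags/primers/adaptors) file.
#' @param metadata optional path to the sample metadata file.
#' @param blast_tab optional path to an existing BLAST tabular result for
#'   the annotation stage.
#' @param out_dir output directory (created if absent).
#' @param filter a [filter_params] list.
#' @param cluster a [cluster_params] list.
#' @param annotation list of annotation settings: `e_value_max`,
#'   `max_descriptions`, `remove_uncultured`, `keywords`, `blast_db`
#'   (optional formatted database to run blastn against).
#' @param stages character subset of `c("filter", "cluster", "annotate")`,
#'   in pipeline order.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sequences = NULL, tpa, metadata = NULL,
                       blast_tab = NULL, out_dir,
                       filter = filter_params(),
                       cluster = cluster_params(),
                       annotation = list(),
                       stages = c("filter", "cluster", "annotate")) {
  stopifnot(inherits(filter, "filter_params"),
            inherits(cluster, "cluster_params"))
  stages <- match.arg(stages, several.ok = TRUE)
  ann <- utils::modifyList(
    list(e_value_max = 1e-3, max_descriptions = 10L,
         remove_uncultured = TRUE,
         keywords = DEFAULT_UNCULTURED_KEYWORDS, blast_db = NULL),
    annotation)
  if (!file.exists(tpa)) stop(sprintf("tpa: file not found: %s", tpa))
  if ("filter" %in% stages) {
    if (is.null(sequences)) stop("sequences: required for the filter stage")
    missing <- sequences[!file.exists(sequences)]
    if (length(missing))
      stop(sprintf("sequences: file not found: %s", missing[1]))
  }
  if (!is.null(metadata) && !file.exists(metadata))
    stop(sprintf("metadata: file not found: %s", metadata))
  if (!is.null(blast_tab) && !file.exists(blast_tab))
    stop(sprintf("blast_tab: file not found: %s", blast_tab))
  tpa_obj <- read_tpa(tpa)
  if (is.null(tpa_obj$forward_primer))
    stop("tpa: no forward primer (FP) defined, primer filtering impossible")
  if (filter$primer_mode == "FP_AND_RP" && is.null(tpa_obj$reverse_primer))
    stop("primer_mode: FP_AND_RP requires a reverse primer (RP) in the TPA file")
  structure(list(sequences = sequences, tpa = tpa, metadata = metadata,
                 blast_tab = blast_tab, out_dir = out_dir, filter = filter,
                 cluster = cluster, annotation = ann, stages = stages),
            class = "run_config")
}

format_params <- function(p) {
  vals <- vapply(p, function(v)
    if (is.null(v)) "off" else paste(format(v), collapse = ","),
    character(1))
  setNames(vals, names(p))
}

top_hit_labels <- function(ann) {
  ifelse(ann$has_hit,
         sprintf("%s %s (evalue=%g)", ann$subject_id,
                 ifelse(!is.na(ann$subject_description) &
                          nzchar(ann$subject_description),
                        ann$subject_description, "-"),
                 ann$e_value),
         "no_hit")
}

#' Run the pipeline
#'
#' Executes the configured stages in order. A stage not selected is skipped;
#' a stage whose inputs were produced by an earlier invocation picks them up
#' from the output directory (`accepted.fas`/`derep.tsv` for clustering,
#' `cluster_out.fas`/`matrix_table_1.tsv` for annotation). The annotation
#' stage is skipped, and reported as such, when neither a BLAST tabular
#' file nor a database is configured.
#'
#' @param config a [run_config].
#' @return an object of class `run_report`: list with `stages_run`,
#'   `skipped`, `stats` (filter cascade), `clustering_summary`,
#'   `annotation_summary`, `manifest` (named file paths, all existing on
#'   success) and `elapsed` (seconds per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tpa <- read_tpa(config$tpa)
  smap <- if (!is.null(config$metadata)) read_metadata(config$metadata)
  stats_path <- file.path(out, "stats_log.txt")
  prior <- if (file.exists(stats_path)) read_stats_log(stats_path)

  manifest <- character(0)
  elapsed <- numeric(0)
  skipped <- character(0)
  stats <- prior$cascade
  filter_param_block <- prior$filter_parameters
  clustering_summary <- prior$clustering
  annotation_summary <- prior$annotation
  fr <- NULL; clustering <- NULL; derep <- NULL; otu_mat <- NULL

  # ---- stage 1: filter ----------------------------------------------------
  if ("filter" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    reads <- read_fasta(config$sequences)
    fr <- run_filter_step(reads, tpa, smap, config$filter)
    stats <- fr$stats
    derep <- fr$derep
    filter_param_block <- format_params(unclass(config$filter))

    acc <- fr$accepted
    abund <- if (!is.null(derep))
      derep$uniques$abundance[match(acc$id, derep$uniques$unique_id)]
    else rep(1L, nrow(acc))
    acc$description <- sprintf("sample=%s abundance=%d", acc$sample, abund)
    write_fasta(acc, file.path(out, "accepted.fas"))
    fr$accepted <- acc  # keep in-memory records identical to accepted.fas

    rej <- fr$rejected
    rej$description <- trimws(paste(rej$description,
                                    paste0("reason=", rej$reason)))
    write_fasta(rej, file.path(out, "rejected.fas"))
    manifest <- c(manifest, accepted = file.path(out, "accepted.fas"),
                  rejected = file.path(out, "rejected.fas"))

    if (!is.null(derep)) {
      write.table(derep$tallies, file.path(out, "derep.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest <- c(manifest, derep = file.path(out, "derep.tsv"))
    }
    if (!is.null(config$filter$homopolymer_limit)) {
      hp <- fr$homopolymer_events[, c("id", "position", "base",
                                      "original_run", "collapsed_run")]
      write.table(hp, file.path(out, "homopolymers.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest <- c(manifest, homopolymers = file.path(out, "homopolymers.tsv"))
    }
    elapsed <- c(elapsed, filter = proc.time()[["elapsed"]] - t0)
  } else skipped <- c(skipped, "filter")

  # ---- stage 2: cluster ---------------------------------------------------
  if ("cluster" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(fr)) {
      accf <- file.path(out, "accepted.fas")
      if (!file.exists(accf))
        stop("cluster stage: no accepted.fas in the output directory; ",
             "run the filter stage first")
      acc <- read_fasta(accf)
      acc$sample <- sub(".*sample=(\\S+).*", "\\1", acc$description)
      acc$sample[!grepl("sample=", acc$description)] <- "unassigned"
      ab <- suppressWarnings(as.integer(
        sub(".*abundance=(\\d+).*", "\\1", acc$description)))
      ab[is.na(ab)] <- 1L
      derepf <- file.path(out, "derep.tsv")
      tallies <- if (file.exists(derepf))
        read.delim(derepf, stringsAsFactors = FALSE)
      else data.frame(unique_id = acc$id, sample = acc$sample, count = ab,
                      stringsAsFactors = FALSE)
      uniques <- data.frame(unique_id = acc$id, sequence = acc$sequence,
                            sample = acc$sample, abundance = ab,
                            stringsAsFactors = FALSE)
      uniques$n_duplicates <- uniques$abundance - 1L
      derep <- structure(list(uniques = uniques,
                              members = data.frame(id = acc$id,
                                                   unique_id = acc$id,
                                                   sample = acc$sample,
                                                   stringsAsFactors = FALSE),
                              tallies = tallies), class = "derep_table")
    } else {
      acc <- fr$accepted
    }
    if (nrow(acc) == 0) stop("cluster stage: no accepted sequences")
    raw <- if (config$cluster$method == "single_linkage")
      cluster_single_linkage(acc, config$cluster)
    else cluster_greedy(acc, config$cluster)
    ol <- order_and_label(raw, derep)
    clustering <- ol$clustering
    otu_mat <- build_otu_matrix(clustering, derep, smap)

    files <- write_cluster_reports(clustering, otu_mat, acc, out)
    manifest <- c(manifest, files)
    singles <- acc[acc$id %in% ol$singletons, , drop = FALSE]
    write_fasta(singles, file.path(out, "singletons.fas"))
    manifest <- c(manifest, singletons = file.path(out, "singletons.fas"))

    sizes <- vapply(clustering$clusters, `[[`, integer(1), "total_abundance")
    clustering_summary <- c(
      method = clustering$method,
      identity_threshold = format(config$cluster$identity_threshold),
      coverage_threshold = format(config$cluster$coverage_threshold),
      n_clusters = format(length(clustering$clusters)),
      n_singletons = format(length(ol$singletons)),
      largest_cluster = format(if (length(sizes)) max(sizes) else 0L),
      total_abundance = format(sum(sizes)))
    elapsed <- c(elapsed, cluster = proc.time()[["elapsed"]] - t0)
  } else skipped <- c(skipped, "cluster")

  # ---- stage 3: annotate --------------------------------------------------
  if ("annotate" %in% config$stages) {
    hits_file <- config$blast_tab
    if (is.null(hits_file) && !is.null(config$annotation$blast_db)) {
      hits_file <- file.path(out, "blastout.txt")
      run_blastn_external(file.path(out, "cluster_out.fas"),
                          config$annotation$blast_db, hits_file,
                          config$annotation$e_value_max,
                          config$annotation$max_descriptions)
      manifest <- c(manifest, blastout = hits_file)
    }
    if (is.null(hits_file)) {
      skipped <- c(skipped, "annotate")
    } else {
      t0 <- proc.time()[["elapsed"]]
      outf <- file.path(out, "cluster_out.fas")
      if (!file.exists(outf))
        stop("annotate stage: no cluster_out.fas in the output directory; ",
             "run the cluster stage first")
      reps <- read_fasta(outf)
      otus <- data.frame(
        otu_index = as.integer(sub("^OTU_(\\d+)_.*", "\\1", reps$id)),
        header_id = reps$id, rep_id = reps$description,
        stringsAsFactors = FALSE)
      hits <- parse_blast_tabular(hits_file, config$annotation$e_value_max,
                                  config$annotation$max_descriptions)
      n_unc <- 0L
      removed <- NULL
      if (isTRUE(config$annotation$remove_uncultured)) {
        fu <- filter_uncultured(hits, config$annotation$keywords)
        hits <- fu$hits; removed <- fu$removed; n_unc <- fu$n_removed
      }
      key <- if (nrow(hits) > 0 && any(hits$query_id %in% otus$rep_id) &&
                 !any(hits$query_id %in% otus$header_id))
        otus$rep_id else otus$header_id
      ann <- select_top_hits(hits,
                             data.frame(otu_index = otus$otu_index,
                                        representative_id = key,
                                        stringsAsFactors = FALSE),
                             removed = removed)
      write.table(hits, file.path(out, "outfile_bp.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)

      mt1 <- file.path(out, "matrix_table_1.tsv")
      if (file.exists(mt1)) {
        mdf <- read.delim(mt1, stringsAsFactors = FALSE, check.names = FALSE)
        idx <- match(mdf$otu, paste0("OTU_", ann$otu_index))
        mdf$top_hit <- top_hit_labels(ann[idx, ])
        write.table(mdf, file.path(out, "matrix_table_2.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        manifest <- c(manifest, matrix_table_2 = file.path(out, "matrix_table_2.tsv"))
      }
      manifest <- c(manifest, outfile_bp = file.path(out, "outfile_bp.tsv"))

      ov <- hit_overlap_stats(ann)
      annotation_summary <- c(
        n_otus = format(nrow(ann)),
        n_otus_with_hit = format(ov$n_otus_with_hit),
        n_uncultured_removed = format(n_unc),
        n_distinct_best_subjects = format(ov$n_distinct_best_subjects),
        max_otus_sharing_one_subject = format(ov$max_otus_sharing_one_subject))
      elapsed <- c(elapsed, annotate = proc.time()[["elapsed"]] - t0)
    }
  } else skipped <- c(skipped, "annotate")

  report <- structure(list(stages_run = setdiff(config$stages, skipped),
                           skipped = skipped, stats = stats,
                           filter_parameters = filter_param_block,
                           clustering_summary = clustering_summary,
                           annotation_summary = annotation_summary,
                           manifest = manifest, elapsed = elapsed),
                      class = "run_report")
  write_stats_log(report, stats_path, append = FALSE)
  write_summary(report, file.path(out, "summary.txt"))
  report$manifest <- c(report$manifest, stats_log = stats_path,
                       summary = file.path(out, "summary.txt"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run:", paste(x$stages_run, collapse = " -> "), "\n")
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  if (!is.null(x$stats)) {
    cat("filter cascade:\n")
    print(x$stats, row.names = FALSE)
  }
  if (!is.null(x$clustering_summary))
    cat(sprintf("clusters: %s (method %s)\n",
                x$clustering_summary[["n_clusters"]],
                x$clustering_summary[["method"]]))
  if (!is.null(x$annotation_summary))
    cat(sprintf("OTUs with BLAST hit: %s\n",
                x$annotation_summary[["n_otus_with_hit"]]))
  invisible(x)
}

#' Write the stats log
#'
#' Human-readable, machine-parseable log: TSV blocks introduced by `##`
#' section headers, the parameter echo preceding the counts. The cascade
#' block can be read back with [read_stats_log()], reproducing the step
#' statistics exactly.
#'
#' @param report a `run_report` (or any list with the same fields).
#' @param path output path.
#' @param append append to existing content instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_stats_log <- function(report, path, append = FALSE) {
  lines <- character(0)
  if (!append) lines <- "# otupipe stats log"
  if (!is.null(report$filter_parameters)) {
    lines <- c(lines, "## filter parameters",
               sprintf("%s\t%s", names(report$filter_parameters),
                       report$filter_parameters))
  }
  if (!is.null(report$stats)) {
    s <- report$stats
    lines <- c(lines, "## filter cascade",
               "step\tconsidered\taccepted\trejected",
               sprintf("%s\t%d\t%d\t%d", s$step, s$considered, s$accepted,
                       s$rejected))
  }
  if (!is.null(report$clustering_summary)) {
    lines <- c(lines, "## clustering",
               sprintf("%s\t%s", names(report$clustering_summary),
                       report$clustering_summary))
  }
  if (!is.null(report$annotation_summary)) {
    lines <- c(lines, "## annotation",
               sprintf("%s\t%s", names(report$annotation_summary),
                       report$annotation_summary))
  }
  con <- file(path, if (append) "a" else "w")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Read a stats log back
#'
#' @param path path to a `stats_log.txt` written by [write_stats_log()].
#' @return list with `filter_parameters` (named character or `NULL`),
#'   `cascade` (the step-statistics data frame or `NULL`), `clustering`
#'   and `annotation` (named character or `NULL`).
#' @export
read_stats_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- NULL
  out <- list(filter_parameters = NULL, cascade = NULL, clustering = NULL,
              annotation = NULL)
  kv <- function(old, line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    c(old, setNames(f[2], f[1]))
  }
  for (line in lines) {
    if (startsWith(line, "##")) { section <- trimws(sub("^##", "", line)); next }
    if (startsWith(line, "#") || !nzchar(trimws(line))) next
    if (is.null(section)) next
    if (section == "filter parameters")
      out$filter_parameters <- kv(out$filter_parameters, line)
    else if (section == "filter cascade") {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (identical(f[1], "step")) next
      row <- data.frame(step = f[1], considered = as.integer(f[2]),
                        accepted = as.integer(f[3]),
                        rejected = as.integer(f[4]), stringsAsFactors = FALSE)
      out$cascade <- rbind(out$cascade, row)
    } else if (section == "clustering")
      out$clustering <- kv(out$clustering, line)
    else if (section == "annotation")
      out$annotation <- kv(out$annotation, line)
  }
  out
}

write_summary <- function(report, path) {
  lines <- c("otupipe run summary", "")
  if (!is.null(report$stats)) {
    final <- report$stats$accepted[nrow(report$stats)]
    lines <- c(lines,
               sprintf("reads considered\t%d", report$stats$considered[1]),
               sprintf("reads accepted\t%d", final),
               sprintf("reads rejected\t%d",
                       report$stats$considered[1] - final))
  }
  if (!is.null(report$clustering_summary))
    lines <- c(lines,
               sprintf("clusters\t%s", report$clustering_summary[["n_clusters"]]),
               sprintf("singletons\t%s", report$clustering_summary[["n_singletons"]]))
  if (!is.null(report$annotation_summary))
    lines <- c(lines,
               sprintf("OTUs with BLAST hit\t%s",
                       report$annotation_summary[["n_otus_with_hit"]]))
  writeLines(lines, path)
  invisible(path)
}
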