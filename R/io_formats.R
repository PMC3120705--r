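# Readers and writers for the file formats the pipeline touches:
# multi-record FASTA (optionally inside a ZIP archive), the tag/primer/adaptor
# (TPA) definition file, the sample metadata file, and TSV reports.

#' Construct a table of sequence records
#'
#' The pipeline's working representation of reads is a plain data frame with
#' columns `id`, `description`, `sequence` and `source_file`. Sequences are
#' uppercased and validated against the IUPAC nucleotide alphabet.
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param sequence character vector of nucleotide strings.
#' @param description free-text descriptions (default empty).
#' @param source_file originating file name (default `NA`).
#' @return a `data.frame` with class `seq_records`.
#' @export
seq_records <- function(id, sequence, description = "", source_file = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(id)) || any(grepl("\\s", id)))
    stop("record ids must be non-empty and contain no whitespace")
  if (any(!nzchar(sequence))) {
    bad <- id[!nzchar(sequence)][1]
    stop(sprintf("record '%s' has an empty sequence", bad))
  }
  pos <- vapply(sequence, first_invalid_pos, integer(1), USE.NAMES = FALSE)
  if (any(pos >= 0)) {
    i <- which(pos >= 0)[1]
    stop(sprintf(
      "record '%s': non-IUPAC character '%s' at position %d (0-based)",
      id[i], substr(sequence[i], pos[i] + 1, pos[i] + 1), pos[i]))
  }
  out <- data.frame(id = id,
                    description = rep_len(as.character(description), length(id)),
                    sequence = sequence,
                    source_file = rep_len(as.character(source_file), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

# Parse one plain FASTA file into a seq_records data frame.
read_fasta_one <- function(path, source_file = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("cannot parse FASTA '%s': %s",
                                 path, conditionMessage(e))))
  if (length(set) == 0) stop(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id))
    stop(sprintf("duplicate record id '%s' in %s",
                 id[duplicated(id)][1], path))
  seq <- gsub("[ \t\r]", "", as.character(set))
  seq_records(id, seq, description, source_file)
}

#' Read amplicon reads from FASTA files or a ZIP archive
#'
#' Accepts a single FASTA file, a character vector of FASTA files, or a ZIP
#' archive whose members are FASTA files. Wrapped sequence lines are
#' concatenated, sequences uppercased, and `source_file` records the file
#' each read came from. When records pooled from several files share an id,
#' the colliding ids are disambiguated by prefixing the source file name
#' (ids must be unique across a run because clustering and the abundance
#' matrices key on them).
#'
#' @param path path(s) to FASTA file(s), or one `.zip` archive.
#' @return a [seq_records] data frame, in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) >= 1)
  if (length(path) == 1 && grepl("\\.zip$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    exdir <- tempfile("fastazip")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE))
    members <- unzip(path, exdir = exdir)
    members <- members[!dir.exists(members)]
    if (length(members) == 0) stop(sprintf("zip archive '%s' is empty", path))
    parts <- lapply(sort(members), function(p) read_fasta_one(p, basename(p)))
  } else {
    parts <- lapply(path, function(p) read_fasta_one(p, basename(p)))
  }
  out <- do.call(rbind, parts)
  if (anyDuplicated(out$id)) {
    dup <- unique(out$id[duplicated(out$id)])
    hit <- out$id %in% dup
    out$id[hit] <- paste(out$source_file[hit], out$id[hit], sep = "|")
    if (anyDuplicated(out$id))
      stop(sprintf("duplicate record id '%s' within one file after pooling",
                   out$id[duplicated(out$id)][1]))
  }
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Write sequence records as FASTA
#'
#' Round-trips with [read_fasta()]: ids, descriptions and sequences are
#' preserved exactly. Sequences are written unwrapped.
#'
#' @param records a [seq_records] data frame (may have zero rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  desc <- records$description %||% rep("", nrow(records))
  header <- paste0(">", records$id,
                   ifelse(nzchar(desc), paste0(" ", desc), ""))
  lines <- as.vector(rbind(header, records$sequence))
  writeLines(lines, path)
  invisible(path)
}

# ---- TPA (tags / primers / adaptors) -------------------------------------

#' Construct a tag/primer/adaptor configuration
#'
#' @param tags data frame with columns `name`, `sequence` (one row per tag).
#' @param forward_primer forward primer sequence (IUPAC letters allowed), or
#'   `NULL`.
#' @param reverse_primer reverse primer sequence, or `NULL`.
#' @param adaptors character vector of adaptor sequences (may be empty).
#' @return an object of class `tpa_config`.
#' @export
tpa_config <- function(tags, forward_primer = NULL, reverse_primer = NULL,
                       adaptors = character()) {
  stopifnot(is.data.frame(tags), all(c("name", "sequence") %in% names(tags)))
  tags$name <- as.character(tags$name)
  tags$sequence <- toupper(as.character(tags$sequence))
  if (anyDuplicated(tags$name))
    stop(sprintf("duplicate tag name '%s'", tags$name[duplicated(tags$name)][1]))
  if (anyDuplicated(tags$sequence))
    stop(sprintf("duplicate tag sequence '%s'",
                 tags$sequence[duplicated(tags$sequence)][1]))
  for (s in c(tags$sequence, forward_primer, reverse_primer, adaptors)) {
    p <- first_invalid_pos(toupper(s))
    if (p >= 0) stop(sprintf("non-IUPAC character in '%s' at position %d", s, p))
  }
  if (nrow(tags) > 1 && length(unique(nchar(tags$sequence))) > 1)
    warning("tag sequences have unequal lengths")
  structure(list(tags = tags[, c("name", "sequence")],
                 forward_primer = if (!is.null(forward_primer)) toupper(forward_primer),
                 reverse_primer = if (!is.null(reverse_primer)) toupper(reverse_primer),
                 adaptors = toupper(adaptors)),
            class = "tpa_config")
}

#' Read a TPA definition file
#'
#' The TPA file is tab- (or whitespace-) separated with three columns:
#' `role` (one of `TAG`, `FP`, `RP`, `ADAPTOR`), `name` (use `-` for rows
#' without a meaningful name) and `sequence`. Lines starting with `#` are
#' comments.
#'
#' @param path path to the TPA file.
#' @return a [tpa_config] object.
#' @export
read_tpa <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tags <- list(); fp <- NULL; rp <- NULL; adaptors <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "[\t ]+")[[1]]
    if (length(fields) != 3)
      stop(sprintf("malformed TPA row %d: expected 3 columns (role, name, sequence), got %d",
                   i, length(fields)))
    role <- toupper(fields[1])
    if (role == "TAG") {
      tags[[length(tags) + 1]] <- data.frame(name = fields[2],
                                             sequence = fields[3],
                                             stringsAsFactors = FALSE)
    } else if (role == "FP") {
      if (!is.null(fp)) stop("multiple FP rows in TPA file")
      fp <- fields[3]
    } else if (role == "RP") {
      if (!is.null(rp)) stop("multiple RP rows in TPA file")
      rp <- fields[3]
    } else if (role == "ADAPTOR") {
      adaptors <- c(adaptors, fields[3])
    } else {
      stop(sprintf("unknown TPA role '%s' on row %d (expected TAG, FP, RP or ADAPTOR)",
                   fields[1], i))
    }
  }
  if (length(tags) == 0) stop("TPA file defines no tags")
  tpa_config(do.call(rbind, tags), fp, rp, adaptors)
}

#' Write a TPA definition file
#'
#' @param tpa a [tpa_config] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tpa <- function(tpa, path) {
  stopifnot(inherits(tpa, "tpa_config"))
  rows <- c(sprintf("TAG\t%s\t%s", tpa$tags$name, tpa$tags$sequence),
            if (!is.null(tpa$forward_primer)) sprintf("FP\t-\t%s", tpa$forward_primer),
            if (!is.null(tpa$reverse_primer)) sprintf("RP\t-\t%s", tpa$reverse_primer),
            if (length(tpa$adaptors)) sprintf("ADAPTOR\t-\t%s", tpa$adaptors))
  writeLines(rows, path)
  invisible(path)
}

# ---- sample metadata ------------------------------------------------------

#' Construct a sample map
#'
#' Maps `(source file, tag name)` pairs to sample identifiers. A row whose
#' tag name is `*` maps every tag in that file to one sample.
#'
#' @param entries data frame with columns `file`, `tag`, `sample`.
#' @return an object of class `sample_map`.
#' @export
sample_map <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("file", "tag", "sample") %in% names(entries)))
  entries <- unique(entries[, c("file", "tag", "sample")])
  if (any(!nzchar(entries$sample))) stop("sample ids must be non-empty")
  key <- paste(entries$file, entries$tag, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("conflicting sample assignments for (file, tag) = (%s)",
                 gsub("\r", ", ", dup)))
  }
  structure(list(entries = entries), class = "sample_map")
}

#' Read the sample metadata file
#'
#' Tab- (or whitespace-) separated columns `filename`, `tag_name`,
#' `sample_id`; `#` lines are comments. Row order is irrelevant.
#'
#' @param path path to the metadata file.
#' @return a [sample_map] object.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "[\t ]+")[[1]]
    if (length(fields) != 3)
      stop(sprintf("malformed metadata row %d: expected 3 columns, got %d",
                   i, length(fields)))
    data.frame(file = fields[1], tag = fields[2], sample = fields[3],
               stringsAsFactors = FALSE)
  })
  sample_map(do.call(rbind, rows))
}

#' Write a sample metadata file
#' @param map a [sample_map] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(map, path) {
  stopifnot(inherits(map, "sample_map"))
  writeLines(sprintf("%s\t%s\t%s", map$entries$file, map$entries$tag,
                     map$entries$sample), path)
  invisible(path)
}

#' Resolve the sample for a (file, tag) pair
#'
#' An unmapped pair resolves to the explicit value `"unassigned"`, never a
#' silent default.
#'
#' @param map a [sample_map] object, or `NULL` (then the tag name itself is
#'   used as the sample id).
#' @param file source file name(s).
#' @param tag tag name(s); `NA` resolves to `"unassigned"`.
#' @return character vector of sample ids.
#' @export
sample_lookup <- function(map, file, tag) {
  n <- max(length(file), length(tag))
  file <- rep_len(as.character(file), n)
  tag <- rep_len(as.character(tag), n)
  if (is.null(map)) return(ifelse(is.na(tag), "unassigned", tag))
  stopifnot(inherits(map, "sample_map"))
  e <- map$entries
  exact <- match(paste(file, tag, sep = "\r"), paste(e$file, e$tag, sep = "\r"))
  wild <- match(paste(file, "*", sep = "\r"), paste(e$file, e$tag, sep = "\r"))
  idx <- ifelse(is.na(exact), wild, exact)
  out <- ifelse(is.na(idx) | is.na(tag), "unassigned", e$sample[idx])
  out
}
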