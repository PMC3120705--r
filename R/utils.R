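# Shared internal helpers.

IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "N",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Reverse-complement nucleotide strings
#'
#' IUPAC ambiguity letters are complemented to their counterparts.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random DNA string(s), uses the current RNG stream.
random_dna <- function(n) {
  vapply(n, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Validate one sequence against the IUPAC alphabet; returns the 0-based
# position of the first offending character, or -1L when clean.
first_invalid_pos <- function(sequence) {
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")),
                 sequence)[1]
  if (bad < 0) -1L else bad - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal store-only ZIP writer ---------------------------------------
# The archive members are stored uncompressed (method 0). Sufficient for the
# small per-cluster FASTA bundles this package emits, and fully readable by
# standard unzip tools and utils::unzip().

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        }
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(raw_bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(raw_bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(tab[idx + 1], bitwShiftR(bitwAnd(crc, -256L), 8))
  }
  bitwXor(crc, -1L)
}

int_le <- function(x, bytes) {
  # little-endian unsigned encoding of a (possibly negative-wrapped) integer
  out <- raw(bytes)
  v <- as.double(x)
  if (v < 0) v <- v + 2^32
  for (i in seq_len(bytes)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

# files: named character vector, names = member names, values = paths
write_zip_store <- function(files, zip_path) {
  con <- file(zip_path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  centrals <- list()
  offset <- 0
  for (i in seq_along(files)) {
    name <- names(files)[i]
    data <- readBin(files[[i]], "raw", n = file.info(files[[i]])$size)
    crc <- crc32(data)
    nm <- charToRaw(name)
    local_hdr <- c(int_le(0x04034b50, 4), int_le(20, 2), int_le(0, 2),
                   int_le(0, 2), int_le(0, 2), int_le(0, 2),
                   int_le(crc, 4), int_le(length(data), 4),
                   int_le(length(data), 4), int_le(length(nm), 2),
                   int_le(0, 2))
    writeBin(c(local_hdr, nm, data), con)
    centrals[[i]] <- c(int_le(0x02014b50, 4), int_le(20, 2), int_le(20, 2),
                       int_le(0, 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
                       int_le(crc, 4), int_le(length(data), 4),
                       int_le(length(data), 4), int_le(length(nm), 2),
                       int_le(0, 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
                       int_le(0, 4), int_le(offset, 4), nm)
    offset <- offset + length(local_hdr) + length(nm) + length(data)
  }
  cd_start <- offset
  for (cd in centrals) {
    writeBin(cd, con)
    offset <- offset + length(cd)
  }
  eocd <- c(int_le(0x06054b50, 4), int_le(0, 2), int_le(0, 2),
            int_le(length(files), 2), int_le(length(files), 2),
            int_le(offset - cd_start, 4), int_le(cd_start, 4), int_le(0, 2))
  writeBin(eocd, con)
  invisible(zip_path)
}
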