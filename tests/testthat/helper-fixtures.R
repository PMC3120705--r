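# Fixture builders: a small fixed TPA configuration and read assembly with
# the expected amplicon layout tag + FP + target + rc(RP) + rc(tag) +
# adaptor. All fixtures are built in code at test time.

FIX_FP <- "GGAAGTAAAAGTCGTAACAAGG"
FIX_RP <- "GCTGCGTTCTTCATCGATGC"
FIX_ADAPTOR <- "CTGAGACTGCCAAGGCACACAGG"
FIX_TAGS <- c(A = "ACGTACGT", B = "TTGGCCAA", C = "GACTGACT", D = "CCAATTGG")

make_tpa <- function(tags = FIX_TAGS, fp = FIX_FP, rp = FIX_RP,
                     adaptors = FIX_ADAPTOR) {
  tpa_config(data.frame(name = names(tags), sequence = unname(tags),
                        stringsAsFactors = FALSE),
             forward_primer = fp, reverse_primer = rp, adaptors = adaptors)
}

# Assemble one read in the standard layout; pieces can be dropped.
build_read <- function(target, tag = FIX_TAGS[["A"]], tag3 = tag,
                       fp = FIX_FP, rp = FIX_RP, adaptor = FIX_ADAPTOR) {
  paste0(tag, fp, target,
         if (!is.null(rp)) revcomp(rp) else "",
         if (!is.null(tag3)) revcomp(tag3) else "",
         if (!is.null(adaptor)) adaptor else "")
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fas")) {
  write_fasta(records, path)
  path
}
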