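#' Write aligned reads to a SAM file
#'
#' Emits a valid SAM 1.6 file: `@SQ` lines matching the reference set,
#' substitution-only CIGAR (`<len>M`), fixed MAPQ 60, FLAG bit 0x10 for
#' reverse-strand reads. Per SAM convention, reverse-strand reads are
#' stored reference-oriented (sequence reverse-complemented, qualities
#' reversed relative to sequencing order).
#'
#' @param reads an `aligned_reads` object.
#' @param ref the `spike_ref` the reads were simulated from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ref, path) {
  r <- ref$records
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", r$id, r$length),
    sprintf("@RG\tID:%s", reads$read_group %||% "RG1")
  )
  n <- nrow(reads$seq)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  ro <- ref_oriented(reads)
  L <- reads$read_len
  seqs <- vapply(seq_len(n), function(i) int_dna(ro$bases[i, ]), character(1))
  quals <- vapply(seq_len(n), function(i) intToUtf8(ro$qual[i, ] + 33L), character(1))
  body <- paste(
    sprintf("r%06d", seq_len(n)),
    ifelse(reads$rev, 16L, 0L),
    reads$ref_ids[reads$rec],
    reads$start + 1L,
    60L,
    paste0(L, "M"),
    "*", 0L, 0L,
    seqs, quals,
    paste0("RG:Z:", reads$read_group %||% "RG1"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an aligned read set
#'
#' A deliberately narrow reader for the substitution-only alignments this
#' package produces and consumes: only reads with an all-match CIGAR and a
#' mapped position are kept (others are skipped with a message), and all
#' kept reads must share one read length. Reverse-strand reads are
#' converted back to sequencing orientation internally.
#'
#' @param path SAM path.
#' @param ref optional `spike_ref`; if given, read reference names are
#'   validated against it.
#' @return An `aligned_reads` object (without a truth sidecar).
#' @export
read_sam <- function(path, ref = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ids <- vapply(strsplit(sq, "\t", fixed = TRUE), function(x) {
    sub("^SN:", "", x[startsWith(x, "SN:")][1])
  }, character(1))
  if (!is.null(ref)) {
    missing <- setdiff(ids, ref$records$id)
    if (length(missing)) stop_data("SAM references absent from reference set: ",
                                   paste(missing, collapse = ", "))
    ids <- ref$records$id
  }
  empty <- structure(list(
    ref_ids = ids, rec = integer(), start = integer(), rev = logical(),
    mate = integer(), seq = matrix(integer(), 0, 0), qual = matrix(integer(), 0, 0),
    read_group = "RG1", read_len = 0L,
    truth = data.frame(read = integer(), cycle = integer(), ref_id = character(),
                       ref_pos = integer(), type = character(), stringsAsFactors = FALSE)
  ), class = "aligned_reads")
  if (length(body) == 0L) return(empty)
  f <- strsplit(body, "\t", fixed = TRUE)
  cig <- vapply(f, `[[`, character(1), 6L)
  ok <- grepl("^[0-9]+M$", cig)
  if (any(!ok)) {
    message("read_sam: skipping ", sum(!ok), " read(s) without an all-match CIGAR")
    f <- f[ok]
  }
  if (length(f) == 0L) return(empty)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  rname <- vapply(f, `[[`, character(1), 3L)
  pos <- as.integer(vapply(f, `[[`, character(1), 4L))
  seqs <- vapply(f, `[[`, character(1), 10L)
  quals <- vapply(f, `[[`, character(1), 11L)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop_data("read_sam: mixed read lengths are not supported")
  rec <- match(rname, ids)
  if (anyNA(rec)) stop_data("SAM reads reference unknown ids: ",
                            paste(unique(rname[is.na(rec)]), collapse = ", "))
  n <- length(f)
  rev <- bitwAnd(flag, 16L) > 0L
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  R <- matrix(unlist(lapply(seqs, dna_int), use.names = FALSE), n, L, byrow = TRUE)
  Qr <- matrix(unlist(lapply(quals, function(s) utf8ToInt(s) - 33L),
                      use.names = FALSE), n, L, byrow = TRUE)
  S <- R
  Q <- Qr
  if (any(rev)) {
    S[rev, ] <- 5L - R[rev, L:1, drop = FALSE]
    Q[rev, ] <- Qr[rev, L:1, drop = FALSE]
  }
  rg_field <- f[[1]][startsWith(f[[1]], "RG:Z:")]
  rg <- if (length(rg_field)) sub("^RG:Z:", "", rg_field[1]) else "RG1"
  structure(list(
    ref_ids = ids, rec = rec, start = pos - 1L, rev = rev, mate = mate,
    seq = S, qual = Q, read_group = rg, read_len = L, truth = empty$truth
  ), class = "aligned_reads")
}
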