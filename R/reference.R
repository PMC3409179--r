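#' Generate a synthetic spike-in reference set
#'
#' Builds an ERCC-style collection of plasmid records: random "standard"
#' insert sequences of i.i.d. bases placed inside a shared vector backbone.
#' The vector sequence is generated once and reused for every record,
#' mirroring a common cloning backbone; the inserts are independent random
#' sequence with the requested GC fraction.
#'
#' @param n_inserts number of records (plasmids) to generate.
#' @param insert_len_range length-2 integer vector `(min, max)`; insert
#'   lengths are drawn i.i.d. uniformly on `min:max`.
#' @param vector_len length in bp of the shared vector backbone (may be 0
#'   for vector-free records such as in vitro transcripts).
#' @param gc_fraction target GC fraction of generated bases, in `[0, 1]`.
#' @param seed integer seed; identical seeds reproduce the set exactly.
#' @return An object of class `spike_ref`: a list with `records`
#'   (data frame: `id`, `length`, `insert_start`, `insert_end` 0-based
#'   half-open, `vector_len`) and `sequences` (named character vector).
#' @examples
#' ref <- generate_reference(4, c(300, 500), vector_len = 100, seed = 1)
#' ref$records
#' @export
generate_reference <- function(n_inserts, insert_len_range = c(273L, 2022L),
                               vector_len = 2800L, gc_fraction = 0.5, seed) {
  n_inserts <- check_count(n_inserts, "n_inserts")
  if (length(insert_len_range) != 2L) stop_invalid("insert_len_range must have length 2")
  lo <- check_count(insert_len_range[1], "insert_len_range[1]")
  hi <- check_count(insert_len_range[2], "insert_len_range[2]", min = lo)
  if (length(vector_len) != 1L || vector_len < 0 || vector_len != floor(vector_len)) {
    stop_invalid("vector_len must be a single non-negative integer")
  }
  vector_len <- as.integer(vector_len)
  gc_fraction <- check_fraction(gc_fraction, "gc_fraction")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2, (1 - gc_fraction) / 2)

  with_seed(seed, {
    vec <- if (vector_len > 0) sample.int(4L, vector_len, replace = TRUE, prob = p) else integer()
    pre_len <- vector_len %/% 2L
    pre <- vec[seq_len(pre_len)]
    post <- vec[seq_len(vector_len - pre_len) + pre_len]
    lens <- lo + sample.int(hi - lo + 1L, n_inserts, replace = TRUE) - 1L
    ids <- sprintf("SPIKE_%03d", seq_len(n_inserts))
    seqs <- vapply(lens, function(L) {
      int_dna(c(pre, sample.int(4L, L, replace = TRUE, prob = p), post))
    }, character(1))
    names(seqs) <- ids
    records <- data.frame(
      id = ids,
      length = lens + vector_len,
      insert_start = pre_len,
      insert_end = pre_len + lens,
      vector_len = vector_len,
      stringsAsFactors = FALSE
    )
    structure(list(records = records, sequences = seqs), class = "spike_ref")
  })
}

#' @export
print.spike_ref <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<spike_ref> %d records, %d bp total (%d insert bp, vector %d bp)\n",
    nrow(r), sum(r$length), sum(r$insert_end - r$insert_start),
    if (nrow(r)) r$vector_len[1] else 0L
  ))
  invisible(x)
}

# internal: integer-coded sequences concatenated, with per-record offsets
ref_flat <- function(ref) {
  lens <- nchar(ref$sequences)
  codes <- unlist(lapply(unname(ref$sequences), dna_int), use.names = FALSE)
  list(
    codes = codes,
    lens = as.integer(lens),
    # 0-based offset of each record within the concatenation
    offset = c(0L, cumsum(as.integer(lens)))[seq_along(lens)],
    ids = ref$records$id
  )
}

#' Enumerate reference positions
#'
#' Lists every position of a reference set (optionally restricted to the
#' insert spans) as a data frame of 0-based coordinates, the canonical
#' "site set" currency used by masks and purity calls.
#'
#' @param ref a `spike_ref`.
#' @param insert_only if `TRUE`, only positions inside the insert spans.
#' @return data frame with columns `id`, `pos` (0-based).
#' @export
all_reference_positions <- function(ref, insert_only = FALSE) {
  r <- ref$records
  pos <- lapply(seq_len(nrow(r)), function(i) {
    if (insert_only) seq.int(r$insert_start[i], r$insert_end[i] - 1L)
    else seq.int(0L, r$length[i] - 1L)
  })
  data.frame(
    id = rep(r$id, lengths(pos)),
    pos = as.integer(unlist(pos)),
    stringsAsFactors = FALSE
  )
}

#' Assign pool concentrations to a reference set
#'
#' Emulates the two pooling designs used with spike-in standards:
#' equimolar pools, and pools spanning a large dynamic range of molar
#' concentrations. Dynamic-range weights are log-uniform with the two
#' endpoints pinned so that `max(w)/min(w)` equals `span` exactly.
#'
#' @param ref a `spike_ref`.
#' @param mode `"equimolar"` or `"dynamic_range"`.
#' @param span ratio of largest to smallest weight (dynamic range), >= 1.
#' @param seed integer seed (required for `dynamic_range` with > 2 records).
#' @return A `pool_profile`: named numeric weights summing to 1.
#' @export
assign_concentrations <- function(ref, mode = c("equimolar", "dynamic_range"),
                                  span = 1e6, seed = NULL) {
  mode <- match.arg(mode)
  n <- nrow(ref$records)
  ids <- ref$records$id
  if (mode == "equimolar") {
    w <- rep(1 / n, n)
  } else {
    if (length(span) != 1L || !is.numeric(span) || is.na(span) || span < 1) {
      stop_invalid("span must be a single number >= 1")
    }
    if (n == 1L) {
      w <- 1
    } else {
      w <- with_seed(seed, {
        u <- stats::runif(n)
        ends <- sample.int(n, 2L)
        u[ends[1]] <- 0
        u[ends[2]] <- 1
        exp(u * log(span))
      })
      w <- w / sum(w)
    }
  }
  names(w) <- ids
  structure(w, class = "pool_profile", mode = mode, span = if (mode == "dynamic_range") span else 1)
}

#' @export
print.pool_profile <- function(x, ...) {
  cat(sprintf(
    "<pool_profile> %d records, mode=%s, max/min=%.4g\n",
    length(x), attr(x, "mode"), max(x) / min(x)
  ))
  invisible(x)
}

#' Write a reference set to FASTA (with a manifest sidecar)
#'
#' Sequences are written wrapped at 70 columns. Insert spans (and pool
#' weights, if a profile is supplied) are persisted in a tab-separated
#' manifest so that [read_fasta()] round-trips the full object.
#'
#' @param ref a `spike_ref`.
#' @param path output FASTA path.
#' @param pool optional `pool_profile` whose weights go into the manifest.
#' @param manifest manifest path; default `<path>.manifest.tsv`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path, pool = NULL,
                        manifest = paste0(path, ".manifest.tsv")) {
  xs <- Biostrings::DNAStringSet(ref$sequences)
  Biostrings::writeXStringSet(xs, filepath = path, width = 70L)
  m <- ref$records[, c("id", "insert_start", "insert_end", "vector_len")]
  m$weight <- if (is.null(pool)) NA_real_ else as.numeric(pool[m$id])
  utils::write.table(m, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference set from FASTA
#'
#' Lowercase bases are uppercased (with a message); characters outside
#' A/C/G/T are rejected. If the manifest written by [write_fasta()] is
#' present it restores insert spans, otherwise each whole sequence is
#' treated as insert.
#'
#' @param path FASTA path.
#' @param manifest manifest path, or `NULL` to look for the default.
#' @return A `spike_ref`.
#' @export
read_fasta <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(structure(list(
      records = data.frame(
        id = character(), length = integer(), insert_start = integer(),
        insert_end = integer(), vector_len = integer(), stringsAsFactors = FALSE
      ),
      sequences = stats::setNames(character(), character())
    ), class = "spike_ref"))
  }
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first) || !startsWith(lines[first], ">")) {
    stop_data("malformed FASTA at line ", first %||% 1L, ": expected '>' header")
  }
  # detect lowercase on the raw lines (DNAStringSet normalises case)
  if (any(grepl("[acgt]", lines[!startsWith(lines, ">")]))) {
    message("read_fasta: lowercase bases found; uppercasing")
  }
  xs <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(xs))
  ids <- sub("\\s.*$", "", names(xs))
  names(seqs) <- ids
  if (anyDuplicated(ids)) stop_data("duplicate record ids in ", path)
  if (any(grepl("[^ACGT]", seqs))) {
    bad <- ids[grepl("[^ACGT]", seqs)][1]
    stop_data("sequence ", bad, " contains characters outside A/C/G/T")
  }
  lens <- nchar(seqs)
  manifest <- manifest %||% paste0(path, ".manifest.tsv")
  if (file.exists(manifest)) {
    m <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    m <- m[match(ids, m$id), ]
    records <- data.frame(
      id = ids, length = as.integer(lens),
      insert_start = as.integer(m$insert_start),
      insert_end = as.integer(m$insert_end),
      vector_len = as.integer(m$vector_len),
      stringsAsFactors = FALSE
    )
  } else {
    records <- data.frame(
      id = ids, length = as.integer(lens),
      insert_start = 0L, insert_end = as.integer(lens),
      vector_len = 0L, stringsAsFactors = FALSE
    )
  }
  structure(list(records = records, sequences = seqs), class = "spike_ref")
}
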