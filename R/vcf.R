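#' Write the exclusion mask of a purity call set as VCF
#'
#' Emits one record per non-high-purity base, 1-based `POS`, with the
#' exclusion reason in `INFO` as `VERDICT=` one of `LOWCOV`, `IMPURE`,
#' `ENDSKIP`, `POLYA`. The file is a minimal but valid VCF 4.2 readable by
#' standard VCF parsers and by [read_site_vcf()].
#'
#' @param calls a `purity_calls` data frame from [classify_bases()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_vcf <- function(calls, path) {
  bad <- calls[calls$verdict != "high_purity", , drop = FALSE]
  if (nrow(bad) == 0L) {
    return(write_site_vcf(data.frame(id = character(), pos = integer()), path))
  }
  verdict_code <- c(
    low_coverage = "LOWCOV", impure = "IMPURE",
    ENDSKIP = "ENDSKIP", POLYA = "POLYA"
  )[bad$verdict]
  write_site_vcf(
    data.frame(
      id = bad$id, pos = bad$pos, ref = bad$ref,
      info = paste0("VERDICT=", verdict_code), stringsAsFactors = FALSE
    ),
    path
  )
}

#' Write a site set as a minimal VCF
#'
#' @param sites data frame with `id`, `pos` (0-based) and optionally
#'   `ref`, `alt`, `info` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_vcf <- function(sites, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VERDICT,Number=1,Type=String,Description=\"Exclusion reason\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(sites) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  body <- paste(
    sites$id, sites$pos + 1L, ".",
    if (is.null(sites$ref)) "N" else sites$ref,
    if (is.null(sites$alt)) "." else sites$alt,
    ".", ".",
    if (is.null(sites$info)) "." else sites$info,
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a site set from a VCF
#'
#' Reads `CHROM`/`POS` (and the `VERDICT` INFO key if present) from a
#' plain-text VCF; positions are returned 0-based, the package's internal
#' coordinate convention.
#'
#' @param path VCF path.
#' @return data frame `id`, `pos` (0-based), `verdict` (NA when absent).
#' @export
read_site_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) {
    return(data.frame(id = character(), pos = integer(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, function(x) if (length(x) >= 8L) x[8] else ".", character(1))
  verdict <- ifelse(grepl("VERDICT=", info, fixed = TRUE),
                    sub(".*VERDICT=([^;]+).*", "\\1", info), NA_character_)
  data.frame(
    id = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)) - 1L,
    verdict = verdict, stringsAsFactors = FALSE
  )
}
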