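#' Genomic regions
#'
#' Regions are represented as a plain `data.frame` with columns `chrom`,
#' `start`, `end` using the BED convention throughout: 0-based, half-open
#' `[start, end)`. A region is the atomic "word" of the embedding model.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts (bp).
#' @param end integer vector, 0-based exclusive ends (bp).
#' @return a validated regions `data.frame`.
#' @examples
#' genomic_regions("chr1", 100, 500)
#' @export
genomic_regions <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  validate_regions(df)
  df
}

validate_regions <- function(df, where = "regions") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop_fmt("%s: non-integer coordinates", where)
  bad <- which(df$end <= df$start | df$start < 0 | !nzchar(df$chrom))
  if (length(bad))
    stop_fmt("%s: invalid interval at line %d (start=%s, end=%s)",
             where, bad[1], df$start[bad[1]], df$end[bad[1]])
  invisible(df)
}

#' Convert a region to its word token and back
#'
#' The model treats each interval as a token `"chrom_start_end"`, joining the
#' chromosome, start and end with underscores. Chromosome names may themselves
#' contain underscores (e.g. unplaced scaffolds); parsing therefore splits on
#' the *last two* underscores.
#'
#' @param regions regions `data.frame` (see [genomic_regions()]).
#' @return `region_to_word`: character vector of tokens.
#' @examples
#' region_to_word(genomic_regions("chr1", 100, 500))  # "chr1_100_500"
#' word_to_region("chr1_gl000191_10_20")
#' @export
region_to_word <- function(regions) {
  sprintf("%s_%d_%d", regions$chrom, as.integer(regions$start), as.integer(regions$end))
}

#' @rdname region_to_word
#' @param words character vector of `"chrom_start_end"` tokens.
#' @return `word_to_region`: regions `data.frame`.
#' @export
word_to_region <- function(words) {
  m <- regmatches(words, regexec("^(.+)_([0-9]+)_([0-9]+)$", words))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad))
    stop_fmt("cannot parse region word(s): %s",
             paste(utils::head(words[bad], 3), collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  start <- as.integer(vapply(m, `[`, "", 3L))
  end <- as.integer(vapply(m, `[`, "", 4L))
  genomic_regions(chrom, start, end)
}

#' Read and write BED interval files
#'
#' `read_bed()` reads the first three columns of a BED3+ file (extra columns
#' are ignored); `write_bed()` writes a three-column BED. Coordinates stay in
#' the file's native 0-based half-open convention.
#'
#' @param path file path.
#' @return `read_bed`: regions `data.frame`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop_fmt("%s: BED needs >= 3 columns, found %d", path, ncol(dt))
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop_fmt("%s: unparseable BED line %d", path, bad[1])
  df <- data.frame(chrom = as.character(dt[[1]]), start = start, end = end,
                   stringsAsFactors = FALSE)
  bad <- which(df$end <= df$start | df$start < 0)
  if (length(bad))
    stop_fmt("%s: invalid interval at line %d (start >= end)", path, bad[1])
  df
}

#' @rdname read_bed
#' @param regions regions `data.frame` to write.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  data.table::fwrite(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
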