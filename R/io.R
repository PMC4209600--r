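#' Read UTR sequences from FASTA
#'
#' @param path FASTA file; record ids (first whitespace token) are
#'   transcript ids.
#' @return Named character vector of sequences.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_utr_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a two-condition counts table
#'
#' Expects a TSV with header columns `gene`, `count_vector`,
#' `count_mir155`, `exon_length_bp` (extra columns are kept; lines
#' starting with `#` are ignored).
#'
#' @param path TSV file.
#' @return data.frame of counts.
#' @export
read_counts_table <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "count_vector", "count_mir155", "exon_length_bp")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop(sprintf("counts table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  d
}

#' Write a TSV with a commented metadata line
#'
#' All pipeline outputs share this format: one `#`-prefixed metadata line
#' (package version plus caller-supplied `key=value` fields, no
#' timestamps, so outputs are byte-reproducible), then a header row and
#' tab-separated records.
#'
#' @param d data.frame.
#' @param path Output file.
#' @param meta Named character/numeric vector of metadata fields.
#' @export
write_tsv <- function(d, path, meta = NULL) {
  fields <- c(sprintf("mirEscape=%s", as.character(utils::packageVersion("mirEscape"))),
              if (length(meta)) sprintf("%s=%s", names(meta), as.character(meta)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("#", paste(fields, collapse = " ")), con)
  dd <- as.data.frame(lapply(d, function(x) {
    if (is.double(x)) format(x, scientific = FALSE, trim = TRUE, digits = 15)
    else as.character(x)
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(dd) <- names(d)
  utils::write.table(dd, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models (BED12 or GFF3)
#'
#' BED is treated as 0-based half-open and GFF3 as 1-based inclusive;
#' `rtracklayer` performs both conversions at import, so the returned
#' `GRanges` uses standard 1-based Bioconductor coordinates. Each record
#' is one 3'UTR model; BED12 block structure is preserved in a `blocks`
#' column when present.
#'
#' @param path `.bed` or `.gff`/`.gff3` file (format inferred from the
#'   extension).
#' @return `GRanges` with a `name` column of transcript ids.
#' @export
read_transcript_models <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (is.null(gr$name)) {
    id <- if (!is.null(gr$ID)) gr$ID else names(gr)
    gr$name <- id
  }
  if (is.null(gr$name) || anyNA(gr$name)) {
    stop("transcript models must carry names/IDs", call. = FALSE)
  }
  gr
}

#' Write single-block BED12 transcript models
#'
#' @param models data.frame with columns `chrom`, `start` (0-based),
#'   `end`, `name`, `strand`.
#' @param path Output file.
#' @export
write_bed12 <- function(models, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(models)))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                   models$chrom, models$start, models$end, models$name,
                   models$strand, models$start, models$end,
                   models$end - models$start)
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-base coverage list as bedGraph
#'
#' Runs of equal coverage are collapsed to intervals (0-based half-open,
#' bedGraph convention). Track names are used as chromosome names, i.e.
#' coverage is emitted in the coordinate system of the supplied models.
#'
#' @param tracks Named list of non-negative integer vectors.
#' @param path Output file.
#' @export
write_bedgraph <- function(tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(tracks)) {
    r <- rle(as.numeric(tracks[[id]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%s", id, starts, ends,
                       format(r$values, scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

#' Read per-base 3'UTR coverage from bedGraph
#'
#' Imports a bedGraph track, projects it onto each transcript model and
#' returns per-base counts oriented transcript 5'->3' (minus-strand models
#' are reversed here, at the reader boundary). Positions not covered by
#' any bedGraph interval are 0.
#'
#' @param path bedGraph file in the genomic coordinates of `models`.
#' @param models `GRanges` of 3'UTR models from [read_transcript_models()]
#'   (blocks are honoured: block pieces are concatenated 5'->3').
#' @return Named list of numeric vectors, one per model, length = UTR
#'   length.
#' @export
read_coverage <- function(path, models) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  out <- lapply(seq_along(models), function(i) {
    m <- models[i]
    chrom <- as.character(GenomicRanges::seqnames(m))
    blocks <- if (!is.null(m$blocks)) {
      IRanges::shift(m$blocks[[1]], BiocGenerics::start(m) - 1L)
    } else {
      IRanges::IRanges(BiocGenerics::start(m), BiocGenerics::end(m))
    }
    if (!chrom %in% names(cov)) {
      return(numeric(sum(BiocGenerics::width(blocks))))
    }
    rl <- cov[[chrom]]
    v <- unlist(lapply(seq_along(blocks), function(j) {
      s <- BiocGenerics::start(blocks)[j]; e <- BiocGenerics::end(blocks)[j]
      n <- length(rl)
      inb <- seq.int(s, min(e, n))
      vals <- if (s <= n) as.numeric(rl[inb]) else numeric(0)
      c(vals, numeric(max(0L, e - max(s - 1L, n))))
    }), use.names = FALSE)
    if (as.character(BiocGenerics::strand(m)) == "-") v <- rev(v)
    v
  })
  ids <- models$name
  if (is.null(ids)) ids <- names(models)
  stats::setNames(out, ids)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member symbols.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(length(descriptions) == length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Text file; blank lines and `#` comments are skipped.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
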