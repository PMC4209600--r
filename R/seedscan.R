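#' Construct a mature miRNA
#'
#' A mature miRNA is the 5'->3' guide sequence whose 5' seed region
#' (positions 2-8, 1-based miRNA convention) defines the target motifs.
#' DNA-alphabet input is accepted and normalized to RNA (T -> U).
#'
#' @param name Identifier, e.g. `"hsa-miR-155-5p"`.
#' @param sequence Guide sequence, 5'->3', alphabet ACGU (or ACGT),
#'   length >= 8.
#' @return An object of class `mature_mirna` with elements `name` and
#'   `sequence` (RNA alphabet).
#' @examples
#' mature_mirna("hsa-miR-155-5p", "UUAAUGCUAAUCGUGAUAGGGGU")
#' @export
mature_mirna <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L)
  seq <- normalize_rna(sequence, what = sprintf("miRNA '%s'", name))
  if (nchar(seq) < 8L) {
    stop(sprintf("miRNA '%s' is %d nt long; at least 8 nt are required to define a seed",
                 name, nchar(seq)), call. = FALSE)
  }
  structure(list(name = name, sequence = seq), class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat(sprintf("mature miRNA %s (%d nt)\n  5'-%s-3'\n  seed (2-8): %s\n",
              x$name, nchar(x$sequence), x$sequence,
              substr(x$sequence, 2L, 8L)))
  invisible(x)
}

# Uppercase, T->U, and validate against an allowed RNA alphabet.
normalize_rna <- function(sequence, what = "sequence", allow_n = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- chartr("t", "u", toupper(sequence))
  seq <- chartr("T", "U", seq)
  alphabet <- if (allow_n) "ACGUN" else "ACGU"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nzchar(bad)) {
    stop(sprintf("%s contains invalid characters: %s",
                 what, paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  seq
}

rna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

#' Derive canonical seed-site motifs from a mature miRNA
#'
#' Target motifs are written in mRNA sense, 5'->3':
#' * `motif_7mer_m8`: reverse complement of miRNA positions 2-8;
#' * `motif_8mer`: the 7mer-m8 motif followed by `A` (the adenosine
#'   opposite miRNA position 1, recognised regardless of the position-1
#'   nucleotide);
#' * `motif_7mer_A1`: reverse complement of positions 2-7 followed by `A`.
#'
#' @param mirna A [mature_mirna] object (or a bare sequence, which is
#'   promoted with a placeholder name).
#' @return An object of class `seed_motif_set` with elements `motif_8mer`,
#'   `motif_7mer_m8`, `motif_7mer_A1` and `mirna_name`.
#' @examples
#' derive_seed_motifs(mature_mirna("hsa-miR-155-5p", "UUAAUGCUAAUCGUGAUAGGGGU"))
#' @export
derive_seed_motifs <- function(mirna) {
  if (!inherits(mirna, "mature_mirna")) {
    mirna <- mature_mirna("miRNA", mirna)
  }
  m8 <- rna_revcomp(substr(mirna$sequence, 2L, 8L))
  structure(list(
    motif_8mer    = paste0(m8, "A"),
    motif_7mer_m8 = m8,
    motif_7mer_A1 = paste0(substr(m8, 2L, 7L), "A"),
    mirna_name    = mirna$name
  ), class = "seed_motif_set")
}

#' @export
print.seed_motif_set <- function(x, ...) {
  cat(sprintf("seed motifs for %s (mRNA sense, 5'->3')\n  8mer:    %s\n  7mer-m8: %s\n  7mer-A1: %s\n",
              x$mirna_name, x$motif_8mer, x$motif_7mer_m8, x$motif_7mer_A1))
  invisible(x)
}

#' The canonical site-type labels, 8mer first.
#' @noRd
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")

# All (possibly overlapping) 1-based match starts of a fixed pattern.
# IUPAC fixed matching: an N in the subject never matches.
match_starts <- function(pattern, subject_rna) {
  if (nchar(subject_rna) < nchar(pattern)) return(integer(0))
  BiocGenerics::start(Biostrings::matchPattern(
    Biostrings::RNAString(pattern), Biostrings::RNAString(subject_rna),
    fixed = TRUE))
}

#' Scan a 3'UTR sequence for seed sites
#'
#' Reports every match of the motif set with maximal-type labelling: a
#' position matching the full 8mer is reported once, as `8mer`, never
#' additionally as its embedded 7mer-m8 or 7mer-A1. Matches of different
#' sites may overlap each other. Coordinates are 0-based half-open offsets
#' into the UTR (transcript 5'->3'); only the given (sense) strand is
#' scanned.
#'
#' @param utr_sequence UTR sequence in ACGUN (T accepted, normalized to U;
#'   N never matches).
#' @param motifs A `seed_motif_set` from [derive_seed_motifs()].
#' @param transcript_id Identifier recorded in the output.
#' @param seven_mer Which 7mer classes to report: `"both"` (default) or
#'   `"m8_only"` (drop 7mer-A1 sites).
#' @return A data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open), `site_type`, sorted by `start`.
#' @examples
#' motifs <- derive_seed_motifs(mature_mirna("hsa-miR-155-5p",
#'                                           "UUAAUGCUAAUCGUGAUAGGGGU"))
#' scan_utr("AAGCAUUAAGG", motifs)
#' @export
scan_utr <- function(utr_sequence, motifs, transcript_id = "utr",
                     seven_mer = c("both", "m8_only")) {
  stopifnot(inherits(motifs, "seed_motif_set"))
  seven_mer <- match.arg(seven_mer)
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(utr_sequence)) return(empty)
  seq <- normalize_rna(utr_sequence, what = sprintf("UTR '%s'", transcript_id),
                       allow_n = TRUE)

  s8   <- match_starts(motifs$motif_8mer, seq)
  sm8  <- setdiff(match_starts(motifs$motif_7mer_m8, seq), s8)
  # a 7mer-A1 at position p is the tail of an 8mer starting at p - 1
  sa1  <- match_starts(motifs$motif_7mer_A1, seq)
  sa1  <- sa1[!(sa1 - 1L) %in% s8]

  starts <- c(s8, sm8, if (seven_mer == "both") sa1)
  if (!length(starts)) return(empty)
  widths <- c(rep(8L, length(s8)), rep(7L, length(sm8)),
              if (seven_mer == "both") rep(7L, length(sa1)))
  types  <- c(rep("8mer", length(s8)), rep("7mer-m8", length(sm8)),
              if (seven_mer == "both") rep("7mer-A1", length(sa1)))
  out <- data.frame(transcript_id = transcript_id,
                    start = starts - 1L,
                    end = starts - 1L + widths,
                    site_type = types,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of UTR sequences
#'
#' @param utrs Named character vector of UTR sequences, or a
#'   `Biostrings::XStringSet` (names are transcript ids).
#' @inheritParams scan_utr
#' @return Row-bound site table over all records (see [scan_utr()]).
#' @export
scan_utr_set <- function(utrs, motifs, seven_mer = c("both", "m8_only")) {
  seven_mer <- match.arg(seven_mer)
  if (methods::is(utrs, "XStringSet")) {
    utrs <- stats::setNames(as.character(utrs), names(utrs))
  }
  if (is.null(names(utrs)) || anyDuplicated(names(utrs))) {
    stop("UTR sequences must carry unique transcript-id names", call. = FALSE)
  }
  res <- lapply(names(utrs), function(id) {
    scan_utr(utrs[[id]], motifs, transcript_id = id, seven_mer = seven_mer)
  })
  do.call(rbind, res)
}

#' Count seed sites per gene
#'
#' Pools sites over a gene's scanned UTR isoforms, deduplicates identical
#' positions, and tabulates the two published site classes: `n_8mer` (8mer
#' sites) and `n_7mer` (7mer-m8 plus 7mer-A1 sites). A position reported
#' as 8mer is never double-counted as 7mer (see [scan_utr()]).
#'
#' @param sites Site table from [scan_utr_set()].
#' @param gene_map Optional named character vector mapping transcript id ->
#'   gene id; unmapped transcripts keep their own id as the gene.
#' @return data.frame with columns `gene`, `n_7mer`, `n_8mer`, one row per
#'   gene appearing in `sites` (genes mapped but without sites get zeros
#'   when present in `gene_map`).
#' @export
count_sites <- function(sites, gene_map = NULL) {
  stopifnot(all(c("transcript_id", "start", "end", "site_type") %in% names(sites)))
  gene <- sites$transcript_id
  if (!is.null(gene_map)) {
    hit <- sites$transcript_id %in% names(gene_map)
    gene[hit] <- unname(gene_map[sites$transcript_id[hit]])
  }
  key <- paste(gene, sites$start, sites$end, sites$site_type, sep = "\r")
  keep <- !duplicated(key)
  gene <- gene[keep]
  type <- sites$site_type[keep]
  universe <- sort(unique(c(gene, if (!is.null(gene_map)) unname(gene_map))))
  n8 <- table(factor(gene[type == "8mer"], levels = universe))
  n7 <- table(factor(gene[type != "8mer"], levels = universe))
  data.frame(gene = universe,
             n_7mer = as.integer(n7),
             n_8mer = as.integer(n8),
             stringsAsFactors = FALSE)
}

#' Extract 3'UTR sequences from a genome and transcript models
#'
#' Concatenates each model's blocks in genomic order and reverse-complements
#' minus-strand records, so the returned sequences read transcript 5'->3'.
#'
#' @param genome A named `DNAStringSet` (or FASTA path) of reference
#'   sequences.
#' @param models A `GRanges` of 3'UTR models as returned by
#'   [read_transcript_models()] (BED12 blocks honoured when present).
#' @return Named character vector of UTR sequences (DNA alphabet), one per
#'   model, named by transcript id.
#' @export
extract_utrs <- function(genome, models) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  ids <- models$name
  if (is.null(ids)) ids <- names(models)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  out <- vapply(seq_along(models), function(i) {
    m <- models[i]
    chrom <- as.character(GenomicRanges::seqnames(m))
    if (!chrom %in% names(genome)) {
      stop(sprintf("transcript '%s' refers to unknown sequence '%s'", ids[i], chrom),
           call. = FALSE)
    }
    blocks <- if (!is.null(m$blocks)) {
      IRanges::shift(m$blocks[[1]], BiocGenerics::start(m) - 1L)
    } else {
      IRanges::IRanges(BiocGenerics::start(m), BiocGenerics::end(m))
    }
    pieces <- vapply(seq_along(blocks), function(j) {
      as.character(Biostrings::subseq(genome[[chrom]],
                                      BiocGenerics::start(blocks)[j],
                                      BiocGenerics::end(blocks)[j]))
    }, character(1))
    seq <- paste(pieces, collapse = "")
    if (as.character(BiocGenerics::strand(m)) == "-") {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    seq
  }, character(1))
  stats::setNames(out, ids)
}
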