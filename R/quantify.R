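#' Reads per kilobase of exon model per million mapped reads
#'
#' @param raw_count Non-negative read count(s).
#' @param exon_length_bp Exon-model length(s) in bp, > 0.
#' @param library_mapped_reads Total mapped reads in the library, > 0.
#' @return RPKM value(s): `raw_count / (exon_length_bp/1e3) /
#'   (library_mapped_reads/1e6)`.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(raw_count, exon_length_bp, library_mapped_reads) {
  if (any(raw_count < 0)) stop("raw counts must be non-negative", call. = FALSE)
  if (any(exon_length_bp <= 0)) stop("exon lengths must be positive", call. = FALSE)
  if (any(library_mapped_reads <= 0)) stop("library sizes must be positive", call. = FALSE)
  raw_count / (exon_length_bp / 1e3) / (library_mapped_reads / 1e6)
}

#' Expression fold change between conditions
#'
#' Ratio of treatment over control expression, optionally stabilised with a
#' pseudocount. The pseudocount defaults to 0 so that zeros are surfaced as
#' an error rather than silently shifting fold values.
#'
#' @param rpkm_mir155 Treatment (miRNA over-expression) RPKM.
#' @param rpkm_vector Control (empty vector) RPKM.
#' @param pseudocount Non-negative value added to both terms.
#' @return `(rpkm_mir155 + pseudocount) / (rpkm_vector + pseudocount)`.
#' @export
fold_change <- function(rpkm_mir155, rpkm_vector, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(rpkm_vector == 0)) {
    stop("control RPKM of 0 with pseudocount 0: fold change undefined; set pseudocount > 0",
         call. = FALSE)
  }
  (rpkm_mir155 + pseudocount) / (rpkm_vector + pseudocount)
}

#' Default classification thresholds
#'
#' `up` is strict (increased when fold > 1.5), `down` inclusive (repressed
#' when fold <= 0.5), `read_floor` strict (low-read when both raw counts
#' are below 10).
#'
#' @param up Upper fold bound, strict.
#' @param down Lower fold bound, inclusive.
#' @param read_floor Raw-read floor, strict, required in both conditions.
#' @return Named list of thresholds.
#' @export
classification_thresholds <- function(up = 1.5, down = 0.5, read_floor = 10) {
  stopifnot(up > down, read_floor >= 0)
  list(up = up, down = down, read_floor = read_floor)
}

#' Classify a gene's response to miRNA over-expression
#'
#' Labels are `low_read_excluded` (both raw counts below the read floor),
#' `repressed` (fold <= `down`), `increased` (fold > `up`) and `unchanged`.
#' With `filter_scope = "all"` (default) the low-read rule is evaluated
#' first for every gene; `"increased_only"` applies it only to genes that
#' would otherwise be called increased, mirroring a workflow where only the
#' increased cohort is read-filtered.
#'
#' @param fold Fold change(s), treatment over control.
#' @param raw_count_vector,raw_count_mir155 Raw counts per condition.
#' @param thresholds See [classification_thresholds()].
#' @param filter_scope `"all"` or `"increased_only"`.
#' @return Character vector of class labels.
#' @examples
#' classify_target(3.0, 4, 7)    # low_read_excluded
#' classify_target(1.5, 50, 80)  # unchanged: the upper bound is strict
#' classify_target(0.5, 50, 30)  # repressed: the lower bound is inclusive
#' @export
classify_target <- function(fold, raw_count_vector, raw_count_mir155,
                            thresholds = classification_thresholds(),
                            filter_scope = c("all", "increased_only")) {
  filter_scope <- match.arg(filter_scope)
  stopifnot(length(fold) == length(raw_count_vector),
            length(fold) == length(raw_count_mir155))
  low <- raw_count_vector < thresholds$read_floor &
         raw_count_mir155 < thresholds$read_floor
  label <- ifelse(fold <= thresholds$down, "repressed",
           ifelse(fold > thresholds$up, "increased", "unchanged"))
  if (filter_scope == "all") {
    label[low] <- "low_read_excluded"
  } else {
    label[low & label == "increased"] <- "low_read_excluded"
  }
  label
}

#' Quantify and classify a two-condition counts table
#'
#' Computes per-gene RPKM for both conditions, the miR-155/vector fold
#' change, and the target class label. Library sizes default to the column
#' sums of the raw counts. When `counts` carries an `isoform` column,
#' isoform counts are summed to gene level first.
#'
#' @param counts data.frame with columns `gene`, `count_vector`,
#'   `count_mir155`, `exon_length_bp` (optional `isoform`).
#' @param library_sizes Optional numeric vector
#'   `c(vector = ..., mir155 = ...)`; defaults to column sums.
#' @param pseudocount Passed to [fold_change()].
#' @param thresholds,filter_scope Passed to [classify_target()].
#' @return data.frame of expression records: `gene`, `count_vector`,
#'   `count_mir155`, `exon_length_bp`, `rpkm_vector`, `rpkm_mir155`,
#'   `fold_change`, `class_label`.
#' @export
quantify_expression <- function(counts, library_sizes = NULL, pseudocount = 0,
                                thresholds = classification_thresholds(),
                                filter_scope = c("all", "increased_only")) {
  filter_scope <- match.arg(filter_scope)
  need <- c("gene", "count_vector", "count_mir155", "exon_length_bp")
  if (!all(need %in% names(counts))) {
    stop("counts table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if ("isoform" %in% names(counts) && anyDuplicated(counts$gene)) {
    # gene-level expression is the sum over isoforms; length is the max
    # isoform exon model (a conservative single-length summary)
    counts <- do.call(rbind, lapply(split(counts, counts$gene), function(d) {
      data.frame(gene = d$gene[1],
                 count_vector = sum(d$count_vector),
                 count_mir155 = sum(d$count_mir155),
                 exon_length_bp = max(d$exon_length_bp),
                 stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(counts$gene)) {
    stop("duplicated gene ids in counts table", call. = FALSE)
  }
  if (is.null(library_sizes)) {
    library_sizes <- c(vector = sum(counts$count_vector),
                       mir155 = sum(counts$count_mir155))
  }
  stopifnot(all(library_sizes > 0))
  rv <- rpkm(counts$count_vector, counts$exon_length_bp, library_sizes[["vector"]])
  rm <- rpkm(counts$count_mir155, counts$exon_length_bp, library_sizes[["mir155"]])
  fc <- fold_change(rm, rv, pseudocount = pseudocount)
  data.frame(gene = counts$gene,
             count_vector = counts$count_vector,
             count_mir155 = counts$count_mir155,
             exon_length_bp = counts$exon_length_bp,
             rpkm_vector = rv, rpkm_mir155 = rm,
             fold_change = fc,
             class_label = classify_target(fc, counts$count_vector,
                                           counts$count_mir155,
                                           thresholds, filter_scope),
             stringsAsFactors = FALSE)
}

#' Bin fold changes into a histogram table
#'
#' Mirrors the screen's fold-distribution views: the gene selection can be
#' restricted to genes carrying any seed site, an 8mer site, or a 7mer
#' site. Bins are right-open `[a, b)` with the final bin closed, so every
#' selected gene falls in exactly one bin.
#'
#' @param records Expression records from [quantify_expression()].
#' @param bin_edges Strictly increasing numeric edges (use `Inf` for an
#'   open-ended last bin).
#' @param site_counts Optional [count_sites()] table used for filtering.
#' @param seed_filter `"all"` (no filter), `"any"` (>= 1 site of any
#'   class), `"8mer"` (>= 1 8mer site) or `"7mer"` (>= 1 7mer site).
#' @return data.frame with columns `bin_start`, `bin_end`, `n_genes`;
#'   counts sum to the number of selected genes.
#' @export
fold_histogram <- function(records, bin_edges, site_counts = NULL,
                           seed_filter = c("all", "any", "8mer", "7mer")) {
  seed_filter <- match.arg(seed_filter)
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  folds <- records$fold_change
  if (seed_filter != "all") {
    if (is.null(site_counts)) {
      stop("seed_filter requires a site_counts table", call. = FALSE)
    }
    sel <- switch(seed_filter,
      any  = site_counts$gene[site_counts$n_7mer + site_counts$n_8mer > 0],
      `8mer` = site_counts$gene[site_counts$n_8mer > 0],
      `7mer` = site_counts$gene[site_counts$n_7mer > 0])
    folds <- folds[records$gene %in% sel]
  }
  nb <- length(bin_edges) - 1L
  if (length(folds) &&
      (any(folds < bin_edges[1]) || any(folds > bin_edges[nb + 1L]))) {
    stop("fold changes outside the bin range; extend the edges (Inf is allowed)",
         call. = FALSE)
  }
  cuts <- cut(folds, breaks = bin_edges, right = FALSE, include.lowest = TRUE)
  data.frame(bin_start = bin_edges[-(nb + 1L)],
             bin_end = bin_edges[-1L],
             n_genes = as.integer(table(cuts)),
             stringsAsFactors = FALSE)
}
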