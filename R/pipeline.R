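#' Configuration for an end-to-end run
#'
#' Collects the input paths and every module's parameter block. All
#' parameters have the module defaults; any can be overridden here (or
#' from the command line, where each flag maps to one field).
#'
#' @param utr_fasta UTR FASTA (record id = transcript id).
#' @param counts Two-condition counts TSV (see [read_counts_table()]).
#' @param coverage_vector,coverage_mir155 Per-condition bedGraph files.
#' @param models BED12/GFF3 transcript models locating each 3'UTR
#'   (required with coverage input).
#' @param gmt Optional GMT gene-set collection.
#' @param mirna_sequence Mature miRNA guide sequence (default miR-155).
#' @param mirna_name Label for the miRNA.
#' @param outdir Output directory for the report tables.
#' @param library_sizes Optional `c(vector = , mir155 = )`; defaults to
#'   counts-column sums.
#' @param pseudocount,thresholds,filter_scope See
#'   [quantify_expression()].
#' @param seven_mer See [scan_utr()].
#' @param shortening See [shortening_params()].
#' @param bin_edges Fold-histogram bin edges.
#' @param universe `"expressed"` (genes with a nonzero count in either
#'   condition; default) or `"gmt_union"`.
#' @param gene_map Optional named vector transcript id -> gene id
#'   (default: transcript ids are gene ids).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(utr_fasta, counts, coverage_vector = NULL,
                       coverage_mir155 = NULL, models = NULL, gmt = NULL,
                       mirna_sequence = "UUAAUGCUAAUCGUGAUAGGGGU",
                       mirna_name = "hsa-miR-155-5p",
                       outdir = "mir_escape_out",
                       library_sizes = NULL, pseudocount = 0,
                       thresholds = classification_thresholds(),
                       filter_scope = "all",
                       seven_mer = "both",
                       shortening = shortening_params(),
                       bin_edges = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5, 10, Inf),
                       universe = c("expressed", "gmt_union"),
                       gene_map = NULL) {
  universe <- match.arg(universe)
  cfg <- as.list(environment())
  for (f in c("utr_fasta", "counts", "coverage_vector", "coverage_mir155",
              "models", "gmt")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop(sprintf("input '%s' does not exist: %s", f, cfg[[f]]), call. = FALSE)
    }
  }
  if (!is.null(cfg$coverage_vector) && is.null(cfg$models)) {
    stop("coverage input requires transcript models", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full seed-escape analysis
#'
#' Orchestrates seed-site scanning, RPKM quantification and target
#' classification, coverage-based shortening/seed-loss calls, and
#' pathway over-representation of the up-regulated, down-regulated and
#' seed-containing gene lists. Per-stage record counts are logged to
#' stderr; all stage outputs are written as TSV (with a commented
#' metadata line) into `config$outdir`. The run is deterministic given
#' inputs and configuration.
#'
#' @param config A [run_config()].
#' @return Invisible `report_bundle` list: `sites`, `site_counts`,
#'   `expression`, `shortening` (or `NULL`), `targets_table`,
#'   `fold_histograms`, `enrichment` (or `NULL`), `paths`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  motifs <- stage("motifs", derive_seed_motifs(
    mature_mirna(config$mirna_name, config$mirna_sequence)))

  utrs <- stage("scan", read_utr_fasta(config$utr_fasta))
  sites <- stage("scan", scan_utr_set(utrs, motifs, seven_mer = config$seven_mer))
  site_counts <- stage("scan", count_sites(sites, gene_map = config$gene_map))
  message(sprintf("[scan] %d UTRs scanned; %d sites on %d genes",
                  length(utrs), nrow(sites), sum(site_counts$n_7mer +
                                                 site_counts$n_8mer > 0)))
  if (nrow(sites) == 0L) {
    warning("no seed sites found in any UTR; targets table will be empty",
            call. = FALSE)
  }

  counts <- stage("quantify", read_counts_table(config$counts))
  expr <- stage("quantify", quantify_expression(
    counts, library_sizes = config$library_sizes,
    pseudocount = config$pseudocount, thresholds = config$thresholds,
    filter_scope = config$filter_scope))
  tab <- table(factor(expr$class_label,
                      c("repressed", "unchanged", "increased", "low_read_excluded")))
  message(sprintf("[quantify] %d genes: %d repressed, %d unchanged, %d increased, %d low-read-excluded",
                  nrow(expr), tab[1], tab[2], tab[3], tab[4]))

  shortening <- NULL
  if (!is.null(config$coverage_vector)) {
    models <- stage("apa", read_transcript_models(config$models))
    tv <- stage("apa", read_coverage(config$coverage_vector, models))
    tm <- stage("apa", read_coverage(config$coverage_mir155, models))
    shortening <- stage("apa", call_shortening_set(tv, tm, sites,
                                                   params = config$shortening))
    message(sprintf("[apa] %d transcripts: %d shortened, %d seed-lost, %d QC-failed",
                    nrow(shortening), sum(shortening$shortened, na.rm = TRUE),
                    sum(shortening$seed_lost, na.rm = TRUE),
                    sum(shortening$qc_fail)))
  }

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    sets <- stage("enrich", read_gmt(config$gmt))
    universe <- if (config$universe == "expressed") {
      expr$gene[expr$count_vector + expr$count_mir155 > 0]
    } else {
      unique(unlist(sets))
    }
    collection <- stage("enrich", gene_set_collection(sets, universe))
    with_site <- site_counts$gene[site_counts$n_7mer + site_counts$n_8mer > 0]
    queries <- list(up = expr$gene[expr$class_label == "increased"],
                    down = expr$gene[expr$class_label == "repressed"],
                    seed_containing = with_site)
    enrichment <- stage("enrich", rank_pathways(queries, collection))
    message(sprintf("[enrich] %d sets tested against lists of %d up, %d down, %d seed-containing genes",
                    length(collection$sets), length(queries$up),
                    length(queries$down), length(queries$seed_containing)))
  }

  targets <- stage("report", build_targets_table(expr, site_counts, shortening))
  hists <- stage("report", lapply(
    stats::setNames(c("all", "any", "8mer", "7mer"),
                    c("all", "any_site", "8mer", "7mer")),
    function(f) fold_histogram(expr, config$bin_edges,
                               site_counts = site_counts, seed_filter = f)))

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(mirna = config$mirna_name, filter_scope = config$filter_scope,
            seven_mer = config$seven_mer)
  paths <- list()
  wt <- function(d, name) {
    p <- file.path(config$outdir, name)
    write_tsv(d, p, meta = meta)
    p
  }
  paths$sites <- wt(sites, "sites.tsv")
  paths$site_counts <- wt(site_counts, "site_counts.tsv")
  paths$expression <- wt(expr, "expression.tsv")
  if (!is.null(shortening)) paths$shortening <- wt(shortening, "shortening.tsv")
  paths$targets_table <- wt(targets, "targets_table.tsv")
  for (h in names(hists)) {
    paths[[paste0("hist_", h)]] <- wt(hists[[h]],
                                      sprintf("fold_histogram_%s.tsv", h))
  }
  if (!is.null(enrichment)) {
    for (q in names(enrichment)) {
      paths[[paste0("enrich_", q)]] <- wt(enrichment[[q]],
                                          sprintf("enrichment_%s.tsv", q))
    }
  }
  message(sprintf("[report] %d genes in targets table; outputs in %s",
                  nrow(targets), config$outdir))
  invisible(structure(list(sites = sites, site_counts = site_counts,
                           expression = expr, shortening = shortening,
                           targets_table = targets, fold_histograms = hists,
                           enrichment = enrichment, paths = paths),
                      class = "report_bundle"))
}

#' Assemble the per-gene targets table
#'
#' Joins expression records with per-gene site counts and (when
#' available) shortening calls. The `utr_shortening` Yes/No column
#' follows the published vocabulary and derives from `seed_lost` (`ND`
#' when coverage failed QC). Rows are sorted by class label and then
#' ascending fold change, the convention used for the published target
#' table.
#'
#' @param expression Records from [quantify_expression()].
#' @param site_counts From [count_sites()].
#' @param shortening Optional calls from [call_shortening_set()].
#' @return data.frame, one row per gene in `expression`.
#' @export
build_targets_table <- function(expression, site_counts, shortening = NULL) {
  d <- merge(expression, site_counts, by = "gene", all.x = TRUE)
  d$n_7mer[is.na(d$n_7mer)] <- 0L
  d$n_8mer[is.na(d$n_8mer)] <- 0L
  if (!is.null(shortening)) {
    s <- shortening[, c("transcript_id", "breakpoint", "dui_ratio",
                        "shortened", "seed_lost", "lost_in_both", "qc_fail")]
    names(s)[1] <- "gene"
    d <- merge(d, s, by = "gene", all.x = TRUE)
    d$utr_shortening <- ifelse(is.na(d$seed_lost), "ND",
                               ifelse(d$seed_lost, "Yes", "No"))
  } else {
    d$utr_shortening <- "ND"
  }
  ord <- order(factor(d$class_label, c("increased", "unchanged", "repressed",
                                       "low_read_excluded")),
               d$fold_change, d$gene)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Select the increased-expression 8mer cohort
#'
#' The screen's headline cohort: genes carrying at least one 8mer seed
#' site whose expression increased, partitioned by the low-read filter.
#'
#' @param expression Records from [quantify_expression()] computed with
#'   `filter_scope = "increased_only"` or `"all"`.
#' @param site_counts From [count_sites()].
#' @param thresholds The thresholds used for classification.
#' @return List with `increased_8mer` (all 8mer genes whose fold cleared
#'   the upper bound, before the read filter), `low_read` (the excluded
#'   subset) and `retained` (the cohort surviving the filter).
#' @export
increased_8mer_cohort <- function(expression, site_counts,
                                  thresholds = classification_thresholds()) {
  g8 <- site_counts$gene[site_counts$n_8mer > 0]
  e <- expression[expression$gene %in% g8, , drop = FALSE]
  inc <- e[e$class_label == "increased", , drop = FALSE]
  low <- e[e$class_label == "low_read_excluded" &
           e$fold_change > thresholds$up, , drop = FALSE]
  list(increased_8mer = rbind(inc, low),
       low_read = low,
       retained = inc)
}
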