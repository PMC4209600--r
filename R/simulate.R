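#' Simulation configuration for a two-condition miRNA screen
#'
#' Defaults describe a realistic desk-scale screen: a few hundred genes,
#' human-like 3'UTR lengths, bursty single-library negative-binomial
#' counts, and clearly planted (but noisy) effects. All randomness in the
#' generator derives from `seed`; a fixed configuration reproduces every
#' emitted file byte for byte.
#'
#' @param n_genes Number of genes (one transcript per gene).
#' @param utr_length Length range (bp) for simulated 3'UTRs.
#' @param p_site_8mer,p_site_7mer Probability that a gene carries one
#'   planted 8mer / 7mer-m8 site.
#' @param frac_up,frac_down Fractions of genes given a true fold effect
#'   above 1.5 / at or below 0.5 (the rest are null, fold 1).
#' @param fold_up,fold_down Ranges from which true up/down folds are
#'   drawn log-uniformly.
#' @param nb_mean_range Range of per-gene negative-binomial means
#'   (log-uniform).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   models library-free biological burstiness.
#' @param n_low_read Genes forced below the read floor in both
#'   conditions.
#' @param low_read_mean NB mean assigned to low-read genes (both
#'   conditions), chosen so both raw counts fall below 10 with
#'   probability >= 0.99.
#' @param depth Mean per-base coverage of the vector condition.
#' @param step_factor Distal coverage attenuation beyond the planted
#'   breakpoint in the miR-155 track of shortened genes (> 1).
#' @param frac_shortened Fraction of increased-expression 8mer targets
#'   given a planted shortening event (breakpoint proximal to the seed,
#'   i.e. a seed-loss event).
#' @param n_sets,set_size Gene-set collection shape for the GMT output.
#' @param enrichment_odds Sampling odds favouring true up-genes in the
#'   planted set (1 = no enrichment).
#' @param exon_flank_bp Added to the UTR length to form the exon-model
#'   length used for RPKM.
#' @param seed RNG seed, recorded in the output metadata.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       utr_length = c(400L, 1200L),
                       p_site_8mer = 0.4, p_site_7mer = 0.3,
                       frac_up = 0.25, frac_down = 0.25,
                       fold_up = c(2, 6), fold_down = c(0.15, 0.5),
                       nb_mean_range = c(100, 2000),
                       dispersion = 0.05,
                       n_low_read = 10L, low_read_mean = 1,
                       depth = 50, step_factor = 8,
                       frac_shortened = 0.5,
                       n_sets = 10L, set_size = 25L,
                       enrichment_odds = 8,
                       exon_flank_bp = 1500L,
                       seed = 1L) {
  stopifnot(n_genes >= 1, utr_length[1] >= 100, utr_length[2] >= utr_length[1],
            p_site_8mer >= 0, p_site_8mer <= 1, p_site_7mer >= 0, p_site_7mer <= 1,
            frac_up + frac_down <= 1, dispersion > 0, step_factor > 1,
            fold_up[1] > 1.5, fold_down[2] <= 0.5,
            frac_shortened >= 0, frac_shortened <= 1,
            enrichment_odds >= 1)
  structure(as.list(environment()), class = "sim_config")
}

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

# Gene-level truth: classes, folds, site plans, planted breakpoints.
simulate_truth <- function(config) {
  n <- config$n_genes
  gene <- sprintf("gene%04d", seq_len(n))
  L <- as.integer(round(stats::runif(n, config$utr_length[1], config$utr_length[2])))
  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  class <- sample(c(rep("up", n_up), rep("down", n_down),
                    rep("null", n - n_up - n_down)))
  fold <- rep(1, n)
  fold[class == "up"] <- runif_log(sum(class == "up"), config$fold_up)
  fold[class == "down"] <- runif_log(sum(class == "down"), config$fold_down)
  mu <- runif_log(n, config$nb_mean_range)
  low_read <- rep(FALSE, n)
  if (config$n_low_read > 0) {
    # prefer up-regulated genes, mirroring a cohort where part of the
    # increased set fails the read floor
    pool <- c(which(class == "up"), which(class != "up"))
    low_read[pool[seq_len(min(config$n_low_read, n))]] <- TRUE
  }
  has_8mer <- stats::runif(n) < config$p_site_8mer
  has_7mer <- stats::runif(n) < config$p_site_7mer
  # distal window for the 8mer keeps room for a proximal breakpoint;
  # proximal window for the 7mer avoids overlap with the 8mer
  s8 <- ifelse(has_8mer,
               floor(stats::runif(n, 0.55, 0.88) * L), NA_integer_)
  s7 <- ifelse(has_7mer,
               floor(stats::runif(n, 0.05, 0.35) * L), NA_integer_)
  shortened <- has_8mer & class == "up" & !low_read &
               stats::runif(n) < config$frac_shortened
  bp <- rep(NA_integer_, n)
  idx <- which(shortened)
  if (length(idx)) {
    lo <- pmax(floor(0.25 * L[idx]), 30L)
    hi <- s8[idx] - 20L
    bp[idx] <- as.integer(floor(lo + stats::runif(length(idx)) * (hi - lo)))
  }
  data.frame(gene = gene, utr_length = L, class = class, true_fold = fold,
             nb_mean = mu, low_read = low_read,
             has_8mer = has_8mer, site_8mer_start = as.integer(s8),
             has_7mer = has_7mer, site_7mer_start = as.integer(s7),
             shortened = shortened, seed_lost = shortened,
             breakpoint = bp, stringsAsFactors = FALSE)
}

random_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

plant_motif <- function(seq, motif, start0) {
  substr(seq, start0 + 1L, start0 + nchar(motif)) <- motif
  seq
}

#' Simulate 3'UTR sequences with planted seed sites
#'
#' Background sequence is drawn motif-free by rejection sampling; planted
#' motifs (full 8mer and/or 7mer-m8) are then inserted at the truth
#' offsets and each record is re-scanned to verify that exactly the
#' planted sites (and nothing else) are present, resampling the record
#' otherwise.
#'
#' @param config A [sim_config()].
#' @param truth Gene truth table (from the screen simulator).
#' @param motifs Seed motifs to plant; defaults to the miR-155 set.
#' @return List with `utrs` (named character vector) and `site_truth`
#'   (data.frame `transcript_id`, `start`, `end`, `site_type`).
#' @export
simulate_utrs <- function(config, truth,
                          motifs = derive_seed_motifs(mir155())) {
  utrs <- character(nrow(truth))
  site_rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    L <- truth$utr_length[i]
    planned <- data.frame(start = integer(0), site_type = character(0))
    if (truth$has_8mer[i]) {
      planned <- rbind(planned, data.frame(start = truth$site_8mer_start[i],
                                           site_type = "8mer"))
    }
    if (truth$has_7mer[i]) {
      planned <- rbind(planned, data.frame(start = truth$site_7mer_start[i],
                                           site_type = "7mer-m8"))
    }
    if (nrow(planned) && L < max(planned$start) + 8L) {
      stop(sprintf("UTR of '%s' (%d bp) too short to host the requested sites",
                   truth$gene[i], L), call. = FALSE)
    }
    ok <- FALSE
    for (try in seq_len(100L)) {
      seq <- random_rna(L)
      if (nrow(scan_utr(seq, motifs, truth$gene[i]))) next   # background not motif-free
      if (truth$has_8mer[i]) {
        seq <- plant_motif(seq, motifs$motif_8mer, truth$site_8mer_start[i])
      }
      if (truth$has_7mer[i]) {
        seq <- plant_motif(seq, motifs$motif_7mer_m8, truth$site_7mer_start[i])
      }
      found <- scan_utr(seq, motifs, truth$gene[i])
      if (nrow(found) == nrow(planned) &&
          (nrow(found) == 0L ||
           all(sort(found$start) == sort(planned$start)) &&
           identical(found$site_type[order(found$start)],
                     planned$site_type[order(planned$start)]))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("could not realise the planted sites for '%s' after 100 draws",
                   truth$gene[i]), call. = FALSE)
    }
    utrs[i] <- seq
    site_rows[[i]] <- if (nrow(planned)) {
      data.frame(transcript_id = truth$gene[i], start = planned$start,
                 end = planned$start + ifelse(planned$site_type == "8mer", 8L, 7L),
                 site_type = planned$site_type, stringsAsFactors = FALSE)
    }
  }
  site_truth <- do.call(rbind, site_rows)
  if (is.null(site_truth)) {
    site_truth <- data.frame(transcript_id = character(0), start = integer(0),
                             end = integer(0), site_type = character(0))
  }
  site_truth <- site_truth[order(site_truth$transcript_id, site_truth$start), ]
  rownames(site_truth) <- NULL
  list(utrs = stats::setNames(utrs, truth$gene), site_truth = site_truth)
}

#' Simulate the two-condition counts table
#'
#' Vector-condition counts are NB(mu, dispersion); miR-155 counts are
#' NB(mu * fold, dispersion). Low-read genes get `low_read_mean` in both
#' conditions so both raw counts land below the read floor with
#' probability >= 0.99.
#'
#' @inheritParams simulate_utrs
#' @return Counts data.frame (`gene`, `count_vector`, `count_mir155`,
#'   `exon_length_bp`).
#' @export
simulate_counts <- function(config, truth) {
  n <- nrow(truth)
  size <- 1 / config$dispersion
  mu_v <- ifelse(truth$low_read, config$low_read_mean, truth$nb_mean)
  mu_m <- ifelse(truth$low_read, config$low_read_mean,
                 truth$nb_mean * truth$true_fold)
  data.frame(gene = truth$gene,
             count_vector = stats::rnbinom(n, mu = mu_v, size = size),
             count_mir155 = stats::rnbinom(n, mu = mu_m, size = size),
             exon_length_bp = truth$utr_length + config$exon_flank_bp,
             stringsAsFactors = FALSE)
}

#' Simulate per-base 3'UTR coverage tracks
#'
#' Per-base counts are Poisson with rate `depth` scaled by the
#' condition's expression (fold for the miR-155 track); for shortened
#' genes the miR-155 rate is divided by `step_factor` beyond the planted
#' breakpoint. Low-read genes get near-zero coverage in both conditions.
#'
#' @inheritParams simulate_utrs
#' @return List with named lists `tracks_vector` and `tracks_mir155`.
#' @export
simulate_coverage <- function(config, truth) {
  tv <- vector("list", nrow(truth))
  tm <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    L <- truth$utr_length[i]
    scale_v <- if (truth$low_read[i]) 0.01 else 1
    scale_m <- if (truth$low_read[i]) 0.01 else truth$true_fold[i]
    lam_m <- rep(config$depth * scale_m, L)
    if (isTRUE(truth$shortened[i])) {
      k <- truth$breakpoint[i]
      lam_m[(k + 1L):L] <- lam_m[(k + 1L):L] / config$step_factor
    }
    tv[[i]] <- stats::rpois(L, config$depth * scale_v)
    tm[[i]] <- stats::rpois(L, lam_m)
  }
  list(tracks_vector = stats::setNames(tv, truth$gene),
       tracks_mir155 = stats::setNames(tm, truth$gene))
}

#' Simulate a GMT gene-set collection with one planted enriched set
#'
#' The planted set samples its members with odds `enrichment_odds` in
#' favour of true up-regulated genes; the remaining sets are uniform
#' draws from the gene universe.
#'
#' @inheritParams simulate_utrs
#' @return List with `sets` (named list, GMT-ready) and `planted_set`
#'   (its name).
#' @export
simulate_gene_sets <- function(config, truth) {
  if (config$n_sets < 1L) {
    warning("empty gene-set collection requested", call. = FALSE)
    return(list(sets = stats::setNames(list(), character(0)),
                planted_set = NA_character_))
  }
  universe <- truth$gene
  size <- min(config$set_size, length(universe))
  w <- ifelse(truth$class == "up", config$enrichment_odds, 1)
  planted <- sample(universe, size, prob = w)
  others <- lapply(seq_len(config$n_sets - 1L), function(i) {
    sample(universe, size)
  })
  sets <- c(list(planted), others)
  names(sets) <- sprintf("pathway_%02d", seq_len(config$n_sets))
  list(sets = sets, planted_set = names(sets)[1])
}

#' Simulate a complete screen
#'
#' Runs the generator stages in a fixed order from a single seed and
#' (optionally) writes all pipeline inputs plus the truth table:
#' `utrs.fa`, `models.bed`, `counts.tsv`, `coverage_vector.bedgraph`,
#' `coverage_mir155.bedgraph`, `gene_sets.gmt`, `truth.tsv`,
#' `site_truth.tsv` and `metadata.tsv`. Emitted transcript models place
#' each 3'UTR on its own plus-strand contig named after the gene, so
#' bedGraph coordinates equal transcript coordinates.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created); `NULL` keeps everything in
#'   memory.
#' @param motifs Seed motifs to plant (default miR-155).
#' @return Invisible list: `config`, `truth`, `site_truth`, `utrs`,
#'   `counts`, `tracks_vector`, `tracks_mir155`, `sets`, `planted_set`,
#'   and `paths` when `outdir` is given.
#' @export
simulate_screen <- function(config = sim_config(), outdir = NULL,
                            motifs = derive_seed_motifs(mir155())) {
  set.seed(config$seed)
  truth <- simulate_truth(config)
  seqres <- simulate_utrs(config, truth, motifs)
  counts <- simulate_counts(config, truth)
  covres <- simulate_coverage(config, truth)
  gsres <- simulate_gene_sets(config, truth)
  truth$in_planted_set <- truth$gene %in% gsres$sets[[gsres$planted_set]]
  res <- list(config = config, truth = truth, site_truth = seqres$site_truth,
              utrs = seqres$utrs, counts = counts,
              tracks_vector = covres$tracks_vector,
              tracks_mir155 = covres$tracks_mir155,
              sets = gsres$sets, planted_set = gsres$planted_set)
  if (!is.null(outdir)) {
    res$paths <- write_screen(res, outdir)
  }
  invisible(res)
}

# Shared writer for simulate_screen() and mimic_screen().
write_screen <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    utr_fasta = file.path(outdir, "utrs.fa"),
    models = file.path(outdir, "models.bed"),
    counts = file.path(outdir, "counts.tsv"),
    coverage_vector = file.path(outdir, "coverage_vector.bedgraph"),
    coverage_mir155 = file.path(outdir, "coverage_mir155.bedgraph"),
    gmt = file.path(outdir, "gene_sets.gmt"),
    truth = file.path(outdir, "truth.tsv"),
    site_truth = file.path(outdir, "site_truth.tsv"),
    metadata = file.path(outdir, "metadata.tsv"))
  write_utr_fasta(res$utrs, p$utr_fasta)
  write_bed12(data.frame(chrom = names(res$utrs), start = 0L,
                         end = nchar(res$utrs), name = names(res$utrs),
                         strand = "+", stringsAsFactors = FALSE), p$models)
  write_tsv(res$counts, p$counts)
  write_bedgraph(res$tracks_vector, p$coverage_vector)
  write_bedgraph(res$tracks_mir155, p$coverage_mir155)
  write_gmt(res$sets, p$gmt)
  write_tsv(res$truth, p$truth)
  write_tsv(res$site_truth, p$site_truth)
  cfg <- res$config
  scalars <- vapply(cfg, function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                                           collapse = ","), character(1))
  write_tsv(data.frame(key = names(scalars), value = unname(scalars),
                       stringsAsFactors = FALSE), p$metadata)
  p
}
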