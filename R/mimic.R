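#' Deterministic screen preset mirroring the published cohort structure
#'
#' Builds a complete in-memory screen whose cohort structure reproduces
#' the published miR-155/MCF-7 analysis (see
#' [transcribe_fixture_tables()]): thirty increased-expression genes with
#' an 8mer seed site, of which fourteen sit below the read floor in both
#' conditions and sixteen survive with fold changes equal to the printed
#' relative-expression values; coverage tracks carry a proximal-to-seed
#' step drop for exactly the targets the screen called shortened
#' (Table 1 flags — note these disagree with the site table for MAP3K14).
#' Counts are constructed, not sampled, so the cohort arithmetic
#' (30 -> 14 excluded -> 16 retained) is exact; sequence draws and
#' Poisson coverage noise use the fixed `seed`.
#'
#' Background realism: repressed, unchanged and 7mer-only genes are added
#' around the cohort so classification and enrichment see a full gene
#' universe.
#'
#' @param outdir Optional directory; when given, all pipeline input files
#'   are written as in [simulate_screen()].
#' @param seed RNG seed for sequence and coverage noise.
#' @param depth Mean per-base coverage for well-expressed genes.
#' @param step_factor Distal attenuation for shortened tracks.
#' @return Invisible list with the same shape as [simulate_screen()],
#'   plus `library_sizes` (equal per condition, to be passed to
#'   [quantify_expression()]) and `expected` (the per-gene expected class
#'   and shortening call).
#' @export
mimic_screen <- function(outdir = NULL, seed = 155L, depth = 50,
                         step_factor = 10) {
  set.seed(seed)
  tabs <- transcribe_fixture_tables()
  retained <- tabs$targets
  base <- 1e6

  gene <- character(0); fold <- numeric(0); cls <- character(0)
  has8 <- logical(0); has7 <- logical(0); shortened <- logical(0)
  add <- function(g, f, cl, h8, h7, sh) {
    gene <<- c(gene, g)
    fold <<- c(fold, rep(f, length.out = length(g)))
    cls <<- c(cls, rep(cl, length.out = length(g)))
    has8 <<- c(has8, rep(h8, length(g))); has7 <<- c(has7, rep(h7, length(g)))
    shortened <<- c(shortened, rep(sh, length.out = length(g)))
  }
  # the 16 retained increased 8mer targets, folds and shortening as printed
  add(retained$gene, retained$relative_expression, "retained",
      TRUE, FALSE, retained$shortening == "Yes")
  # the 14 increased 8mer targets excluded for low reads
  add(sprintf("LOWREAD%02d", 1:14), 2, "low_read", TRUE, FALSE, rep(FALSE, 14))
  # background: repressed / unchanged 8mer genes, 7mer-only, site-free
  add(sprintf("REP8_%02d", 1:20), seq(0.2, 0.5, length.out = 20), "repressed",
      TRUE, FALSE, rep(FALSE, 20))
  add(sprintf("UNCH8_%02d", 1:20), seq(0.8, 1.4, length.out = 20), "unchanged",
      TRUE, FALSE, rep(FALSE, 20))
  add(sprintf("SEV7_%02d", 1:15), seq(0.4, 2.5, length.out = 15), "background7",
      FALSE, TRUE, rep(FALSE, 15))
  add(sprintf("NOSITE%02d", 1:20), seq(0.6, 1.8, length.out = 20), "nosite",
      FALSE, FALSE, rep(FALSE, 20))

  n <- length(gene)
  L <- as.integer(600 + round(stats::runif(n, 0, 400)))
  low <- cls == "low_read"
  s8 <- ifelse(has8, floor(0.7 * L), NA_integer_)
  s7 <- ifelse(has7, floor(0.2 * L), NA_integer_)
  bp <- ifelse(shortened, floor(0.4 * L), NA_integer_)
  truth <- data.frame(gene = gene, utr_length = L,
                      class = ifelse(low, "low_read",
                              ifelse(fold > 1.5, "up",
                              ifelse(fold <= 0.5, "down", "null"))),
                      true_fold = fold, nb_mean = ifelse(low, 3, base),
                      low_read = low,
                      has_8mer = has8, site_8mer_start = as.integer(s8),
                      has_7mer = has7, site_7mer_start = as.integer(s7),
                      shortened = shortened, seed_lost = shortened,
                      breakpoint = as.integer(bp), stringsAsFactors = FALSE)

  seqres <- simulate_utrs(sim_config(seed = seed), truth)
  cv <- ifelse(low, 3, round(base))
  cm <- ifelse(low, 6, round(base * fold))
  counts <- data.frame(gene = gene, count_vector = as.integer(cv),
                       count_mir155 = as.integer(cm),
                       exon_length_bp = L + 1500L, stringsAsFactors = FALSE)

  tv <- vector("list", n); tm <- vector("list", n)
  for (i in seq_len(n)) {
    scale <- if (low[i]) 0.006 else 1
    lam_m <- rep(depth * scale, L[i])
    if (shortened[i]) lam_m[(bp[i] + 1L):L[i]] <- lam_m[(bp[i] + 1L):L[i]] / step_factor
    tv[[i]] <- stats::rpois(L[i], depth * scale)
    tm[[i]] <- stats::rpois(L[i], lam_m)
  }

  # small collection: one pathway concentrated on the retained cohort
  sets <- c(list(pathway_mapk_like = c(retained$gene,
                                       sprintf("NOSITE%02d", 1:4))),
            lapply(1:5, function(i) sample(gene, 25)))
  names(sets)[-1] <- sprintf("pathway_%02d", 1:5)

  res <- list(config = list(seed = seed, depth = depth,
                            step_factor = step_factor),
              truth = truth, site_truth = seqres$site_truth,
              utrs = seqres$utrs, counts = counts,
              tracks_vector = stats::setNames(tv, gene),
              tracks_mir155 = stats::setNames(tm, gene),
              sets = sets, planted_set = "pathway_mapk_like",
              library_sizes = c(vector = 3e7, mir155 = 3e7),
              expected = data.frame(gene = gene, cohort = cls,
                                    shortened = shortened,
                                    stringsAsFactors = FALSE))
  if (!is.null(outdir)) {
    res$paths <- write_screen(res, outdir)
  }
  invisible(res)
}
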