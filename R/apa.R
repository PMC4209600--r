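#' Fit a two-segment changepoint to a coverage track
#'
#' Finds the split that minimises the piecewise-constant residual sum of
#' squares on `log2(coverage + 1)` (the log transform stabilises the
#' variance of high-coverage positions). The breakpoint is the 0-based
#' offset of the first distal base; ties go to the smallest breakpoint.
#' A track whose best split reduces the one-segment RSS by (numerically)
#' nothing is flagged flat and reported at `k = minseg`.
#'
#' @param coverage Non-negative per-base counts, transcript 5'->3'.
#' @param minseg Minimum segment length on either side of the split.
#' @param transform `"log2"` (default, fit on `log2(x + 1)`) or `"raw"`
#'   (fit on the raw counts; invariant to positive scaling of the track).
#' @return List with `breakpoint` (0-based first distal base),
#'   `proximal_mean`/`distal_mean` (raw coverage scale), `rss` (log2
#'   scale), `flat` flag, and `qc_fail` (TRUE with `breakpoint = NA` when
#'   the track is shorter than `2 * minseg`).
#' @examples
#' fit_breakpoint(c(5, 5, 5, 1, 1, 1), minseg = 1)
#' @export
fit_breakpoint <- function(coverage, minseg = 25L,
                           transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(coverage), all(coverage >= 0), minseg >= 1)
  L <- length(coverage)
  if (L < 2L * minseg) {
    return(list(breakpoint = NA_integer_, proximal_mean = NA_real_,
                distal_mean = NA_real_, rss = NA_real_, flat = NA,
                qc_fail = TRUE))
  }
  y <- if (transform == "log2") log2(coverage + 1) else coverage
  cs <- cumsum(y)
  cs2 <- cumsum(y^2)
  ks <- seq.int(minseg, L - minseg)                 # split after position k
  rss <- (cs2[ks] - cs[ks]^2 / ks) +
         (cs2[L] - cs2[ks] - (cs[L] - cs[ks])^2 / (L - ks))
  rss1 <- cs2[L] - cs[L]^2 / L                      # one-segment RSS
  best <- which.min(rss)                            # which.min takes first tie
  flat <- (rss1 - rss[best]) <= 1e-9 * max(1, rss1)
  k <- if (flat) as.integer(minseg) else as.integer(ks[best])
  list(breakpoint = k,
       proximal_mean = mean(coverage[seq_len(k)]),
       distal_mean = mean(coverage[(k + 1L):L]),
       rss = if (flat) rss[1L] else rss[best],
       flat = flat,
       qc_fail = FALSE)
}

#' Distal usage index
#'
#' Ratio of mean coverage distal to a breakpoint over mean coverage
#' proximal to it. Values near 1 indicate full-length 3'UTR usage; values
#' near 0 indicate the distal UTR is not transcribed (shortening). The
#' pseudocount guards zero proximal coverage.
#'
#' @param coverage Per-base counts.
#' @param breakpoint 0-based offset of the first distal base
#'   (`1 <= breakpoint <= length - 1`).
#' @param pseudocount Added to both means.
#' @return `(mean(distal) + pseudocount) / (mean(proximal) + pseudocount)`.
#' @examples
#' distal_usage_index(c(5, 5, 5, 1, 1, 1), 3, pseudocount = 0)  # 0.2
#' @export
distal_usage_index <- function(coverage, breakpoint, pseudocount = 0.5) {
  L <- length(coverage)
  if (!(breakpoint >= 1 && breakpoint <= L - 1)) {
    stop("breakpoint must leave a non-empty segment on both sides", call. = FALSE)
  }
  prox <- mean(coverage[seq_len(breakpoint)])
  dist <- mean(coverage[(breakpoint + 1L):L])
  (dist + pseudocount) / (prox + pseudocount)
}

#' Default parameters for shortening calls
#'
#' @param tau Shortening threshold on the between-condition DUI ratio
#'   (call shortened when `dui_mir155 / dui_vector <= tau`).
#' @param min_proximal_mean Minimum raw proximal mean coverage in the
#'   miR-155 track for a confident call.
#' @param minseg Minimum changepoint segment length in bp; capped at a
#'   tenth of the UTR length for short UTRs.
#' @param pseudocount DUI pseudocount.
#' @param min_mean_coverage QC floor: either condition's track below this
#'   mean coverage yields no call.
#' @param lost_in_both_cutoff Absolute DUI below which the vector track
#'   itself is annotated as already shortened (`lost_in_both`).
#' @return Named list of parameters.
#' @export
shortening_params <- function(tau = 0.5, min_proximal_mean = 5, minseg = 25L,
                              pseudocount = 0.5, min_mean_coverage = 1,
                              lost_in_both_cutoff = 0.1) {
  stopifnot(tau > 0, minseg >= 1)
  list(tau = tau, min_proximal_mean = min_proximal_mean, minseg = minseg,
       pseudocount = pseudocount, min_mean_coverage = min_mean_coverage,
       lost_in_both_cutoff = lost_in_both_cutoff)
}

#' Call 3'UTR shortening and seed-site loss for one transcript
#'
#' The breakpoint is fitted on the miR-155 track (the condition expected
#' to exhibit shortening) and the same split is applied to the vector
#' track. The transcript is called shortened when the DUI ratio
#' miR-155/vector drops to `tau` or below, the miR-155 proximal coverage
#' clears the confidence floor, and the miR-155 track is not flat. A seed
#' site is lost when the transcript is shortened and the site lies
#' entirely at or beyond the breakpoint. `lost_in_both` annotates
#' transcripts whose vector track already shows negligible distal usage.
#'
#' @param track_vector,track_mir155 Per-base coverage, equal length,
#'   transcript 5'->3'.
#' @param seed_sites Site table for this transcript ([scan_utr()] columns);
#'   may be empty.
#' @param params See [shortening_params()].
#' @param transcript_id Used in messages and the output row.
#' @return One-row data.frame: `transcript_id`, `breakpoint`,
#'   `proximal_mean_vector`, `distal_mean_vector`, `proximal_mean_mir155`,
#'   `distal_mean_mir155`, `dui_vector`, `dui_mir155`, `dui_ratio`,
#'   `shortened`, `seed_lost`, `lost_in_both`, `qc_fail`.
#' @export
call_shortening <- function(track_vector, track_mir155, seed_sites = NULL,
                            params = shortening_params(),
                            transcript_id = "transcript") {
  if (length(track_vector) != length(track_mir155)) {
    stop(sprintf("coverage tracks for '%s' differ in length (%d vs %d)",
                 transcript_id, length(track_vector), length(track_mir155)),
         call. = FALSE)
  }
  L <- length(track_vector)
  minseg <- max(1L, min(as.integer(params$minseg), L %/% 10L))
  no_call <- data.frame(transcript_id = transcript_id, breakpoint = NA_integer_,
                        proximal_mean_vector = NA_real_, distal_mean_vector = NA_real_,
                        proximal_mean_mir155 = NA_real_, distal_mean_mir155 = NA_real_,
                        dui_vector = NA_real_, dui_mir155 = NA_real_,
                        dui_ratio = NA_real_, shortened = NA, seed_lost = NA,
                        lost_in_both = NA, qc_fail = TRUE,
                        stringsAsFactors = FALSE)
  if (L < 2L * minseg ||
      mean(track_vector) < params$min_mean_coverage ||
      mean(track_mir155) < params$min_mean_coverage) {
    return(no_call)
  }
  fit <- fit_breakpoint(track_mir155, minseg = minseg)
  if (fit$qc_fail) return(no_call)
  k <- fit$breakpoint
  dui_v <- distal_usage_index(track_vector, k, params$pseudocount)
  dui_m <- distal_usage_index(track_mir155, k, params$pseudocount)
  ratio <- dui_m / dui_v
  shortened <- (ratio <= params$tau) &&
               (fit$proximal_mean >= params$min_proximal_mean) &&
               !fit$flat
  seed_lost <- FALSE
  if (shortened && !is.null(seed_sites) && nrow(seed_sites)) {
    seed_lost <- any(seed_sites$start >= k)
  }
  data.frame(transcript_id = transcript_id, breakpoint = k,
             proximal_mean_vector = mean(track_vector[seq_len(k)]),
             distal_mean_vector = mean(track_vector[(k + 1L):L]),
             proximal_mean_mir155 = fit$proximal_mean,
             distal_mean_mir155 = fit$distal_mean,
             dui_vector = dui_v, dui_mir155 = dui_m, dui_ratio = ratio,
             shortened = shortened, seed_lost = seed_lost,
             lost_in_both = dui_v <= params$lost_in_both_cutoff,
             qc_fail = FALSE,
             stringsAsFactors = FALSE)
}

#' Call shortening across a set of transcripts
#'
#' @param tracks_vector,tracks_mir155 Named lists of per-base coverage
#'   vectors (names are transcript ids), e.g. from [read_coverage()].
#' @param sites Pooled site table from [scan_utr_set()].
#' @param params See [shortening_params()].
#' @return data.frame with one [call_shortening()] row per transcript
#'   present in both track sets.
#' @export
call_shortening_set <- function(tracks_vector, tracks_mir155, sites = NULL,
                                params = shortening_params()) {
  ids <- intersect(names(tracks_vector), names(tracks_mir155))
  rows <- lapply(ids, function(id) {
    ss <- if (!is.null(sites)) sites[sites$transcript_id == id, , drop = FALSE]
    call_shortening(tracks_vector[[id]], tracks_mir155[[id]], ss,
                    params = params, transcript_id = id)
  })
  do.call(rbind, rows)
}

#' Fraction of a gene's expression escaping the seed-bearing 3'UTR
#'
#' Expression-weighted fraction of isoforms that do not carry the
#' seed-containing 3'UTR — the isoform-level route to miRNA escape
#' (truncated transcripts lacking the targeted UTR).
#'
#' @param isoforms data.frame with columns `isoform_id`, `expression`
#'   (>= 0) and `contains_seed_utr` (logical).
#' @return Fraction in `[0, 1]`.
#' @examples
#' seed_escape_fraction(data.frame(
#'   isoform_id = c("v1", "v2", "v4"),
#'   expression = c(3, 0, 1),
#'   contains_seed_utr = c(TRUE, TRUE, FALSE)))  # 0.25
#' @export
seed_escape_fraction <- function(isoforms) {
  stopifnot(all(c("isoform_id", "expression", "contains_seed_utr") %in% names(isoforms)),
            all(isoforms$expression >= 0))
  total <- sum(isoforms$expression)
  if (total == 0) {
    stop("total isoform expression is 0; escape fraction undefined", call. = FALSE)
  }
  sum(isoforms$expression[!isoforms$contains_seed_utr]) / total
}
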