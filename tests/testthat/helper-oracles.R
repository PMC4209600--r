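# Independent oracles used to freeze expected values. Each is a direct,
# unoptimised restatement of the operation's definition and shares no code
# with the implementation under test.

# Exhaustive offset-by-offset seed scan with the maximal-type rule.
brute_scan <- function(seq, motifs) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  L <- nchar(seq)
  rows <- list()
  is8 <- logical(max(L, 1))
  if (L >= 8) {
    for (i in seq_len(L - 7L)) {
      if (substring(seq, i, i + 7L) == motifs$motif_8mer) {
        is8[i] <- TRUE
        rows[[length(rows) + 1L]] <- c(i - 1L, i + 7L, "8mer")
      }
    }
  }
  if (L >= 7) {
    for (i in seq_len(L - 6L)) {
      w <- substring(seq, i, i + 6L)
      if (w == motifs$motif_7mer_m8 && !is8[i]) {
        rows[[length(rows) + 1L]] <- c(i - 1L, i + 6L, "7mer-m8")
      }
      if (w == motifs$motif_7mer_A1 && !(i > 1 && is8[i - 1L])) {
        rows[[length(rows) + 1L]] <- c(i - 1L, i + 6L, "7mer-A1")
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  }
  d <- data.frame(start = as.integer(vapply(rows, `[`, "", 1)),
                  end = as.integer(vapply(rows, `[`, "", 2)),
                  site_type = vapply(rows, `[`, "", 3),
                  stringsAsFactors = FALSE)
  d <- d[order(d$start, d$site_type), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Exhaustive two-segment RSS minimisation (first minimum wins).
brute_breakpoint <- function(cov, minseg, transform = "log2") {
  y <- if (transform == "log2") log2(cov + 1) else cov
  L <- length(y)
  ks <- seq.int(minseg, L - minseg)
  rss <- vapply(ks, function(k) {
    a <- y[1:k]; b <- y[(k + 1):L]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  list(k = ks[which.min(rss)], rss = min(rss))
}

# Hypergeometric upper tail by enumeration of all n-subsets of 1..N,
# with the gene set taken as 1..K.
enum_upper_tail <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

random_rna_seq <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

mir155_motifs <- function() derive_seed_motifs(mir155())
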