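#' The mature hsa-miR-155-5p sequence
#'
#' Guide-strand sequence used throughout the examples and the mimic
#' preset.
#'
#' @return A [mature_mirna] object.
#' @export
mir155 <- function() {
  mature_mirna("hsa-miR-155-5p", "UUAAUGCUAAUCGUGAUAGGGGU")
}

#' Reference cohort tables from the miR-155/MCF-7 over-expression screen
#'
#' Two published tables from a miR-155 over-expression screen in MCF-7
#' cells, transcribed verbatim for tests and the mimic preset:
#'
#' * `targets`: the 16 increased-expression 8mer-seed-site targets that
#'   survived the low-read filter, with the screen's 3'UTR-shortening
#'   call (`Yes`/`No`) and relative expression (miR-155/vector RPKM
#'   fold).
#' * `sites`: six MAPK-pathway genes with their 7mer/8mer seed-site
#'   counts and shortening call.
#'
#' The two tables disagree for MAP3K14 (shortening `Yes` in `targets`,
#' `No` in `sites`); both are kept as printed, and the narrative count of
#' shortened transcripts (ten) likewise differs from the eleven `Yes`
#' rows of `targets`. Neither discrepancy is resolved here.
#'
#' @return List with data.frames `targets` (columns `gene`, `shortening`,
#'   `relative_expression`) and `sites` (columns `gene`, `n_7mer`,
#'   `n_8mer`, `shortening`).
#' @export
transcribe_fixture_tables <- function() {
  targets <- data.frame(
    gene = c("SPIN2B", "GLT25D1", "MAP3K14", "CARS2", "ARVCF", "AGTRAP",
             "MYLK", "CARD10", "IRF2BP2", "CSNK1G2", "TRMT61A", "MAP3K10",
             "CEBPB", "PRKAR1B", "SOCS1", "SPOCK1"),
    shortening = c("Yes", "No", "Yes", "Yes", "Yes", "Yes",
                   "No", "Yes", "Yes", "No", "Yes", "Yes",
                   "Yes", "Yes", "No", "No"),
    relative_expression = c(1.516575, 1.557417, 1.849516, 1.862035, 2.292287,
                            2.816578, 3.222538, 3.237354, 3.330693, 3.472894,
                            3.627442, 3.813621, 4.871474, 7.552545, 8.080313,
                            20.33727),
    stringsAsFactors = FALSE)
  sites <- data.frame(
    gene = c("RSK2", "Rac1", "k-Ras", "KSR1", "MAP3K14", "MAP3K10"),
    n_7mer = c(1L, 1L, 3L, 0L, 0L, 0L),
    n_8mer = c(0L, 0L, 0L, 1L, 1L, 1L),
    shortening = c("No", "Yes", "No", "No", "No", "Yes"),
    stringsAsFactors = FALSE)
  list(targets = targets, sites = sites)
}
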