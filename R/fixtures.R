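#' Bundled three-dyad case-study dataset
#'
#' Summary-variable scores for three therapist-client dyads from different
#' therapy traditions: Dyad A (psychoanalysis, 15 sessions), Dyad B
#' (cognitive-behavioral therapy, 14 sessions) and Dyad C (humanistic
#' therapy, 20 sessions). Each dyad contributes one client and one therapist
#' sub-transcript per session (30, 28 and 40 rows), scored on the four 0-100
#' summary variables by the commercial LIWC program. The raw transcripts are
#' licensed and not distributed; only this numeric table is shipped, exactly
#' as published, to two decimals.
#'
#' `dyad_expected_outcomes()` returns the dataset's reference synchrony
#' outcomes: the cluster count used for each dyad's reference analysis
#' (3, 2, 2 — chosen by visual elbow-plot inspection), the synchronized
#' session sets and the percentages. For Dyad A the automatic
#' second-difference elbow rule prefers k = 2; the reference analysis reads
#' the elbow at k = 3 (see the package vignette), and
#' `dyad_synchrony(dyad_profiles("A"), k = 3)` reproduces the reference
#' outcome.
#'
#' @param dyad One of `"A"`, `"B"`, `"C"`.
#' @return `dyad_profiles()`: an assembled profile tibble (see
#'   [assemble_profiles()]). `dyad_expected_outcomes()`: a tibble with one
#'   row per dyad (`dyad_id`, `n_sessions`, `k`, `synchronized` list-column,
#'   `percentage`).
#' @examples
#' dyad_profiles("A")
#' dyad_expected_outcomes()
#' @export
dyad_profiles <- function(dyad = c("A", "B", "C")) {
  dyad <- match.arg(dyad)
  path <- lingsync_example(sprintf("dyad_%s_profiles.csv", dyad))
  assemble_profiles(read_profiles(path))
}

#' @rdname dyad_profiles
#' @export
dyad_expected_outcomes <- function() {
  tibble(
    dyad_id = c("A", "B", "C"),
    n_sessions = c(15L, 14L, 20L),
    k = c(3L, 2L, 2L),
    synchronized = list(c(2L, 8L, 10L, 11L, 12L), integer(0),
                        c(9L, 11L, 12L, 14L, 17L)),
    percentage = c(33.3, 0, 25)
  )
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/` (e.g. `"toy.dic"`,
#'   `"dyad_A_profiles.csv"`); with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
lingsync_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "lingsync")))
  }
  path <- system.file("extdata", file, package = "lingsync")
  if (path == "") abort_data(sprintf("No packaged example file \"%s\".", file))
  path
}
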