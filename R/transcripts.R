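#' Default speaker-label mapping
#'
#' Maps the line-initial labels found in a transcript to the two dyad roles.
#' Labels are matched case-sensitively against uppercase line prefixes such
#' as `"THERAPIST:"`. Supply your own named character vector (values must be
#' `"therapist"` or `"client"`) when transcripts use other labels, e.g.
#' `c(DR_X = "therapist", PT = "client")`.
#'
#' @return A named character vector mapping label to role.
#' @export
default_speaker_map <- function() {
  c(THERAPIST = "therapist", CLIENT = "client")
}

check_speaker_map <- function(speaker_map) {
  if (is.null(names(speaker_map)) || any(names(speaker_map) == "") ||
      !all(speaker_map %in% c("therapist", "client"))) {
    abort_usage("`speaker_map` must be a named character vector with values \"therapist\" or \"client\".")
  }
  speaker_map
}

# annotations such as "[inaudible]" or "(laughs)" carry no scored speech
strip_annotations <- function(x) {
  x <- stringr::str_remove_all(x, "\\[[^\\]]*\\]")
  x <- stringr::str_remove_all(x, "\\([^)]*\\)")
  stringr::str_squish(x)
}

#' Parse a speaker-turn transcript
#'
#' Splits raw transcript text into conversational turns. A turn starts at a
#' line-initial uppercase label followed by a colon (`"CLIENT: ..."`); lines
#' without a label continue the current turn. Bracketed annotations such as
#' `"[inaudible]"` and parenthetical stage directions are stripped, and turns
#' left empty by stripping are dropped.
#'
#' @param raw_text Transcript text: a single string (possibly with embedded
#'   newlines, LF or CRLF) or a character vector of lines.
#' @param speaker_map Named character vector mapping line-initial labels to
#'   roles; see [default_speaker_map()].
#' @param session Session index (1-based) stamped onto every turn.
#' @return A tibble with columns `session`, `turn`, `speaker` and `text`,
#'   one row per conversational turn in original order.
#' @examples
#' parse_transcript("THERAPIST: Hmm.\nCLIENT: Yeah.")
#' @export
parse_transcript <- function(raw_text, speaker_map = default_speaker_map(),
                             session = 1L) {
  check_speaker_map(speaker_map)
  if (!is.character(raw_text)) abort_usage("`raw_text` must be character.")
  session <- as.integer(session)
  if (is.na(session) || session < 1L) abort_usage("`session` must be a positive integer.")

  lines <- unlist(strsplit(gsub("\r\n?", "\n", paste(raw_text, collapse = "\n")),
                           "\n", fixed = TRUE))
  prefix_re <- "^\\s*([A-Z][A-Z0-9_]*)\\s*:\\s*"

  empty_turns <- tibble(session = integer(0), turn = integer(0),
                        speaker = character(0), text = character(0))
  if (!any(nzchar(trimws(lines)))) return(empty_turns)  # blank session

  speakers <- character(0)
  texts <- character(0)
  current <- 0L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    m <- stringr::str_match(line, prefix_re)
    if (!is.na(m[1, 1])) {
      label <- m[1, 2]
      if (!label %in% names(speaker_map)) {
        abort_data(sprintf("Unknown speaker label \"%s\" on line %d.", label, i))
      }
      current <- current + 1L
      speakers[current] <- speaker_map[[label]]
      texts[current] <- stringr::str_remove(line, prefix_re)
    } else {
      if (current == 0L) {
        abort_data(sprintf("Content before the first speaker label (line %d).", i))
      }
      texts[current] <- paste(texts[current], trimws(line))
    }
  }
  if (current == 0L) {
    abort_data("No recognizable speaker prefixes (\"LABEL:\") found in transcript.")
  }

  out <- tibble(
    session = session,
    turn = seq_len(current),
    speaker = speakers,
    text = strip_annotations(texts)
  )
  out <- dplyr::filter(out, nzchar(.data$text))
  out$turn <- seq_len(nrow(out))
  out
}

#' Split a session's turns into role sub-transcripts
#'
#' Pools all of each speaker's turns, in order, into a single
#' "sub-transcript" — the unit that is scored and clustered downstream. Both
#' roles are always returned; a role with no turns yields an empty
#' sub-transcript with `token_count` 0.
#'
#' @param turns A tibble of turns as returned by [parse_transcript()].
#' @param dyad_id Identifier of the dyad.
#' @param session Session index; defaults to the (single) value found in
#'   `turns`.
#' @return A tibble with one row per role and columns `dyad_id`, `role`,
#'   `session`, `token_count` and `text` (client row first).
#' @export
split_by_role <- function(turns, dyad_id, session = NULL) {
  if (is.null(session)) {
    session <- unique(turns$session)
    if (length(session) > 1L) abort_usage("`turns` spans multiple sessions; supply one session at a time.")
    if (length(session) == 0L) session <- 1L
  }
  purrr::map_dfr(c("client", "therapist"), function(r) {
    txt <- paste(turns$text[turns$speaker == r], collapse = " ")
    txt <- stringr::str_squish(txt)
    tibble(
      dyad_id = dyad_id, role = r, session = as.integer(session),
      token_count = length(tokenize(txt)), text = txt
    )
  })
}

#' Load a dyad's sessions from transcript files
#'
#' Reads one transcript file per session (file order defines the 1-based
#' session index) and returns all sub-transcripts of the dyad.
#'
#' @param paths Character vector of transcript file paths, one per session,
#'   in session order.
#' @param dyad_id Identifier of the dyad.
#' @param speaker_map See [default_speaker_map()].
#' @param quiet Suppress the per-session token-count messages.
#' @return A tibble of `2 * length(paths)` sub-transcripts (see
#'   [split_by_role()]).
#' @export
load_dyad <- function(paths, dyad_id, speaker_map = default_speaker_map(),
                      quiet = FALSE) {
  check_speaker_map(speaker_map)
  purrr::map_dfr(seq_along(paths), function(i) {
    path <- paths[[i]]
    if (!file.exists(path)) abort_data(sprintf("Cannot read transcript file \"%s\".", path))
    raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
    turns <- parse_transcript(raw, speaker_map, session = i)
    subs <- split_by_role(turns, dyad_id = dyad_id, session = i)
    if (!quiet) {
      inform(sprintf("session %d: %d client / %d therapist tokens", i,
                     subs$token_count[subs$role == "client"],
                     subs$token_count[subs$role == "therapist"]))
    }
    subs
  })
}

#' Read a session manifest
#'
#' A manifest is a CSV with columns `session_index` and `path` that fixes
#' the session order of a dyad's transcript files explicitly.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble sorted by `session_index`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("Cannot read manifest \"%s\".", path))
  m <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("session_index", "path") %in% names(m))) {
    abort_data("Manifest must have columns `session_index` and `path`.")
  }
  dplyr::arrange(m, .data$session_index)
}

#' Write sub-transcripts to CSV
#'
#' @param subs Sub-transcript tibble from [split_by_role()] or [load_dyad()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subtranscripts <- function(subs, path) {
  readr::write_csv(subs[, c("dyad_id", "role", "session", "token_count", "text")], path)
  invisible(path)
}
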