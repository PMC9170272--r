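#' Assemble and validate a dyad's profile matrix
#'
#' Checks that the profiles cover one dyad with both roles present for every
#' session, and orders rows client-first (C1..Cn then T1..Tn). A `label`
#' column in that convention is added.
#'
#' @param profiles Profile tibble (columns `dyad_id`, `role`, `session` and
#'   the four summary variables), e.g. from [score_subtranscripts()],
#'   [read_profiles()] or [dyad_profiles()].
#' @param drop_degenerate Drop sessions whose profiles are flagged
#'   `degenerate` (both rows of such sessions are removed).
#' @return The validated, ordered profile tibble with attributes
#'   `standardized = FALSE` and `centered = FALSE`.
#' @export
assemble_profiles <- function(profiles, drop_degenerate = FALSE) {
  need <- c("dyad_id", "role", "session", sync_vars)
  missing <- setdiff(need, names(profiles))
  if (length(missing)) {
    abort_data(sprintf("Profile table is missing columns: %s.", paste(missing, collapse = ", ")))
  }
  if (length(unique(profiles$dyad_id)) != 1L) {
    abort_data("`profiles` must cover exactly one dyad.")
  }
  if (drop_degenerate && "degenerate" %in% names(profiles)) {
    bad <- unique(profiles$session[profiles$degenerate])
    profiles <- profiles[!profiles$session %in% bad, ]
  }
  vals <- as.matrix(profiles[, sync_vars])
  if (anyNA(vals)) abort_data("Profile table contains missing values.")

  by_sess <- split(profiles$role, profiles$session)
  incomplete <- names(by_sess)[!purrr::map_lgl(by_sess, ~ setequal(.x, c("therapist", "client")))]
  if (length(incomplete)) {
    abort_data(sprintf("Both roles are required for every session; incomplete sessions: %s.",
                       paste(incomplete, collapse = ", ")))
  }

  out <- dplyr::arrange(profiles, dplyr::desc(.data$role == "client"), .data$session)
  out <- dplyr::mutate(out, label = role_label(.data$role, .data$session),
                       .after = "session")
  out <- as_tibble(out)
  attr(out, "standardized") <- FALSE
  attr(out, "centered") <- FALSE
  out
}

# numeric matrix of the four variables with C/T row labels
profile_values <- function(profiles) {
  m <- as.matrix(profiles[, sync_vars])
  rownames(m) <- if ("label" %in% names(profiles)) profiles$label
                 else role_label(profiles$role, profiles$session)
  m
}

is_standardized <- function(profiles) isTRUE(attr(profiles, "standardized"))

#' Z-score the summary variables of a profile matrix
#'
#' Standardizes each variable to mean 0 and SD 1 over all of the dyad's
#' sub-transcripts pooled across roles, so that a negative value means the
#' score is below that dyad's average. Standardization is per dyad: the
#' clustering of one dyad never depends on another dyad's data.
#'
#' @param profiles Profile tibble (ordered with [assemble_profiles()] if row
#'   convention matters downstream).
#' @param sd_type `"sample"` (denominator n-1, the default) or
#'   `"population"` (n).
#' @return The profile tibble with the four variables standardized and
#'   attribute `standardized = TRUE`.
#' @export
zscore_profiles <- function(profiles, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  out <- profiles
  n <- nrow(out)
  for (v in sync_vars) {
    x <- out[[v]]
    s <- sd(x)
    if (sd_type == "population") s <- s * sqrt((n - 1) / n)
    if (!is.finite(s) || s == 0) {
      abort_degenerate(sprintf("Variable \"%s\" has zero variance; cannot z-score.", v))
    }
    out[[v]] <- (x - mean(x)) / s
  }
  attr(out, "standardized") <- TRUE
  attr(out, "centered") <- attr(profiles, "centered") %||% FALSE
  out
}

#' Mean-center each variable within speaker
#'
#' Subtracts, within each role, the speaker's own mean of each variable.
#' This disentangles within-person from between-person variation and is off
#' by default in [dyad_synchrony()]; apply it before [zscore_profiles()].
#'
#' @param profiles Profile tibble (not yet standardized).
#' @return The centered profile tibble with attribute `centered = TRUE`.
#' @export
mean_center_by_speaker <- function(profiles) {
  if (is_standardized(profiles)) {
    abort_usage("Mean-centering must be applied before z-scoring.")
  }
  out <- dplyr::mutate(
    profiles,
    dplyr::across(dplyr::all_of(sync_vars), ~ .x - mean(.x)),
    .by = "role"
  )
  out <- as_tibble(out)
  attr(out, "standardized") <- FALSE
  attr(out, "centered") <- TRUE
  out
}

#' Read / write profile tables
#'
#' CSV layout: `dyad_id`, `role`, `session`, `analytic`, `clout`,
#' `authentic`, `tone` (plus optional `degenerate`). Values are written at
#' full precision so a write/read round trip is exact.
#'
#' @param path CSV path.
#' @return `read_profiles()`: a profile tibble. `write_profiles()`: `path`,
#'   invisibly.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("Cannot read profile table \"%s\".", path))
  p <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("dyad_id", "role", "session", sync_vars), names(p))
  if (length(missing)) {
    abort_data(sprintf("\"%s\" is not a profile table; missing columns: %s.",
                       path, paste(missing, collapse = ", ")))
  }
  p$dyad_id <- as.character(p$dyad_id)
  p
}

#' @param profiles Profile tibble.
#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  keep <- intersect(c("dyad_id", "role", "session", sync_vars, "degenerate"),
                    names(profiles))
  readr::write_csv(profiles[, keep], path)
  invisible(path)
}
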