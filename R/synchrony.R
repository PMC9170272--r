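#' Session synchrony from a clustering solution
#'
#' Applies the co-membership rule: session `x` is synchronized iff the
#' therapist sub-transcript `Tx` and the client sub-transcript `Cx` are
#' assigned to the same cluster. The result is invariant under relabeling of
#' clusters and reordering of rows or variables.
#'
#' With `k = 1` every session trivially co-clusters, so the 100% measure is
#' degenerate and a warning is raised; inspect the elbow plot before
#' trusting such a result.
#'
#' @param solution A [kmeans_fit()] solution whose assignment names follow
#'   the `C<session>` / `T<session>` label convention.
#' @param n_sessions Number of sessions; defaults to the largest session
#'   index found among the labels.
#' @param dyad_id Optional dyad identifier carried into the outcome.
#' @return A `synchrony_outcome`: list with `dyad_id`, `n_sessions`, `k`,
#'   `session_flags` (logical, index = session), `synchronized_sessions`,
#'   `percentage` (0-100, exact; printed to 1 decimal), and `runs` (tibble
#'   run-length encoding of the flags: `start`, `length`, `synchronized`).
#' @export
session_synchrony <- function(solution, n_sessions = NULL, dyad_id = NULL) {
  a <- solution$assignments
  labels <- names(a)
  if (is.null(labels)) abort_usage("Solution assignments carry no C/T session labels.")
  if (is.null(n_sessions)) {
    sess <- suppressWarnings(as.integer(sub("^[CT]", "", labels[grepl("^[CT][0-9]+$", labels)])))
    if (!length(sess)) abort_usage("No C<session>/T<session> labels found in the solution.")
    n_sessions <- max(sess)
  }
  need <- c(paste0("C", seq_len(n_sessions)), paste0("T", seq_len(n_sessions)))
  missing <- setdiff(need, labels)
  if (length(missing)) {
    abort_data(sprintf("Solution is missing sub-transcripts: %s.", paste(missing, collapse = ", ")))
  }
  flags <- unname(a[paste0("T", seq_len(n_sessions))] == a[paste0("C", seq_len(n_sessions))])
  if (solution$k == 1L) {
    warn("k = 1: every session co-clusters by construction; the synchrony measure is degenerate.")
  }
  r <- rle(flags)
  runs <- tibble(
    start = cumsum(c(1L, head(r$lengths, -1L))),
    length = r$lengths,
    synchronized = r$values
  )
  structure(
    list(
      dyad_id = dyad_id %||% attr(solution, "dyad_id"),
      n_sessions = as.integer(n_sessions),
      k = solution$k,
      session_flags = flags,
      synchronized_sessions = which(flags),
      percentage = 100 * sum(flags) / n_sessions,
      runs = runs,
      degenerate_k1 = solution$k == 1L
    ),
    class = "synchrony_outcome"
  )
}

#' @export
print.synchrony_outcome <- function(x, ...) {
  cat(sprintf(
    "<synchrony_outcome>%s %d/%d sessions synchronized (%.1f%%) at k = %d\n",
    if (is.null(x$dyad_id)) "" else paste0(" dyad ", x$dyad_id, ":"),
    length(x$synchronized_sessions), x$n_sessions, x$percentage, x$k
  ))
  if (length(x$synchronized_sessions)) {
    cat("  synchronized sessions:", paste(x$synchronized_sessions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.synchrony_outcome <- function(x, ...) {
  tibble(session = seq_len(x$n_sessions), synchronized = x$session_flags)
}

#' @export
glance.synchrony_outcome <- function(x, ...) {
  sync_runs <- x$runs[x$runs$synchronized, ]
  tibble(
    dyad_id = x$dyad_id %||% NA_character_,
    n_sessions = x$n_sessions,
    k = x$k,
    n_synchronized = length(x$synchronized_sessions),
    percentage = x$percentage,
    longest_sync_run = if (nrow(sync_runs)) max(sync_runs$length) else 0L
  )
}

#' Temporal distribution of (a)synchrony
#'
#' Run-length view of the session flags: contiguous synchronized blocks,
#' the longest block, and the first/last synchronized session. Salient
#' patterns (contiguous late blocks vs. intermittent singletons) are the
#' entry points for qualitative reading of the transcripts.
#'
#' @param outcome A [session_synchrony()] outcome.
#' @return A `synchrony_distribution`: list with `runs` (tibble), `longest`
#'   (start/length of the longest synchronized block), `first_synchronized`,
#'   `last_synchronized` and a one-line `text` summary.
#' @export
distribution_summary <- function(outcome) {
  runs <- outcome$runs
  sync_runs <- runs[runs$synchronized, , drop = FALSE]
  longest <- if (nrow(sync_runs)) sync_runs[which.max(sync_runs$length), ] else NULL
  sync <- outcome$synchronized_sessions
  text <- if (!length(sync)) {
    sprintf("No synchronized sessions across the %d-session span.", outcome$n_sessions)
  } else {
    sprintf(
      "%d synchronized session%s between sessions %d and %d; longest contiguous block: %d session%s starting at session %d.",
      length(sync), if (length(sync) > 1) "s" else "", min(sync), max(sync),
      longest$length, if (longest$length > 1) "s" else "", longest$start
    )
  }
  structure(
    list(runs = runs, longest = longest,
         first_synchronized = if (length(sync)) min(sync) else NA_integer_,
         last_synchronized = if (length(sync)) max(sync) else NA_integer_,
         text = text),
    class = "synchrony_distribution"
  )
}

#' @export
print.synchrony_distribution <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Assemble a machine-readable synchrony report
#'
#' Collects the synchrony outcome, cluster centers, elbow scan and 2-D
#' projection into one JSON-serializable report that echoes the full
#' configuration (seed, k, preprocessing choices), so a run can be
#' replicated exactly. Identical configuration and inputs yield
#' byte-identical JSON.
#'
#' @param outcome A [session_synchrony()] outcome.
#' @param centers Optional [cluster_centers_table()] tibble.
#' @param elbow Optional [elbow_scan()].
#' @param projection Optional [pca_project()] result (omitted gracefully when
#'   unavailable, e.g. fewer than 3 rows).
#' @param config Named list of configuration values to echo.
#' @return A `synchrony_report` list matching the JSON schema.
#' @export
synchrony_report <- function(outcome, centers = NULL, elbow = NULL,
                             projection = NULL, config = list()) {
  for (part in list(centers, elbow, projection)) {
    part_dyad <- attr(part, "dyad_id", exact = TRUE)
    if (!is.null(part_dyad) && !is.null(outcome$dyad_id) && !identical(part_dyad, outcome$dyad_id)) {
      abort_data(sprintf("Report parts disagree on the dyad (\"%s\" vs \"%s\").",
                         outcome$dyad_id, part_dyad))
    }
  }
  report <- list(
    dyad_id = outcome$dyad_id,
    n_sessions = outcome$n_sessions,
    k = outcome$k,
    seed = config$seed,
    flags = outcome$session_flags,
    synchronized_sessions = as.integer(outcome$synchronized_sessions),
    percentage = round(outcome$percentage, 1),
    runs = outcome$runs,
    degenerate_k1 = isTRUE(outcome$degenerate_k1),
    centers = if (!is.null(centers)) unname(purrr::transpose(as.list(centers))) else NULL,
    elbow = if (!is.null(elbow)) list(k = elbow$scan$k, distortion = elbow$scan$distortion) else NULL,
    projection = if (!is.null(projection)) {
      list(label = projection$label, pc1 = projection$pc1, pc2 = projection$pc2,
           var_explained = attr(projection, "var_explained"))
    } else NULL,
    config = config
  )
  report[!purrr::map_lgl(report, is.null)] -> report
  class(report) <- "synchrony_report"
  report
}

#' Serialize a synchrony report to JSON
#'
#' @param report A [synchrony_report()].
#' @param path Output path; the JSON is written with a fixed 10-digit
#'   numeric precision so identical runs produce byte-identical files.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                           dataframe = "columns")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Run the full synchrony pipeline on one dyad's profiles
#'
#' Convenience wrapper over the whole measurement stage: validates and
#' orders the profiles ([assemble_profiles()]), optionally mean-centers
#' within speaker, z-scores ([zscore_profiles()]), scans cluster numbers
#' ([elbow_scan()]), clusters at the elbow-selected (or overridden) `k`
#' ([kmeans_fit()]), and applies the co-membership rule
#' ([session_synchrony()]). Cluster centers and a 2-D principal-component
#' projection are attached for validation and plotting.
#'
#' @param profiles Profile tibble for one dyad.
#' @param k Optional override of the cluster number. The elbow scan is a
#'   numerical reading of the distortion curve; when visual inspection of
#'   the elbow plot supports a different k (adjacent curvatures can be
#'   close), pass it here — the report records both the scan and the k used.
#' @param standardize Z-score the variables first (default `TRUE`).
#' @param mean_center Mean-center within speaker before standardizing
#'   (default `FALSE`).
#' @param k_min,k_max Elbow-scan range; `k_max` is clamped to `nrow - 1`.
#' @param n_restarts,seed Passed to [kmeans_fit()] / [elbow_scan()].
#' @param sd_type Passed to [zscore_profiles()].
#' @param drop_degenerate Passed to [assemble_profiles()].
#' @return A `dyad_synchrony` object: list with `profiles` (preprocessed),
#'   `elbow`, `solution`, `centers`, `projection`, `outcome`, `report`.
#' @examples
#' res <- dyad_synchrony(dyad_profiles("B"))
#' res$outcome
#' @export
dyad_synchrony <- function(profiles, k = NULL, standardize = TRUE,
                           mean_center = FALSE, k_min = 1, k_max = 10,
                           n_restarts = 50, seed = 0,
                           sd_type = c("sample", "population"),
                           drop_degenerate = FALSE) {
  sd_type <- match.arg(sd_type)
  prof <- assemble_profiles(profiles, drop_degenerate = drop_degenerate)
  dyad_id <- prof$dyad_id[[1]]
  if (mean_center) prof <- mean_center_by_speaker(prof)
  if (standardize) prof <- zscore_profiles(prof, sd_type = sd_type)

  k_max_eff <- min(as.integer(k_max), nrow(prof) - 1L)
  elbow <- if (k_max_eff - as.integer(k_min) >= 2L) {
    elbow_scan(prof, k_min = k_min, k_max = k_max_eff,
               n_restarts = n_restarts, seed = seed)
  } else NULL
  if (is.null(elbow) && is.null(k)) {
    abort_usage("Too few sub-transcripts for an elbow scan; supply `k` explicitly.")
  }
  k_used <- if (is.null(k)) elbow$chosen_k else as.integer(k)

  solution <- kmeans_fit(prof, k_used, n_restarts = n_restarts, seed = seed)
  attr(solution, "dyad_id") <- dyad_id
  centers <- cluster_centers_table(solution, prof)
  projection <- if (nrow(prof) >= 3L) {
    tryCatch(pca_project(prof), lingsync_degenerate_error = function(e) NULL)
  } else NULL

  outcome <- session_synchrony(solution, n_sessions = nrow(prof) / 2L,
                               dyad_id = dyad_id)
  config <- list(
    dyad_id = dyad_id, k = k_used, k_override = !is.null(k),
    k_min = as.integer(k_min), k_max = k_max_eff,
    n_restarts = as.integer(n_restarts), seed = as.integer(seed),
    standardize = standardize, mean_center = mean_center, sd_type = sd_type
  )
  report <- synchrony_report(outcome, centers = centers, elbow = elbow,
                             projection = projection, config = config)
  structure(
    list(profiles = prof, elbow = elbow, solution = solution,
         centers = centers, projection = projection, outcome = outcome,
         report = report),
    class = "dyad_synchrony"
  )
}

#' @export
print.dyad_synchrony <- function(x, ...) {
  print(x$elbow)
  print(x$solution)
  print(x$outcome)
  invisible(x)
}

#' @export
glance.dyad_synchrony <- function(x, ...) glance(x$outcome)

#' @export
tidy.dyad_synchrony <- function(x, ...) {
  a <- x$solution$assignments
  n <- x$outcome$n_sessions
  tibble(
    session = seq_len(n),
    therapist_cluster = unname(a[paste0("T", seq_len(n))]),
    client_cluster = unname(a[paste0("C", seq_len(n))]),
    synchronized = x$outcome$session_flags
  )
}
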