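#' Read a LIWC-style category dictionary
#'
#' Parses the de-facto standard `.dic` layout: a header block delimited by
#' lines containing only `%`, with one `id<TAB>name` pair per line, followed
#' by entry lines `pattern<TAB>id[<TAB>id...]`. Patterns are literal words or
#' stems with a single trailing `*` wildcard (prefix match). Matching is
#' case-insensitive: patterns are stored lowercase and tokens are lowercased
#' before lookup.
#'
#' The proprietary LIWC dictionary is *not* shipped; supply your own `.dic`
#' file (the package bundles a small open toy dictionary for examples and
#' tests, see `lingsync_example("toy.dic")`).
#'
#' @param path Path to a `.dic` file.
#' @return An object of class `liwc_dictionary`: a list with elements
#'   `categories` (tibble of `id`, `name`), `literals` (named list mapping
#'   word to integer category ids) and `wildcards` (tibble of `stem`, `ids`).
#' @export
read_dic <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("Cannot read dictionary \"%s\".", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L) abort_data("Not a .dic file: missing '%'-delimited category header.")

  header <- lines[(pct[1] + 1):(pct[2] - 1)]
  header <- header[nzchar(trimws(header))]
  fields <- stringr::str_split(trimws(header), "\\s+")
  ids <- suppressWarnings(as.integer(purrr::map_chr(fields, 1)))
  if (anyNA(ids)) abort_data("Malformed category header: non-integer category id.")
  cats <- tibble(id = ids, name = purrr::map_chr(fields, ~ paste(.x[-1], collapse = " ")))
  if (anyDuplicated(cats$id)) abort_data("Duplicate category id in header.")

  body <- lines[-seq_len(pct[2])]
  literals <- list()
  wc_stem <- character(0)
  wc_ids <- list()
  for (off in seq_along(body)) {
    line <- trimws(body[[off]])
    if (!nzchar(line)) next
    parts <- stringr::str_split(line, "\\s+")[[1]]
    pattern <- tolower(parts[[1]])
    entry_ids <- suppressWarnings(as.integer(parts[-1]))
    lineno <- pct[2] + off
    if (length(entry_ids) == 0L || anyNA(entry_ids)) {
      abort_data(sprintf("Malformed entry on line %d of \"%s\".", lineno, path))
    }
    bad <- setdiff(entry_ids, cats$id)
    if (length(bad)) {
      abort_data(sprintf("Entry \"%s\" (line %d) uses undeclared category id %s.",
                         pattern, lineno, paste(bad, collapse = ", ")))
    }
    stars <- stringr::str_count(pattern, "\\*")
    if (stars > 1L || (stars == 1L && !stringr::str_ends(pattern, "\\*"))) {
      abort_data(sprintf("Pattern \"%s\" (line %d): at most one wildcard, in final position.",
                         pattern, lineno))
    }
    if (stars == 1L) {
      stem <- stringr::str_sub(pattern, end = -2L)
      if (stem %in% wc_stem) {
        warn(sprintf("Duplicate pattern \"%s\": last definition wins.", pattern))
        wc_ids[[match(stem, wc_stem)]] <- entry_ids
      } else {
        wc_stem <- c(wc_stem, stem)
        wc_ids <- c(wc_ids, list(entry_ids))
      }
    } else {
      if (!is.null(literals[[pattern]])) {
        warn(sprintf("Duplicate pattern \"%s\": last definition wins.", pattern))
      }
      literals[[pattern]] <- entry_ids
    }
  }

  structure(
    list(categories = cats, literals = literals,
         wildcards = tibble(stem = wc_stem, ids = wc_ids)),
    class = "liwc_dictionary"
  )
}

#' @export
print.liwc_dictionary <- function(x, ...) {
  cat(sprintf("<liwc_dictionary> %d categories, %d literal and %d wildcard patterns\n",
              nrow(x$categories), length(x$literals), nrow(x$wildcards)))
  invisible(x)
}

#' Tokenize text into lowercase word tokens
#'
#' Tokens are maximal runs of letters/digits joined by internal apostrophes
#' (so contractions like `"it's"` stay one token); punctuation is discarded
#' and curly apostrophes are normalized.
#'
#' @param text A character scalar (or vector, concatenated in order).
#' @return Character vector of lowercase tokens.
#' @examples
#' tokenize("It's so hard.")
#' @export
tokenize <- function(text) {
  text <- paste(text, collapse = " ")
  text <- stringr::str_replace_all(text, "[’ʼ]", "'")
  toks <- stringr::str_extract_all(tolower(text), "[[:alnum:]]+(?:'[[:alnum:]]+)*")[[1]]
  toks
}

# integer category ids matched by each unique token (literal + wildcard)
match_token_ids <- function(token, dictionary) {
  ids <- dictionary$literals[[token]]
  if (nrow(dictionary$wildcards)) {
    hit <- startsWith(token, dictionary$wildcards$stem)
    if (any(hit)) ids <- c(ids, unlist(dictionary$wildcards$ids[hit]))
  }
  unique(ids)
}

#' Score word-category percentages
#'
#' Computes, for every dictionary category, the percentage of tokens matching
#' any of its patterns. A token may count toward several categories; within
#' one category a token counts once no matter how many patterns it matches.
#'
#' @param tokens Character vector of tokens from [tokenize()].
#' @param dictionary A [read_dic()] dictionary.
#' @return A tibble with columns `category`, `count` and `percentage`
#'   (0-100), one row per category, with attributes `token_count` and
#'   `degenerate` (`TRUE` when `token_count` is 0, in which case all
#'   percentages are 0).
#' @export
score_categories <- function(tokens, dictionary) {
  stopifnot(inherits(dictionary, "liwc_dictionary"))
  n <- length(tokens)
  counts <- setNames(rep(0, nrow(dictionary$categories)), dictionary$categories$name)
  if (n > 0L && nrow(dictionary$categories) > 0L) {
    tab <- table(tokens)
    for (i in seq_along(tab)) {
      ids <- match_token_ids(names(tab)[[i]], dictionary)
      if (length(ids)) {
        at <- match(ids, dictionary$categories$id)
        counts[at] <- counts[at] + as.integer(tab[[i]])
      }
    }
  }
  out <- tibble(
    category = dictionary$categories$name,
    count = as.integer(unname(counts)),
    percentage = if (n > 0L) unname(100 * counts / n) else rep(0, length(counts))
  )
  attr(out, "token_count") <- n
  attr(out, "degenerate") <- n == 0L
  out
}

#' Define a summary-variable composition
#'
#' A summary variable is a signed composition of category percentages:
#' `offset + sum(positive percentages) - sum(negative percentages)`, clamped
#' to \[0, 100\]. Category names must match the dictionary in use.
#'
#' @param name Variable name.
#' @param positive,negative Character vectors of category names entering with
#'   `+`/`-` sign; jointly non-empty and disjoint.
#' @param offset Additive offset (default 50, the scale midpoint).
#' @return A `summary_spec` object.
#' @export
summary_spec <- function(name, positive = character(0), negative = character(0),
                         offset = 50) {
  if (length(positive) + length(negative) == 0L) {
    abort_usage("A summary variable needs at least one category.")
  }
  if (length(intersect(positive, negative))) {
    abort_usage("`positive` and `negative` categories must be disjoint.")
  }
  structure(list(name = name, positive = positive, negative = negative,
                 offset = offset),
            class = "summary_spec")
}

#' Default compositions of the four summary variables
#'
#' The canonical signed compositions, in terms of the category names used by
#' the bundled toy dictionary:
#' * **analytic**: + articles, prepositions; − pronouns, auxiliary verbs,
#'   conjunctions, adverbs, negations.
#' * **clout**: + first-person plural and second-person pronouns;
#'   − tentative words.
#' * **authentic**: + first-person singular and third-person pronouns,
#'   exclusive words; − negative-emotion words, motion verbs.
#' * **tone**: + positive-emotion words; − negative-emotion words.
#'
#' The exact standardizations used by the commercial LIWC program are
#' unpublished, so scores from these open compositions are *not* numerically
#' comparable with LIWC output; they share only the 0-100 scale and the sign
#' structure. Adjust the category names to match your own dictionary.
#'
#' @param offset Offset passed to every [summary_spec()] (default 50).
#' @return Named list of four `summary_spec` objects.
#' @export
default_summary_specs <- function(offset = 50) {
  list(
    analytic = summary_spec("analytic",
      positive = c("article", "preposition"),
      negative = c("pronoun", "auxverb", "conjunction", "adverb", "negation"),
      offset = offset),
    clout = summary_spec("clout",
      positive = c("we", "you"),
      negative = "tentative",
      offset = offset),
    authentic = summary_spec("authentic",
      positive = c("i", "third_person", "exclusive"),
      negative = c("negemo", "motion"),
      offset = offset),
    tone = summary_spec("tone",
      positive = "posemo",
      negative = "negemo",
      offset = offset)
  )
}

#' Evaluate one summary variable on a category profile
#'
#' @param profile Category profile from [score_categories()].
#' @param spec A [summary_spec()].
#' @return The composition value, clamped to \[0, 100\].
#' @export
summary_variable <- function(profile, spec) {
  stopifnot(inherits(spec, "summary_spec"))
  need <- c(spec$positive, spec$negative)
  missing <- setdiff(need, profile$category)
  if (length(missing)) {
    abort_usage(sprintf("Summary variable \"%s\" uses categories absent from the dictionary: %s.",
                        spec$name, paste(missing, collapse = ", ")))
  }
  pct <- setNames(profile$percentage, profile$category)
  raw <- spec$offset + sum(pct[spec$positive]) - sum(pct[spec$negative])
  min(100, max(0, raw))
}

#' Score sub-transcripts on the four summary variables
#'
#' Runs [tokenize()], [score_categories()] and [summary_variable()] on every
#' sub-transcript. Empty (zero-token) sub-transcripts get a flagged all-50
#' profile — 50 is the scale midpoint — and can be excluded downstream via
#' the `degenerate` column.
#'
#' @param subs Sub-transcript tibble from [split_by_role()] or [load_dyad()].
#' @param dictionary A [read_dic()] dictionary.
#' @param specs List of exactly four [summary_spec()]s named `analytic`,
#'   `clout`, `authentic`, `tone`; see [default_summary_specs()].
#' @return A profile tibble: `dyad_id`, `role`, `session`, the four summary
#'   variables, and `degenerate`.
#' @export
score_subtranscripts <- function(subs, dictionary,
                                 specs = default_summary_specs()) {
  if (!setequal(names(specs), sync_vars)) {
    abort_usage("`specs` must be four summary specs named analytic, clout, authentic, tone.")
  }
  purrr::map_dfr(seq_len(nrow(subs)), function(i) {
    prof <- score_categories(tokenize(subs$text[[i]]), dictionary)
    vals <- purrr::map_dbl(sync_vars, ~ summary_variable(prof, specs[[.x]]))
    tibble(
      dyad_id = subs$dyad_id[[i]], role = subs$role[[i]],
      session = subs$session[[i]],
      analytic = vals[[1]], clout = vals[[2]], authentic = vals[[3]],
      tone = vals[[4]],
      degenerate = attr(prof, "degenerate")
    )
  })
}
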