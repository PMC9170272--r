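#' Simulate a dyad's profile matrix with planted synchrony
#'
#' Generates the statistical structure the co-membership measure assumes:
#' each session is independently synchronized with probability
#' `planted_rate`. A synchronized session has a *single shared linguistic
#' profile* — one draw from an isotropic Gaussian around `sync_center` — used
#' for both the therapist and the client row (plus optional within-pair
#' jitter `pair_sd`; the default 0 is the perfect-synchrony limit). An
#' asynchronized session draws the therapist row around `therapist_center`
#' and the client row around `client_center`, independently.
#'
#' Default geometry: the therapist and client centers sit at
#' `+separation/2` and `-separation/2` noise-SD units on every variable, and
#' the synchronized-session center is equidistant from both. Values are in
#' arbitrary (standardized-like) units; the measurement pipeline z-scores
#' them anyway.
#'
#' @param n_sessions Number of sessions.
#' @param planted_rate Probability a session is synchronized, in \[0, 1\].
#' @param separation Per-variable gap between the therapist and client
#'   centers, in units of `noise_sd` (default 6).
#' @param noise_sd Isotropic Gaussian noise SD (> 0).
#' @param sync_center,therapist_center,client_center Optional 4-vectors
#'   overriding the default geometry; must be pairwise distinct.
#' @param pair_sd Within-pair jitter SD for synchronized sessions
#'   (default 0).
#' @param sigma Optional 4x4 noise covariance matrix (overrides
#'   `noise_sd`'s identity scaling; `noise_sd` still sets the default
#'   centers).
#' @param seed Integer seed; same seed, same output.
#' @param dyad_id Identifier stamped on the profiles.
#' @return List with `profiles` (assembled profile tibble) and `truth`
#'   (tibble of `session`, `synchronized`).
#' @examples
#' sim <- simulate_profiles(n_sessions = 10, planted_rate = 0.5, seed = 1)
#' mean(sim$truth$synchronized)
#' @export
simulate_profiles <- function(n_sessions = 50, planted_rate = 0.3,
                              separation = 6, noise_sd = 1,
                              sync_center = NULL, therapist_center = NULL,
                              client_center = NULL, pair_sd = 0,
                              sigma = NULL, seed = 1, dyad_id = "SIM") {
  if (planted_rate < 0 || planted_rate > 1) abort_usage("`planted_rate` must be in [0, 1].")
  if (noise_sd <= 0) abort_usage("`noise_sd` must be positive.")
  half <- separation / 2 * noise_sd
  therapist_center <- therapist_center %||% rep(half, 4)
  client_center <- client_center %||% rep(-half, 4)
  sync_center <- sync_center %||% c(half, -half, half, -half)
  centers <- list(sync_center, therapist_center, client_center)
  if (any(purrr::map_lgl(centers, ~ length(.x) != 4L))) {
    abort_usage("Centers must be 4-vectors (one value per summary variable).")
  }
  d <- stats::dist(do.call(rbind, centers))
  if (any(d == 0)) abort_usage("Centers must be pairwise distinct.")

  chol_sigma <- if (!is.null(sigma)) chol(sigma) else NULL
  noise <- function() {
    z <- rnorm(4)
    if (is.null(chol_sigma)) z * noise_sd else drop(z %*% chol_sigma)
  }

  withr::with_seed(seed, {
    flags <- runif(n_sessions) < planted_rate
    rows <- purrr::map_dfr(seq_len(n_sessions), function(i) {
      if (flags[i]) {
        shared <- sync_center + noise()
        t_row <- shared + rnorm(4, 0, pair_sd)
        c_row <- shared + rnorm(4, 0, pair_sd)
      } else {
        t_row <- therapist_center + noise()
        c_row <- client_center + noise()
      }
      tibble(
        dyad_id = dyad_id,
        role = c("client", "therapist"),
        session = i,
        analytic = c(c_row[1], t_row[1]), clout = c(c_row[2], t_row[2]),
        authentic = c(c_row[3], t_row[3]), tone = c(c_row[4], t_row[4])
      )
    })
    list(
      profiles = assemble_profiles(rows),
      truth = tibble(session = seq_len(n_sessions), synchronized = flags)
    )
  })
}

#' Simulate a token stream with planted category rates
#'
#' Draws `n_tokens` tokens i.i.d.: with probability `rates[c]` a uniformly
#' chosen literal word of category `c`, otherwise a filler word matching no
#' dictionary pattern. Scored category percentages converge to the planted
#' rates (binomial error).
#'
#' @param dictionary A [read_dic()] dictionary; every category named in
#'   `rates` must have at least one literal pattern.
#' @param rates Named numeric vector of per-category rates, sum at most 1.
#' @param n_tokens Number of tokens to draw.
#' @param seed Integer seed.
#' @return A single string of space-separated tokens.
#' @export
simulate_token_stream <- function(dictionary, rates, n_tokens, seed = 1) {
  stopifnot(inherits(dictionary, "liwc_dictionary"))
  if (is.null(names(rates)) || any(rates < 0) || sum(rates) > 1 + 1e-12) {
    abort_usage("`rates` must be a named vector of non-negative rates summing to at most 1.")
  }
  missing <- setdiff(names(rates), dictionary$categories$name)
  if (length(missing)) {
    abort_usage(sprintf("Categories absent from the dictionary: %s.", paste(missing, collapse = ", ")))
  }
  reps <- purrr::map(names(rates), function(cat) {
    id <- dictionary$categories$id[dictionary$categories$name == cat]
    words <- names(dictionary$literals)[purrr::map_lgl(dictionary$literals, ~ id %in% .x)]
    if (!length(words)) {
      abort_usage(sprintf("Category \"%s\" has no literal pattern to draw from.", cat))
    }
    words
  })
  # filler vocabulary that provably matches nothing in the dictionary
  filler_pool <- character(0)
  i <- 0L
  while (length(filler_pool) < 20L) {
    i <- i + 1L
    cand <- sprintf("zq%dx", i)
    if (length(match_token_ids(cand, dictionary)) == 0L) filler_pool <- c(filler_pool, cand)
    if (i > 1000L) abort_data("Could not construct filler words outside the dictionary.")
  }
  if (n_tokens == 0L) return("")
  withr::with_seed(seed, {
    choice <- sample.int(length(rates) + 1L, n_tokens, replace = TRUE,
                         prob = c(rates, 1 - sum(rates)))
    toks <- vapply(choice, function(ch) {
      pool <- if (ch <= length(rates)) reps[[ch]] else filler_pool
      pool[[sample.int(length(pool), 1L)]]
    }, character(1))
    paste(toks, collapse = " ")
  })
}
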