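# shared fixtures built in code

toy_dic <- function() read_dic(lingsync_example("toy.dic"))

# profile tibble for a dyad from client and therapist n_sessions x 4 matrices
make_profiles <- function(client, therapist, dyad_id = "X") {
  stopifnot(nrow(client) == nrow(therapist))
  n <- nrow(client)
  rows <- dplyr::bind_rows(
    tibble::tibble(dyad_id = dyad_id, role = "client", session = seq_len(n),
                   analytic = client[, 1], clout = client[, 2],
                   authentic = client[, 3], tone = client[, 4]),
    tibble::tibble(dyad_id = dyad_id, role = "therapist", session = seq_len(n),
                   analytic = therapist[, 1], clout = therapist[, 2],
                   authentic = therapist[, 3], tone = therapist[, 4])
  )
  assemble_profiles(rows)
}

# minimal hand-built clustering solution for synchrony unit tests
make_solution <- function(assignments, k = max(assignments)) {
  structure(
    list(k = as.integer(k), assignments = assignments,
         centers = NULL, distortion = NA_real_, sizes = tabulate(assignments, k),
         n_restarts = 1L, seed = 0L),
    class = "kmeans_solution"
  )
}

# random small clustering instance for oracle comparisons
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  p <- sample(2:4, 1)
  k <- sample(1:3, 1)
  centers <- matrix(rnorm(k * p, sd = 3), k, p)
  X <- centers[sample.int(k, n, replace = TRUE), , drop = FALSE] +
    matrix(rnorm(n * p), n, p)
  list(X = X, k = k)
}

# write a transcript to a temp file and return its path
write_transcript <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
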