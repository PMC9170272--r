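test_that("the toy .dic fixture parses to exactly its written content", {
  dict <- toy_dic()
  expect_s3_class(dict, "liwc_dictionary")
  expect_equal(nrow(dict$categories), 16L)
  expect_equal(dict$categories$name[dict$categories$id == 1], "article")
  # "i" belongs to both the pronoun and first-person-singular categories
  expect_setequal(dict$literals[["i"]], c(3L, 10L))
  expect_equal(sort(dict$wildcards$stem), c("happ", "run", "tentativ"))
})

test_that("wildcards are prefix matches of at least the stem length", {
  dict <- toy_dic()
  tent_id <- dict$categories$id[dict$categories$name == "tentative"]
  for (w in c("tentativ", "tentative", "tentatively")) {
    expect_true(tent_id %in% lingsync:::match_token_ids(w, dict), label = w)
  }
  expect_false(tent_id %in% lingsync:::match_token_ids("tentati", dict))
})

test_that("malformed dictionaries are rejected with line numbers", {
  bad <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tarticle", "%", "the\t1", "dog\t9"), bad)
  expect_error(read_dic(bad), "undeclared category id 9",
               class = "lingsync_data_error")

  dup <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tarticle", "2\tnoun", "%", "the\t1", "the\t2"), dup)
  expect_warning(d <- read_dic(dup), "last definition wins")
  expect_equal(d$literals[["the"]], 2L)

  nohdr <- withr::local_tempfile(fileext = ".dic")
  writeLines("the\t1", nohdr)
  expect_error(read_dic(nohdr), class = "lingsync_data_error")
})

test_that("tokenizer keeps contractions, drops punctuation, lowercases", {
  expect_equal(tokenize("It's so hard."), c("it's", "so", "hard"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("Like, yeah. That's the point."),
               c("like", "yeah", "that's", "the", "point"))
  # curly apostrophes normalize to the ASCII form
  expect_equal(tokenize("It’s fine"), c("it's", "fine"))
})

test_that("category percentages are direct token ratios", {
  dic_path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tarticle", "%", "the\t1"), dic_path)
  dict <- read_dic(dic_path)
  prof <- score_categories(c("the", "the", "dog"), dict)
  expect_equal(prof$percentage[prof$category == "article"], 100 * 2 / 3)
  expect_equal(attr(prof, "token_count"), 3L)

  # dictionary with declared categories but no entries scores everything zero
  empty_path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tarticle", "%"), empty_path)
  empty <- score_categories(c("the", "dog"), read_dic(empty_path))
  expect_true(all(empty$percentage == 0))
})

test_that("a token counts once per category but toward every category it matches", {
  dict <- toy_dic()
  prof <- score_categories(c("i"), dict)
  expect_equal(prof$percentage[prof$category == "pronoun"], 100)
  expect_equal(prof$percentage[prof$category == "i"], 100)
})

test_that("summary variables compose signed category percentages with clamping", {
  dic_path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tpos", "2\tneg", "%", "up\t1", "down\t2"), dic_path)
  dict <- read_dic(dic_path)
  spec <- summary_spec("v", positive = "pos", negative = "neg")

  balanced <- score_categories(c(rep("up", 1), rep("down", 1), rep("x", 8)), dict)
  expect_equal(summary_variable(balanced, spec), 50)  # 50 + 10 - 10

  top <- score_categories(c(rep("up", 8), rep("down", 1), rep("x", 1)), dict)
  expect_equal(summary_variable(top, spec), 100)      # 50 + 80 - 10 -> clamp

  bottom <- score_categories(rep("down", 10), dict)
  expect_equal(summary_variable(bottom, spec), 0)     # 50 + 0 - 100 -> clamp

  expect_error(summary_variable(balanced, summary_spec("v", positive = "missing")),
               "missing", class = "lingsync_usage_error")
  expect_error(summary_spec("v"), class = "lingsync_usage_error")
  expect_error(summary_spec("v", positive = "a", negative = "a"),
               class = "lingsync_usage_error")
})

test_that("a hand-computed composition matches score_subtranscripts", {
  dict <- toy_dic()
  subs <- tibble::tibble(dyad_id = "D", role = "client", session = 1L,
                         token_count = 6L,
                         text = "the cat went to the house")
  prof <- score_subtranscripts(subs, dict)
  # 6 tokens: "the" x2 (article), "to" (preposition), "went" (motion)
  expect_equal(prof$analytic, 100)                    # 50 + 100*(2+1)/6 = 100, at clamp
  expect_equal(prof$authentic, 50 - 100 * 1 / 6)      # motion is negative
  expect_equal(prof$clout, 50)
  expect_equal(prof$tone, 50)
  expect_false(prof$degenerate)
})

test_that("duplicating a text changes no percentage or summary variable", {
  dict <- toy_dic()
  text <- "I was so afraid but we went to the house and it was good"
  once <- score_categories(tokenize(text), dict)
  twice <- score_categories(tokenize(paste(text, text)), dict)
  expect_equal(once$percentage, twice$percentage)

  subs <- tibble::tibble(dyad_id = "D", role = "client", session = 1:2,
                         token_count = NA_integer_,
                         text = c(text, paste(text, text)))
  prof <- score_subtranscripts(subs, dict)
  expect_equal(unlist(prof[1, c("analytic", "clout", "authentic", "tone")]),
               unlist(prof[2, c("analytic", "clout", "authentic", "tone")]))
})

test_that("adding a positive-category token weakly increases the variable", {
  dict <- toy_dic()
  specs <- default_summary_specs()
  base_tokens <- c("cat", "house", "dog", "tree")  # nothing scored
  for (extra in c("the", "of")) {                  # analytic positives only
    v0 <- summary_variable(score_categories(base_tokens, dict), specs$analytic)
    v1 <- summary_variable(score_categories(c(base_tokens, extra), dict), specs$analytic)
    expect_gte(v1, v0)
  }
})

test_that("empty sub-transcripts get the flagged midpoint profile", {
  dict <- toy_dic()
  subs <- tibble::tibble(dyad_id = "D", role = "client", session = 1L,
                         token_count = 0L, text = "")
  prof <- score_subtranscripts(subs, dict)
  expect_true(prof$degenerate)
  expect_equal(unlist(prof[, c("analytic", "clout", "authentic", "tone")]),
               c(analytic = 50, clout = 50, authentic = 50, tone = 50))
})

test_that("identical input text yields identical profiles", {
  dict <- toy_dic()
  subs <- tibble::tibble(dyad_id = "D", role = "client", session = 1:2,
                         token_count = NA_integer_,
                         text = rep("we went to the house and i was happy", 2))
  prof <- score_subtranscripts(subs, dict)
  expect_equal(prof[1, sync_cols <- c("analytic", "clout", "authentic", "tone")],
               prof[2, sync_cols], ignore_attr = TRUE)
})
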