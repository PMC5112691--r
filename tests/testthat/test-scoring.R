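test_that("intermediate score follows the received-answer formula", {
  expect_equal(intermediate_score(c("yes", "yes", "yes")),
               list(value = 100, n_received = 3L, n_scorers = 3L))
  expect_equal(intermediate_score(c("yes", "unsure", "unaware")),
               list(value = 75, n_received = 2L, n_scorers = 3L))
  all_blank <- intermediate_score(c("unaware", "unaware"))
  expect_true(is.na(all_blank$value))
  expect_identical(all_blank$n_received, 0L)
  expect_error(intermediate_score(character()), "non-empty")
})

test_that("value times n_received recovers the raw sum of answers", {
  set.seed(21)
  for (i in 1:50) {
    codes <- sample(response_codes(), sample(1:12, 1), replace = TRUE)
    got <- intermediate_score(codes)
    raw_sum <- sum(response_value(codes), na.rm = TRUE)
    if (got$n_received > 0) {
      expect_equal(got$value * got$n_received / 100, raw_sum)
      expect_gte(got$value, 0)
      expect_lte(got$value, 100)
    }
  }
})

test_that("priority score is the mean over defined criteria", {
  expect_equal(priority_score(rep(100, 5))$value, 100)
  expect_equal(priority_score(c(80, 60, 70, 90, 100))$value, 80)
  partial <- priority_score(c(90, NA))
  expect_equal(partial$value, 90)
  expect_identical(partial$n_criteria_used, 1L)
  expect_error(priority_score(c(NA_real_, NA_real_)), "undefined")
  expect_error(priority_score(numeric()), "non-empty")
})

test_that("dominant suggestion ranks first and singleton ranks 1", {
  arr <- array("no", dim = c(3, 2, 5))
  arr[, 1, ] <- "yes"
  rt <- rank_table(matrix_from_array(arr), test_criteria(5))
  expect_identical(rt$suggestion_id, c("sug1", "sug2"))
  expect_identical(rt$rank, 1:2)
  expect_equal(rt$priority_score, c(100, 0))

  single <- matrix_from_array(array("unsure", dim = c(3, 1, 5)))
  rt1 <- rank_table(single, test_criteria(5))
  expect_identical(rt1$rank, 1L)
  expect_equal(rt1$priority_score, 50)
})

test_that("ties break by AEA then catalogue order, with consecutive ranks", {
  # sug1 and sug2 share priority 75 but sug2 is more consensual:
  # 2 yes / 2 unsure (mode 0.5) vs 3 yes / 1 no (mode 0.75)
  arr <- array("yes", dim = c(4, 3, 2))
  arr[3, 1, ] <- "unsure"; arr[4, 1, ] <- "unsure"
  arr[4, 2, ] <- "no"
  arr[, 3, ] <- "no"
  stopifnot(identical(oracle_suggestion(arr[, 1, ])$priority,
                      oracle_suggestion(arr[, 2, ])$priority))
  rt <- rank_table(matrix_from_array(arr), test_criteria(2))
  expect_identical(rt$rank, 1:3)
  expect_equal(rt$priority_score[1], rt$priority_score[2])
  expect_gte(rt$aea[1], rt$aea[2])
  expect_identical(rt$suggestion_id[1], "sug2")

  # exact tie in both keys: catalogue (here: matrix) order wins
  arr2 <- array("yes", dim = c(2, 2, 2))
  rt2 <- rank_table(matrix_from_array(arr2), test_criteria(2))
  expect_identical(rt2$suggestion_id, c("sug1", "sug2"))
})

test_that("suggestions with no received answers are excluded or abort", {
  arr <- array("yes", dim = c(2, 2, 2))
  arr[, 2, ] <- "unaware"
  m <- matrix_from_array(arr)
  expect_warning(rt <- rank_table(m, test_criteria(2)), "sug2")
  expect_identical(rt$suggestion_id, "sug1")
  expect_error(rank_table(m, test_criteria(2), strict = TRUE), "sug2")
})

test_that("a partially unaware criterion still contributes its mean", {
  arr <- array("yes", dim = c(2, 1, 2))
  arr[, 1, 2] <- "unaware"
  rt <- rank_table(matrix_from_array(arr), test_criteria(2))
  expect_equal(rt$priority_score, 100)
  expect_identical(rt$n_criteria_used, 1L)
})

test_that("scores are invariant under scorer and suggestion permutation", {
  set.seed(31)
  for (i in 1:20) {
    m <- random_matrix(4, 3, 2)
    cs <- test_criteria(2)
    base <- rank_table(m, cs)
    perm <- m
    perm$cells <- perm$cells[sample(nrow(perm$cells)), ]
    expect_equal(rank_table(perm, cs), base)
    relab <- m
    swap <- c(sug1 = "sug2", sug2 = "sug1", sug3 = "sug3")
    relab$cells$suggestion_id <- unname(swap[relab$cells$suggestion_id])
    relab$suggestions <- unname(swap[relab$suggestions])
    out <- rank_table(relab, cs)
    m1 <- base[order(base$suggestion_id), c("priority_score", "aea")]
    m2 <- out[order(unname(swap[out$suggestion_id])), c("priority_score", "aea")]
    expect_equal(unname(as.matrix(m2)), unname(as.matrix(m1)))
  }
})

test_that("appending an unaware scorer leaves all scores unchanged", {
  set.seed(41)
  for (i in 1:20) {
    m <- random_matrix(3, 2, 2)
    cs <- test_criteria(2)
    base <- rank_table(m, cs)
    extra <- expand.grid(scorer_id = "sc_extra",
                         suggestion_id = m$suggestions,
                         criterion_id = m$criteria,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    extra$response <- "unaware"
    grown <- response_matrix(rbind(m$cells, extra), m$kind,
                             scorers = c(m$scorers, "sc_extra"),
                             suggestions = m$suggestions,
                             criteria = m$criteria)
    out <- rank_table(grown, cs)
    expect_equal(out$priority_score, base$priority_score)
    for (cid in m$criteria) expect_equal(out[[cid]], base[[cid]])
  }
})

test_that("upgrading one response never decreases the affected scores", {
  set.seed(51)
  upgrade <- c(no = "unsure", unsure = "yes")
  for (i in 1:30) {
    m <- random_matrix(4, 2, 2)
    cs <- test_criteria(2)
    candidates <- which(m$cells$response %in% names(upgrade))
    if (!length(candidates)) next
    j <- candidates[sample(length(candidates), 1)]
    before <- intermediate_scores(m, cs)
    pre_rank <- suppressWarnings(rank_table(m, cs))
    m$cells$response[j] <- unname(upgrade[m$cells$response[j]])
    after <- intermediate_scores(m, cs)
    post_rank <- suppressWarnings(rank_table(m, cs))
    touched <- before$suggestion_id == m$cells$suggestion_id[j] &
      before$criterion_id == m$cells$criterion_id[j]
    expect_gte(after$value[touched], before$value[touched])
    sid <- m$cells$suggestion_id[j]
    expect_gte(post_rank$priority_score[post_rank$suggestion_id == sid],
               pre_rank$priority_score[pre_rank$suggestion_id == sid])
  }
})

test_that("degenerate matrices hit the exact scale bounds", {
  cs <- test_criteria(3)
  for (code in c("yes", "no", "unsure")) {
    m <- matrix_from_array(array(code, dim = c(5, 2, 3)))
    rt <- rank_table(m, cs)
    expect_equal(rt$priority_score,
                 rep(c(yes = 100, no = 0, unsure = 50)[[code]], 2))
    expect_equal(rt$aea, c(1, 1))
  }
})

test_that("pipeline matches the brute-force oracle on random small matrices", {
  set.seed(61)
  for (i in 1:25) {
    dims <- c(sample(2:4, 1), sample(1:3, 1), sample(1:3, 1))
    codes <- sample(response_codes(), prod(dims), replace = TRUE,
                    prob = c(0.35, 0.25, 0.2, 0.2))
    arr <- array(codes, dim = dims)
    m <- matrix_from_array(arr)
    cs <- test_criteria(dims[3])
    rt <- suppressWarnings(rank_table(m, cs))
    for (s in seq_len(dims[2])) {
      want <- oracle_suggestion(matrix(arr[, s, ], nrow = dims[1]))
      sid <- paste0("sug", s)
      row <- rt[rt$suggestion_id == sid, ]
      if (is.na(want$priority)) {
        expect_identical(nrow(row), 0L)
      } else {
        expect_equal(row$priority_score, want$priority)
        expect_equal(row$aea, want$aea)
        got_ints <- as.numeric(row[, cs$criteria$id])
        expect_equal(got_ints, want$intermediates)
      }
    }
  }
})
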