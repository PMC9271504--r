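hads_row <- function(items) {
  stats::setNames(as.data.frame(as.list(items)), paste0("item_a", 1:7))
}

test_that("HADS-A scoring sums items and flags at the >= 8 cutoff", {
  expect_identical(hads_a_score(hads_row(rep(0, 7)))$hads_a, 0L)
  expect_false(hads_a_score(hads_row(rep(0, 7)))$anxiety_flag)
  s21 <- hads_a_score(hads_row(rep(3, 7)))
  expect_identical(s21$hads_a, 21L)
  expect_true(s21$anxiety_flag)
  # boundary: 7 no flag, 8 flags
  s7 <- hads_a_score(hads_row(rep(1, 7)))
  expect_identical(s7$hads_a, 7L)
  expect_false(s7$anxiety_flag)
  s8 <- hads_a_score(hads_row(c(2, rep(1, 6))))
  expect_identical(s8$hads_a, 8L)
  expect_true(s8$anxiety_flag)
})

test_that("HADS-A handles missing and invalid items without imputation", {
  r <- hads_row(c(NA, rep(1, 6)))
  out <- hads_a_score(r)
  expect_true(is.na(out$hads_a))
  expect_true(is.na(out$anxiety_flag))
  expect_error(hads_a_score(hads_row(c(4, rep(1, 6)))),
               class = "sharedcare_invalid_response")
  expect_error(hads_a_score(hads_row(rep(1, 7))[, -3]),
               class = "sharedcare_schema")
})

test_that("HADS-A score is invariant to item order and stays in [0, 21]", {
  set.seed(8)
  for (i in 1:10) {
    items <- sample(0:3, 7, replace = TRUE)
    s1 <- hads_a_score(hads_row(items))$hads_a
    s2 <- hads_a_score(hads_row(sample(items)))$hads_a
    expect_identical(s1, s2)
    expect_gte(s1, 0L)
    expect_lte(s1, 21L)
  }
})

rand_row <- function(values) {
  stats::setNames(as.data.frame(as.list(values)), sprintf("item_%02d", 1:36))
}

rand36_best <- function() {
  vapply(sharedcare:::rand36_recode_key, which.max, integer(1))
}
rand36_worst <- function() {
  vapply(sharedcare:::rand36_recode_key, which.min, integer(1))
}

test_that("RAND-36 extremes score 100 and 0 on every subscale", {
  best <- rand36_subscales(rand_row(rand36_best()))
  worst <- rand36_subscales(rand_row(rand36_worst()))
  sub <- names(sharedcare:::rand36_subscale_items)
  expect_true(all(as.numeric(best[1, sub]) == 100))
  expect_true(all(as.numeric(worst[1, sub]) == 0))
})

test_that("half best, half worst within a subscale scores 50", {
  items <- rand36_best()
  pf <- sharedcare:::rand36_subscale_items$physical_functioning
  items[pf[1:5]] <- rand36_worst()[pf[1:5]]
  out <- rand36_subscales(rand_row(items))
  expect_equal(out$physical_functioning, 50)
})

test_that("RAND-36 subscales stay in [0, 100] and average non-missing items", {
  set.seed(9)
  key <- sharedcare:::rand36_recode_key
  for (i in 1:10) {
    items <- vapply(key, function(k) sample(seq_along(k), 1), integer(1))
    out <- rand36_subscales(rand_row(items))
    vals <- as.numeric(out[1, names(sharedcare:::rand36_subscale_items)])
    expect_true(all(vals >= 0 & vals <= 100))
  }
  # one missing pain item: subscale is the other item's recoded value
  items <- rand36_best()
  items[21] <- NA
  out <- rand36_subscales(rand_row(items))
  expect_equal(out$pain, 100)
  # all pain items missing: undefined
  items[22] <- NA
  expect_true(is.na(rand36_subscales(rand_row(items))$pain))
  # out-of-range raw category is rejected
  bad <- rand36_best(); bad[3] <- 4
  expect_error(rand36_subscales(rand_row(bad)),
               class = "sharedcare_invalid_response")
})

test_that("longitudinal comparison pairs patients and reports the shift", {
  b <- data.frame(patient_id = 1:20, hads_a = rep(2:6, 4))
  # identical administrations: zero difference carries no evidence of change
  same <- longitudinal_compare(b, b)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  # a constant +1 shift moves the mean by exactly 1
  f <- b; f$hads_a <- f$hads_a + 1
  shift <- longitudinal_compare(b, f)
  expect_equal(shift$mean_after - shift$mean_before, 1)
  expect_equal(shift$mean_diff, 1)
  expect_lt(shift$p_value, 0.05)
  # the signed-rank alternative runs on the same pairs
  w <- longitudinal_compare(b, f, method = "wilcoxon")
  expect_identical(w$method, "wilcoxon")
  expect_lt(w$p_value, 0.05)
  # fewer than two pairs is undefined
  expect_warning(u <- longitudinal_compare(b[1, ], b[1, ]), "pairs")
  expect_true(is.na(u$p_value))
})
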