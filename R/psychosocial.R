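#' Score the HADS anxiety subscale
#'
#' Sums the seven anxiety items (each 0-3) to a 0-21 score and flags
#' clinically relevant anxiety at the instrument's conventional cutoff of 8
#' points or more. Responses with a missing item get an undefined score (`NA`,
#' no imputation) and are excluded from prevalence denominators.
#'
#' @param responses Data frame with columns `item_a1` ... `item_a7` (integers
#'   0-3, `NA` allowed) and optionally `patient_id`, `administration_label`.
#' @param cutoff Anxiety flag threshold (default 8).
#' @return The input tibble with `hads_a` (integer) and `anxiety_flag`
#'   (logical) appended.
#' @examples
#' hads_a_score(data.frame(item_a1 = 1, item_a2 = 1, item_a3 = 1,
#'                         item_a4 = 1, item_a5 = 1, item_a6 = 1, item_a7 = 2))
#' @export
hads_a_score <- function(responses, cutoff = 8) {
  items <- paste0("item_a", 1:7)
  miss <- setdiff(items, names(responses))
  if (length(miss)) {
    abort_sc(sprintf("missing HADS-A item column(s): %s",
                     paste(miss, collapse = ", ")), "schema")
  }
  m <- as.matrix(responses[items])
  if (any(!is.na(m) & (m < 0 | m > 3 | m != floor(m)))) {
    abort_sc("HADS-A items must be integers in 0..3.", "invalid_response")
  }
  out <- tibble::as_tibble(responses)
  out$hads_a <- as.integer(rowSums(m))       # NA when any item missing
  out$anxiety_flag <- out$hads_a >= cutoff
  out
}

# RAND 36-item Health Survey 1.0 recoding key: raw category -> 0..100
rand36_recode_key <- local({
  key <- vector("list", 36)
  set <- function(items, values) for (i in items) key[[i]] <<- values
  set(c(1, 2, 20, 22, 34, 36), c(100, 75, 50, 25, 0))
  set(3:12, c(0, 50, 100))
  set(13:19, c(0, 100))
  set(c(21, 23, 26, 27, 30), c(100, 80, 60, 40, 20, 0))
  set(c(24, 25, 28, 29, 31), c(0, 20, 40, 60, 80, 100))
  set(c(32, 33, 35), c(0, 25, 50, 75, 100))
  key
})

rand36_subscale_items <- list(
  physical_functioning = 3:12,
  role_physical = 13:16,
  role_emotional = 17:19,
  vitality = c(23, 27, 29, 31),
  emotional_wellbeing = c(24, 25, 26, 28, 30),
  social_functioning = c(20, 32),
  pain = c(21, 22),
  general_health = c(1, 33, 34, 35, 36)
)

#' Score the RAND-36 health survey into its eight subscales
#'
#' Published two-step RAND scoring: each item is recoded to 0-100 according
#' to the RAND key (higher = better health), then each subscale is the mean
#' of its non-missing recoded items. A subscale with all items missing is
#' undefined (`NA`).
#'
#' @param responses Data frame with columns `item_01` ... `item_36` on the
#'   published raw categorical scales, plus optional identifier columns.
#' @return A tibble with the identifier columns (if present) and the eight
#'   subscale scores in `[0, 100]`: `physical_functioning`, `role_physical`,
#'   `role_emotional`, `vitality`, `emotional_wellbeing`,
#'   `social_functioning`, `pain`, `general_health`.
#' @export
rand36_subscales <- function(responses) {
  items <- sprintf("item_%02d", 1:36)
  miss <- setdiff(items, names(responses))
  if (length(miss)) {
    abort_sc(sprintf("missing RAND-36 item column(s): %s",
                     paste(miss, collapse = ", ")), "schema")
  }
  raw <- as.matrix(responses[items])
  recoded <- matrix(NA_real_, nrow(raw), 36)
  for (j in 1:36) {
    k <- rand36_recode_key[[j]]
    x <- raw[, j]
    bad <- !is.na(x) & (x < 1 | x > length(k) | x != floor(x))
    if (any(bad)) {
      abort_sc(sprintf("item_%02d has values outside its published 1..%d range.",
                       j, length(k)), "invalid_response")
    }
    recoded[, j] <- k[x]
  }
  id_cols <- intersect(c("patient_id", "administration_label"), names(responses))
  out <- tibble::as_tibble(responses[id_cols])
  for (nm in names(rand36_subscale_items)) {
    out[[nm]] <- rowMeans(recoded[, rand36_subscale_items[[nm]], drop = FALSE],
                          na.rm = TRUE)
    out[[nm]][is.nan(out[[nm]])] <- NA_real_
  }
  out
}

#' Compare questionnaire scores between two administrations
#'
#' Pairs baseline and follow-up scores by patient and tests the per-patient
#' differences: a paired two-sided t-test by default, or a Wilcoxon
#' signed-rank test. When every paired difference is zero the comparison
#' carries no evidence of change and the p-value is reported as 1 (documented
#' convention; the t statistic is undefined there). Fewer than two pairs give
#' an undefined comparison.
#'
#' @param baseline,followup Data frames with `patient_id` and a score column.
#' @param score Name of the score column (default `"hads_a"`).
#' @param method `"t"` (paired t-test) or `"wilcoxon"` (signed-rank).
#' @return A one-row tibble: `mean_before`, `mean_after`, `mean_diff`,
#'   `n_pairs`, `p_value`, `method`.
#' @examples
#' b <- data.frame(patient_id = 1:5, hads_a = c(2, 4, 3, 5, 1))
#' f <- data.frame(patient_id = 1:5, hads_a = c(3, 5, 4, 6, 2))
#' longitudinal_compare(b, f)
#' @export
longitudinal_compare <- function(baseline, followup, score = "hads_a",
                                 method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  paired <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(baseline), "patient_id",
                  before = dplyr::all_of(score)),
    dplyr::select(tibble::as_tibble(followup), "patient_id",
                  after = dplyr::all_of(score)),
    by = "patient_id"
  ) |>
    dplyr::filter(!is.na(.data$before), !is.na(.data$after))
  n <- nrow(paired)
  if (n < 2) {
    rlang::warn("fewer than two complete pairs; comparison undefined.")
    return(tibble::tibble(mean_before = NA_real_, mean_after = NA_real_,
                          mean_diff = NA_real_, n_pairs = n,
                          p_value = NA_real_, method = method))
  }
  d <- paired$after - paired$before
  p <- if (all(d == 0)) {
    1
  } else if (stats::sd(d) == 0) {
    # an exactly constant nonzero shift: the paired t statistic degenerates;
    # report certainty of change
    0
  } else if (method == "t") {
    stats::t.test(paired$after, paired$before, paired = TRUE)$p.value
  } else {
    stats::wilcox.test(paired$after, paired$before, paired = TRUE,
                       exact = FALSE)$p.value
  }
  tibble::tibble(mean_before = mean(paired$before),
                 mean_after = mean(paired$after),
                 mean_diff = mean(d),
                 n_pairs = n,
                 p_value = p,
                 method = method)
}
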