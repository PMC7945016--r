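# Subsequent-memory classification of old-item test trials and the
# guess-corrected source memory index.
#
# The memory test branches: Q1 "have you seen this item?" (yes/no); only
# after a Yes, Q2 "do you remember what you were supposed to do with it?"
# (yes/no); only after a Yes, Q3 a two-alternative choice of the encoded
# action (correct/incorrect). Outcomes:
#   source           q1=yes, q2=yes, q3=correct
#   incorrect_source q1=yes, q2=yes, q3=incorrect (an item-condition trial,
#                    tracked separately for the guessing correction)
#   item             q1=yes and (q2=no, or no response at Q2/Q3)
#   miss             q1=no
#   no_response      no response at Q1
# Because Q3 is a two-alternative choice, correct source responses occur at
# chance 0.5 given yes/yes; the corrected index
# (n_source - n_incorrect_source) / n_old removes that guessing component.

TRIAL_CATEGORIES <- c("source", "item", "incorrect_source", "miss",
                      "no_response")

#' Classify old-item memory-test trials
#'
#' Vectorized deterministic mapping from the (Q1, Q2, Q3) response triple of
#' each old-item test trial to its subsequent-memory outcome. Responses must
#' respect the branching design: Q2 may only be answered after a Yes to Q1,
#' and Q3 only after a Yes to Q2; violations are an error. A missing (`NA`)
#' response at Q1 is `no_response`; a missing response after a Yes to Q1 is
#' classified as `item` (the item was recognized, the association was not
#' retrieved).
#'
#' @param q1,q2 `"yes"`, `"no"` or `NA`.
#' @param q3 `"correct"`, `"incorrect"` or `NA`.
#' @param is_old logical; only old-item trials are classifiable.
#' @return factor with levels `source`, `item`, `incorrect_source`, `miss`,
#'   `no_response`.
#' @examples
#' classify_trials("yes", "yes", "correct")   # source
#' classify_trials("yes", "yes", "incorrect") # incorrect_source
#' classify_trials("no", NA, NA)              # miss
#' @export
classify_trials <- function(q1, q2, q3, is_old = TRUE) {
  n <- max(length(q1), length(q2), length(q3))
  q1 <- rep_len(as.character(q1), n)
  q2 <- rep_len(as.character(q2), n)
  q3 <- rep_len(as.character(q3), n)
  is_old <- rep_len(is_old, n)
  if (any(!is_old)) stop_invalid("only old-item trials can be classified")
  bad_val <- function(x, ok) !is.na(x) & !x %in% ok
  if (any(bad_val(q1, c("yes", "no"))) || any(bad_val(q2, c("yes", "no"))) ||
      any(bad_val(q3, c("correct", "incorrect"))))
    stop_invalid("responses must be yes/no (Q1, Q2), correct/incorrect (Q3), or NA")
  q1y <- !is.na(q1) & q1 == "yes"
  q2y <- !is.na(q2) & q2 == "yes"
  if (any(!is.na(q2) & !q1y))
    stop_invalid("Q2 answered without a Yes response to Q1")
  if (any(!is.na(q3) & !q2y))
    stop_invalid("Q3 answered without a Yes response to Q2")
  out <- rep("item", n)
  out[is.na(q1)] <- "no_response"
  out[!is.na(q1) & q1 == "no"] <- "miss"
  out[q2y & !is.na(q3) & q3 == "correct"] <- "source"
  out[q2y & !is.na(q3) & q3 == "incorrect"] <- "incorrect_source"
  factor(out, levels = TRIAL_CATEGORIES)
}

#' Score subjects on the corrected source-memory index
#'
#' Counts trial outcomes per subject and computes the guess-corrected source
#' memory performance index `(n_source - n_incorrect_source) / n_old`,
#' a proportion in `[-1, 1]` that is 0 in expectation when the Q3 action
#' choice is at its 0.5 chance level.
#'
#' @param trials data.frame with columns `subject_id`, `q1`, `q2`, `q3` and
#'   optionally `is_old` (old trials only are scored; defaults to all old).
#' @return data.frame, one row per subject: outcome counts `n_source`,
#'   `n_item`, `n_incorrect_source`, `n_miss`, `n_no_response`, `n_old`,
#'   and `corrected_index`.
#' @examples
#' tr <- data.frame(subject_id = "s1",
#'                  q1 = c("yes", "yes", "no"),
#'                  q2 = c("yes", "yes", NA),
#'                  q3 = c("correct", "incorrect", NA))
#' score_subjects(tr)
#' @export
score_subjects <- function(trials) {
  stopifnot(all(c("subject_id", "q1", "q2", "q3") %in% names(trials)))
  if ("is_old" %in% names(trials)) trials <- trials[trials$is_old, ]
  if (!nrow(trials)) stop_invalid("at least one old trial is required")
  cat_ <- classify_trials(trials$q1, trials$q2, trials$q3)
  tab <- table(subject_id = trials$subject_id, category = cat_)
  out <- data.frame(subject_id = rownames(tab),
                    n_source = as.integer(tab[, "source"]),
                    n_item = as.integer(tab[, "item"]),
                    n_incorrect_source = as.integer(tab[, "incorrect_source"]),
                    n_miss = as.integer(tab[, "miss"]),
                    n_no_response = as.integer(tab[, "no_response"]),
                    stringsAsFactors = FALSE)
  out$n_old <- rowSums(tab)
  if (any(out$n_old < 1)) stop_invalid("every subject needs >= 1 old trial")
  out$corrected_index <- (out$n_source - out$n_incorrect_source) / out$n_old
  rownames(out) <- NULL
  out
}

#' Exclude subjects with too few trials in a condition of interest
#'
#' Subjects with fewer than `min_trials` trials in either fMRI condition of
#' interest -- source, or item (which for condition modelling includes
#' incorrect-source trials) -- are excluded, mirroring the usual
#' "< 6 trials per condition" retention rule for subsequent-memory designs.
#'
#' @param scores output of [score_subjects()].
#' @param min_trials minimum per-condition trial count (>= 0; 0 keeps all).
#' @return list with `kept` and `excluded` subject-id vectors and `log`,
#'   a data.frame recording each subject's condition counts and status.
#' @export
exclude_low_trial_subjects <- function(scores, min_trials = 6) {
  check_count(min_trials, "min_trials", min = 0)
  n_item_cond <- scores$n_item + scores$n_incorrect_source
  keep <- scores$n_source >= min_trials & n_item_cond >= min_trials
  log <- data.frame(subject_id = scores$subject_id,
                    n_source = scores$n_source,
                    n_item_condition = n_item_cond,
                    kept = keep,
                    stringsAsFactors = FALSE)
  list(kept = scores$subject_id[keep],
       excluded = scores$subject_id[!keep],
       log = log)
}
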