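#' Tally visual-grading scores per case
#'
#' For each case and question, counts the readers whose score is at least 3
#' (the "diagnostically sufficient" half of the 5-point scale); the per-case
#' `vg_sum` is the sum of these counts over the questions. Missing
#' (case, reader, question) readings are tolerated: the count runs over the
#' available readers and the case is flagged as incomplete.
#'
#' @param scores a `reader_scores` data frame (columns `case_id`,
#'   `reader_id`, `question`, `score`), e.g. from
#'   [simulate_reader_scores()].
#' @param threshold minimum score counted as favourable (default 3).
#' @return A data frame with one row per case: `case_id`, one column per
#'   question (lower-cased label, e.g. `q1`), `vg_sum`, `n_readers`, and
#'   `complete` (`FALSE` where any question was rated by fewer readers than
#'   the study maximum).
#' @export
tally_scores <- function(scores, threshold = 3) {
  stopifnot(is.data.frame(scores),
            all(c("case_id", "reader_id", "question", "score") %in%
                  names(scores)))
  if (nrow(scores) == 0L) stop("no scores to tally")
  if (any(!scores$score %in% 1:5))
    stop("scores must be integers 1-5")
  dup <- duplicated(scores[c("case_id", "reader_id", "question")])
  if (any(dup))
    stop("duplicate (case, reader, question) entries in score table")

  questions <- sort(unique(scores$question))
  cases <- sort(unique(scores$case_id))
  n_readers <- length(unique(scores$reader_id))

  hit <- scores$score >= threshold
  counts <- table(
    factor(scores$case_id, levels = cases),
    factor(scores$question, levels = questions)
  )
  hits <- table(
    factor(scores$case_id[hit], levels = cases),
    factor(scores$question[hit], levels = questions)
  )
  out <- data.frame(case_id = cases)
  for (j in seq_along(questions))
    out[[tolower(questions[j])]] <- as.integer(hits[, j])
  out$vg_sum <- as.integer(rowSums(hits))
  out$n_readers <- n_readers
  out$complete <- apply(counts, 1, function(r) all(r == n_readers))
  out
}

#' Case-by-reader score matrix for one question
#'
#' @param scores a `reader_scores` data frame.
#' @param question question label to extract.
#' @return Numeric matrix, rows = cases, columns = readers; `NA` where a
#'   reading is missing.
#' @export
score_matrix <- function(scores, question) {
  sub <- scores[scores$question == question, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no scores for question ", question)
  cases <- sort(unique(sub$case_id))
  readers <- sort(unique(sub$reader_id))
  m <- matrix(NA_real_, length(cases), length(readers),
              dimnames = list(as.character(cases), readers))
  m[cbind(match(sub$case_id, cases), match(sub$reader_id, readers))] <- sub$score
  m
}
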