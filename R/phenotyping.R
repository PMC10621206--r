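# Symptom-change scores and quartile/median case-control cohort construction.

#' Per-sample symptom change scores
#'
#' For each sample, the sum over the selected symptoms of
#' `post - pre`; scales are oriented so that higher = worse, hence larger
#' positive scores mean greater deterioration. The `"total"` subset uses
#' every symptom in the group map; `"fatigue"` uses only symptoms whose group
#' is `"fatigue"`. Samples missing any pre/post value for a symptom in the
#' subset are flagged incomplete and excluded from scoring (with a message),
#' never silently zeroed.
#'
#' @param phenotypes data.frame with `sample_id` and `<symptom>_pre` /
#'   `<symptom>_post` columns.
#' @param symptom_groups named character vector mapping symptom name to group
#'   label (`respiratory`, `fatigue`, `mental_health`, ...).
#' @param subset `"total"` or `"fatigue"`.
#' @return data.frame with `sample_id`, `score`, `complete`.
#' @export
change_scores <- function(phenotypes, symptom_groups,
                          subset = c("total", "fatigue")) {
  subset <- match.arg(subset)
  symptoms <- names(symptom_groups)
  if (subset == "fatigue") symptoms <- symptoms[symptom_groups == "fatigue"]
  if (length(symptoms) == 0L) stop("no symptoms selected for subset ", subset)
  pre_cols <- paste0(symptoms, "_pre")
  post_cols <- paste0(symptoms, "_post")
  missing_cols <- setdiff(c(pre_cols, post_cols), names(phenotypes))
  if (length(missing_cols)) {
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  pre <- as.matrix(phenotypes[, pre_cols, drop = FALSE])
  post <- as.matrix(phenotypes[, post_cols, drop = FALSE])
  complete <- rowSums(is.na(pre)) == 0 & rowSums(is.na(post)) == 0
  score <- rowSums(post - pre)
  score[!complete] <- NA_real_
  if (any(!complete)) {
    message(sprintf("change_scores: %d sample(s) incomplete for subset '%s', excluded",
                    sum(!complete), subset))
  }
  data.frame(sample_id = as.character(phenotypes$sample_id),
             score = score, complete = complete)
}

#' Assign case/control cohort labels from change scores
#'
#' Cases are samples whose score is greater than or equal to the upper
#' quartile of the score distribution; controls have a score greater than or
#' equal to 0 but below the median. All other scored samples (including
#' negative scores, i.e. net improvement) are excluded. Quartiles use linear
#' interpolation between order statistics (R's default type-7 rule),
#' computed over all complete samples.
#'
#' @param scores output of [change_scores()] (or any data.frame with
#'   `sample_id`, `score`).
#' @param mode label recorded in the output: `"severe"` (total-change
#'   scores) or `"fatigue"` (fatigue-change scores).
#' @return a `cohort_assignment`: data.frame with `sample_id`, `label`
#'   (`case` / `control` / `excluded`) and attributes `thresholds`
#'   (`q3`, `median`) and `mode`.
#' @export
assign_cohort <- function(scores, mode = c("severe", "fatigue")) {
  mode <- match.arg(mode)
  s <- scores$score[!is.na(scores$score)]
  if (length(s) < 4) stop("need at least 4 scored samples")
  q3 <- unname(stats::quantile(s, 0.75, type = 7))
  med <- unname(stats::median(s))
  if (q3 == med) {
    stop("degenerate score distribution (Q3 == median); supply manual thresholds")
  }
  label <- rep("excluded", nrow(scores))
  label[!is.na(scores$score) & scores$score >= q3] <- "case"
  label[!is.na(scores$score) & scores$score >= 0 & scores$score < med] <- "control"
  if (!any(label == "control")) {
    stop("no controls: every scored sample is negative or above the median")
  }
  out <- data.frame(sample_id = as.character(scores$sample_id), label = label)
  attr(out, "thresholds") <- list(q3 = q3, median = med)
  attr(out, "mode") <- mode
  class(out) <- c("cohort_assignment", "data.frame")
  out
}

#' Build a cohort assignment directly from known labels
#'
#' Convenience constructor used with simulated data, where case status comes
#' from the disease model rather than from symptom scores.
#'
#' @param sample_ids character vector.
#' @param is_case logical vector (TRUE = case); `NA` = excluded.
#' @return a `cohort_assignment`.
#' @export
cohort_from_labels <- function(sample_ids, is_case) {
  stopifnot(length(sample_ids) == length(is_case))
  label <- ifelse(is.na(is_case), "excluded",
                  ifelse(is_case, "case", "control"))
  out <- data.frame(sample_id = as.character(sample_ids), label = label)
  class(out) <- c("cohort_assignment", "data.frame")
  out
}

#' Case and control sample ids of a cohort assignment
#' @param cohort a `cohort_assignment`.
#' @return character vector of sample ids.
#' @export
cohort_cases <- function(cohort) cohort$sample_id[cohort$label == "case"]

#' @rdname cohort_cases
#' @export
cohort_controls <- function(cohort) cohort$sample_id[cohort$label == "control"]

#' Write a cohort assignment with its thresholds sidecar
#'
#' @param cohort a `cohort_assignment`.
#' @param path output TSV (`sample_id`, `label`).
#' @param json_path thresholds sidecar; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, json_path = paste0(path, ".json")) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(mode = attr(cohort, "mode"),
               thresholds = attr(cohort, "thresholds"),
               n_case = sum(cohort$label == "case"),
               n_control = sum(cohort$label == "control"),
               n_excluded = sum(cohort$label == "excluded"))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
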