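# Onset-based clinical score: the four onset classes, the DEE17/NEDIM
# mutation dictionary, and per-group onset summaries.

.onset_levels <- c("very_early", "early", "late", "very_late")

#' Classify disease onset into the four-way clinical score
#'
#' Half-open intervals on postnatal days: very early `[0, 10)`, early
#' `[10, 90)` (10 days to 3 months), late `[90, 730)` (3 months to 2 years),
#' very late `[730, Inf)`. The month/year boundaries use the round clinical
#' conversions 3 months = 90 d and 2 years = 730 d and are configurable.
#'
#' @param onset_days Non-negative onset(s) in days; vectorised.
#' @param boundaries Increasing 3-vector of class boundaries in days.
#' @return A factor with levels `very_early`, `early`, `late`, `very_late`.
#' @examples
#' classify_onset(c(0, 9, 10, 89, 90, 729, 730))
#' @export
classify_onset <- function(onset_days, boundaries = c(10, 90, 730)) {
  if (any(!is.finite(onset_days)) || any(onset_days < 0))
    stop("`onset_days` must be finite and >= 0", call. = FALSE)
  if (length(boundaries) != 3L || any(diff(boundaries) <= 0) ||
      boundaries[1] <= 0)
    stop("`boundaries` must be 3 increasing positive values", call. = FALSE)
  cut(onset_days, breaks = c(0, boundaries, Inf), labels = .onset_levels,
      right = FALSE, include.lowest = TRUE)
}

#' The GNAO1 encephalopathy mutation dictionary
#'
#' The studied pathogenic Gao missense mutations with their OMIM disorder
#' grouping (DEE17 or NEDIM), assigned onset class and biochemical activity
#' status (whether measurable nucleotide binding was observed for the
#' purified protein). Shipped as an editable CSV in `inst/extdata`. Q52P is
#' carried for its disorder/activity status (it contributes to the
#' inactive-mutation group) although it is not among the 16 systematically
#' characterised variants.
#'
#' @return A `data.frame` with columns `mutation`, `disorder`,
#'   `onset_class`, `activity`.
#' @export
gnao1_mutations <- function() {
  path <- system.file("extdata", "gnao1_mutations.csv", package = "gnaokin",
                      mustWork = TRUE)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$onset_class <- factor(tab$onset_class, levels = .onset_levels)
  tab
}

#' Look up the disorder caused by a mutation
#'
#' @param mutation Mutation label(s), e.g. `"R209C"`; vectorised.
#' @param dictionary The mutation dictionary (defaults to
#'   [gnao1_mutations()]).
#' @return Character vector of `"DEE17"` / `"NEDIM"`. Unknown mutations are
#'   an explicit error, never a silent default.
#' @examples
#' disorder_of(c("G45E", "R209C"))
#' @export
disorder_of <- function(mutation, dictionary = gnao1_mutations()) {
  idx <- match(mutation, dictionary$mutation)
  if (anyNA(idx))
    stop("unknown mutation(s): ",
         paste(mutation[is.na(idx)], collapse = ", "), call. = FALSE)
  dictionary$disorder[idx]
}

#' Summarise onset by group
#'
#' Medians are taken over *patients* (not over per-mutation medians); an
#' even-sized group reports the mean of the central pair (the default
#' [stats::median()] convention). Grouping by activity joins the mutation
#' dictionary's biochemical activity status.
#'
#' @param records Cohort `data.frame` with columns `mutation`, `onset_days`
#'   and (for `by_disorder`) `disorder`.
#' @param grouping `"by_disorder"`, `"by_activity"` or `"by_mutation"`.
#' @param dictionary Mutation dictionary used for `by_activity`.
#' @return A `data.frame` with columns `group`, `n`, `median_onset_days`,
#'   ordered by group label.
#' @examples
#' coh <- simulate_cohort(default_cohort_spec(sigma_log = 0))
#' group_onset_summary(coh, "by_disorder")
#' @export
group_onset_summary <- function(records,
                                grouping = c("by_disorder", "by_activity",
                                             "by_mutation"),
                                dictionary = gnao1_mutations()) {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  if (any(records$onset_days < 0))
    stop("`onset_days` must be >= 0", call. = FALSE)
  key <- switch(grouping,
    by_disorder = records$disorder,
    by_mutation = records$mutation,
    by_activity = {
      idx <- match(records$mutation, dictionary$mutation)
      if (anyNA(idx))
        stop("unknown mutation(s): ",
             paste(unique(records$mutation[is.na(idx)]), collapse = ", "),
             call. = FALSE)
      dictionary$activity[idx]
    })
  keep <- !is.na(key)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " record(s) with missing group")
    records <- records[keep, , drop = FALSE]
    key <- key[keep]
  }
  groups <- sort(unique(key))
  out <- data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(key == g), integer(1)),
    median_onset_days = vapply(groups, function(g)
      median(records$onset_days[key == g]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
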