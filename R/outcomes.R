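#' Kaplan-Meier estimate and median survival
#'
#' Product-limit estimator (deaths processed before censorings at tied
#' times, the standard convention). The median is the earliest time at which
#' the estimate drops to 0.5 or below; NA when the curve never reaches 0.5
#' ("not reached").
#'
#' @param times survival times (months).
#' @param events event indicators (1 = death, 0 = censored).
#' @return list with `fit` (a [survival::survfit] object), `median` (months,
#'   NA when not reached), and `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(fit = fit, median = med, n = length(times))
}

#' Log-rank test between two arms
#'
#' Unstratified 1-df log-rank chi-square with the p-value from the upper
#' chi-square tail. With no events in either arm the test is undefined and
#' p = 1 is returned with a warning.
#'
#' @param times_a,events_a arm A survival times and event indicators.
#' @param times_b,events_b arm B.
#' @return list with `chisq` and `p`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    stop("both arms must be non-empty")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    warning("no events in either arm; log-rank undefined, returning p = 1")
    return(list(chisq = 0, p = 1))
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  arm <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# subgroup filters over the clinical table
.apply_filter <- function(clinical, filter) {
  switch(filter,
    all = rep(TRUE, nrow(clinical)),
    metastatic = clinical$stage == "metastatic",
    resectable = clinical$stage == "resectable",
    borderline = clinical$stage == "borderline",
    locally_advanced = clinical$stage == "locally advanced",
    surgery = clinical$surgery %in% TRUE,
    no_surgery = clinical$surgery %in% FALSE,
    stop("unknown subgroup filter: ", filter)
  )
}

#' Compare a genomic group to the rest of the cohort on one clinical measure
#'
#' Continuous measures (age, CA19-9) are compared by medians with a
#' Mann-Whitney U test; categorical measures (race, stage, sex, vital
#' status) by chi-square, switching to Fisher's exact test when any expected
#' cell count is below 5; overall survival by Kaplan-Meier medians with a
#' log-rank p. CA19-9 comparisons are restricted to producers.
#'
#' @param membership named logical vector (patient_id -> in group).
#' @param clinical clinical table (see [read_clinical()]).
#' @param measure one of "age", "ca19_9", "race", "stage", "sex",
#'   "vital_status", "os".
#' @param filter subgroup filter: "all", "metastatic", "resectable",
#'   "borderline", "locally_advanced", "surgery", "no_surgery".
#' @return one-row data.frame (measure, filter, n_group, n_rest, group_value,
#'   rest_value, test, p) or NULL when the comparison is degenerate (empty
#'   group or empty rest after filtering).
#' @export
compare_clinical <- function(membership, clinical,
                             measure = c("age", "ca19_9", "race", "stage",
                                         "sex", "vital_status", "os"),
                             filter = "all") {
  measure <- match.arg(measure)
  clin <- clinical[.apply_filter(clinical, filter), , drop = FALSE]
  m <- membership[clin$patient_id]
  if (measure == "ca19_9") {
    keep <- clin$ca19_9_producer %in% TRUE
    clin <- clin[keep, , drop = FALSE]
    m <- m[keep]
  }
  if (measure == "os") {
    keep <- !is.na(clin$os_months)
    clin <- clin[keep, , drop = FALSE]
    m <- m[keep]
  }
  if (sum(m) == 0L || sum(!m) == 0L) return(NULL)
  row <- data.frame(measure = measure, filter = filter,
                    n_group = sum(m), n_rest = sum(!m),
                    group_value = NA_character_, rest_value = NA_character_,
                    test = NA_character_, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (measure %in% c("age", "ca19_9")) {
    x <- clin[[measure]][m]
    y <- clin[[measure]][!m]
    row$group_value <- format(stats::median(x, na.rm = TRUE))
    row$rest_value <- format(stats::median(y, na.rm = TRUE))
    row$test <- "mann_whitney"
    row$p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  } else if (measure %in% c("race", "stage", "sex", "vital_status")) {
    tab <- table(group = m, value = clin[[measure]])
    if (ncol(tab) < 2L) return(NULL)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      row$test <- "fisher_exact"
      row$p <- stats::fisher.test(tab,
                                  simulate.p.value = length(tab) > 10,
                                  B = 1e4)$p.value
    } else {
      row$test <- "chi_square"
      row$p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    }
  } else { # os
    km_g <- km_estimate(clin$os_months[m], clin$vital_status[m])
    km_r <- km_estimate(clin$os_months[!m], clin$vital_status[!m])
    lr <- suppressWarnings(
      logrank(clin$os_months[m], clin$vital_status[m],
              clin$os_months[!m], clin$vital_status[!m]))
    fmt_med <- function(x) if (is.na(x)) "not reached" else format(round(x, 1))
    row$group_value <- fmt_med(km_g$median)
    row$rest_value <- fmt_med(km_r$median)
    row$test <- "logrank"
    row$p <- lr$p
  }
  row
}

#' Full group-by-measure-by-filter comparison report
#'
#' Evaluates every group against the rest of the cohort for every clinical
#' measure and subgroup filter, mirroring the study's reporting schema. Raw
#' p-values are reported (matching the source analysis); a Benjamini-Hochberg
#' adjusted column (`p_bh`) is appended for convenience.
#'
#' @param membership patients x groups logical matrix from [assign_groups()].
#' @param clinical clinical table.
#' @param measures measures to test (default all supported).
#' @param filters subgroup filters to apply (default: all, metastatic,
#'   resectable, locally_advanced, surgery, no_surgery).
#' @param alpha significance threshold for the filtered view (default 0.05).
#' @return list with `full` (every evaluated row, with group id and `p_bh`)
#'   and `significant` (rows with p < alpha).
#' @export
run_table4 <- function(membership, clinical,
                       measures = c("age", "ca19_9", "race", "stage",
                                    "vital_status", "os"),
                       filters = c("all", "metastatic", "resectable",
                                   "locally_advanced", "surgery",
                                   "no_surgery"),
                       alpha = 0.05) {
  rows <- list()
  for (g in colnames(membership)) {
    memb <- stats::setNames(membership[, g], rownames(membership))
    for (msr in measures) {
      for (fl in filters) {
        r <- compare_clinical(memb, clinical, msr, fl)
        if (!is.null(r)) {
          r$group <- g
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  full <- do.call(rbind, rows)
  if (is.null(full)) {
    full <- data.frame(group = character(0), measure = character(0),
                       filter = character(0), p = numeric(0))
  }
  full <- full[, c("group", setdiff(names(full), "group"))]
  full$p_bh <- stats::p.adjust(full$p, method = "BH")
  list(full = full, significant = full[!is.na(full$p) & full$p < alpha, ])
}
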