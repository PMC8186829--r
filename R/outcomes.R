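# Clinical-course association: Cox proportional-hazards models with a
# mutation x complexity interaction, Kaplan-Meier curves per stratum, and
# pairwise logrank comparisons. This stage is pipeline plumbing over the
# survival package, not bespoke methodology.

#' Fit outcome models for mutation status and lineage complexity
#'
#' Fits Cox proportional-hazards models for the event time with and without
#' the mutation x complexity interaction, Kaplan-Meier curves for the four
#' strata, pairwise logrank tests between strata (unadjusted), and
#' within-status hazard ratios of High vs Low complexity.
#'
#' @param clinical Tibble with `mutation_status` ("M-CLL"/"U-CLL"),
#'   `complexity` ("Low"/"High"), event time and indicator columns.
#' @param time_col,event_col Column names of the time and event indicator.
#' @return Object of class `outcome_model`: `fit_interaction`,
#'   `fit_additive` (coxph), `interaction_p` (Wald p of the interaction
#'   term), `km` (survfit over the four strata), `pairwise` (tibble of
#'   logrank p values; NA with a note when a stratum has no events),
#'   `group_hr` (tibble: High-vs-Low HR and 95% CI within each status).
#' @export
fit_outcome <- function(clinical, time_col = "ttft_months",
                        event_col = "ttft_event") {
  time <- clinical[[time_col]]
  event <- as.integer(clinical[[event_col]])
  if (sum(event) == 0) stop("no events observed; outcome model not fitted")
  df <- data.frame(
    time = time, event = event,
    mutation_status = factor(clinical$mutation_status, c("M-CLL", "U-CLL")),
    complexity = factor(clinical$complexity, c("Low", "High"))
  )
  fit_int <- survival::coxph(survival::Surv(time, event) ~
                               mutation_status * complexity, data = df)
  fit_add <- survival::coxph(survival::Surv(time, event) ~
                               mutation_status + complexity, data = df)
  cf <- summary(fit_int)$coefficients
  int_row <- grep(":", rownames(cf))
  interaction_p <- unname(cf[int_row, "Pr(>|z|)"])
  df$group <- paste(df$mutation_status, df$complexity, sep = "_")
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  groups <- sort(unique(df$group))
  pairs <- utils::combn(groups, 2)
  pairwise <- bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sub <- df[df$group %in% c(a, b), ]
    ev_a <- sum(sub$event[sub$group == a])
    ev_b <- sum(sub$event[sub$group == b])
    if (ev_a == 0 || ev_b == 0) {
      return(tibble(group_a = a, group_b = b, p_value = NA_real_,
                    note = "no events in a stratum"))
    }
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = sub)
    tibble(group_a = a, group_b = b,
           p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
           note = NA_character_)
  }))
  group_hr <- bind_rows(lapply(c("M-CLL", "U-CLL"), function(st) {
    sub <- df[df$mutation_status == st, ]
    if (sum(sub$event) == 0 || length(unique(sub$complexity)) < 2) {
      return(tibble(mutation_status = st, hr = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_))
    }
    fit <- survival::coxph(survival::Surv(time, event) ~ complexity, data = sub)
    ci <- suppressMessages(stats::confint(fit))
    tibble(mutation_status = st, hr = unname(exp(coef(fit)[1])),
           ci_lower = exp(ci[1, 1]), ci_upper = exp(ci[1, 2]))
  }))
  structure(list(fit_interaction = fit_int, fit_additive = fit_add,
                 interaction_p = interaction_p, km = km,
                 pairwise = pairwise, group_hr = group_hr),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("Cox outcome model: interaction p = %.4g\n", x$interaction_p))
  cat("High-vs-Low hazard ratios by IGHV mutation status:\n")
  print(as.data.frame(x$group_hr), row.names = FALSE)
  invisible(x)
}

#' Spearman correlation of variant burden with an outcome time
#'
#' @param variant_fraction Per-sample variant fractions.
#' @param outcome_months Matching outcome times (e.g. TTFT).
#' @return Tibble `rho`, `p_value`, `n`.
#' @export
variant_outcome_correlation <- function(variant_fraction, outcome_months) {
  ok <- !is.na(variant_fraction) & !is.na(outcome_months)
  ct <- suppressWarnings(cor.test(variant_fraction[ok], outcome_months[ok],
                                  method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
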