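# Score-stratified time-to-event analysis: deterministic top-tertile split,
# Kaplan-Meier curves, log-rank test and univariate Cox fits. The underlying
# estimators come from the `survival` package (Efron ties by default).

#' Split samples into top tertile vs bottom two-thirds of a score
#'
#' `high` is the `ceiling(n/3)` samples with the largest scores; ranks are
#' by descending score with ties broken by ascending sample id, so the split
#' is deterministic.
#'
#' @param scores named numeric vector (names = sample ids).
#' @return named character vector of `"high"` / `"low"` labels.
#' @export
stratify_top_tertile <- function(scores) {
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n < 3L) stop("need >= 3 samples with finite scores")
  if (length(unique(scores)) == 1L)
    stop("degenerate stratification: all scores identical")
  ids <- names(scores) %||% as.character(seq_len(n))
  ord <- order(-scores, ids)
  n_high <- ceiling(n / 3)
  labels <- rep("low", n)
  labels[ord[seq_len(n_high)]] <- "high"
  setNames(labels, ids)
}

#' Assemble survival data from a clinical table
#'
#' Extracts `(time, event)` for the chosen endpoint, joins an optional
#' covariate by sample id, and drops samples with missing time or event
#' (logged).
#'
#' @param clinical a [clinical_table()].
#' @param endpoint `"bcr"` (biochemical recurrence) or `"os"`.
#' @param covariate optional named vector (score or group label).
#' @return data.frame `(sample_id, time, event, covariate)`.
#' @export
survival_data <- function(clinical, endpoint = c("bcr", "os"),
                          covariate = NULL) {
  endpoint <- match.arg(endpoint)
  time <- clinical[[paste0("time_to_", endpoint)]]
  event <- clinical[[paste0(endpoint, "_event")]]
  df <- data.frame(sample_id = clinical$sample_id, time = time,
                   event = event, stringsAsFactors = FALSE)
  if (!is.null(covariate))
    df$covariate <- covariate[match(df$sample_id, names(covariate))]
  keep <- !is.na(df$time) & !is.na(df$event) & df$time > 0
  if (!is.null(covariate)) keep <- keep & !is.na(df$covariate)
  if (any(!keep))
    message(sum(!keep), " sample(s) dropped for missing/invalid time, ",
            "event or covariate")
  df[keep, , drop = FALSE]
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimate with risk-set bookkeeping; censoring does not drop
#' the curve.
#'
#' @param sd data.frame with `time` and `event` columns.
#' @param group optional per-row group labels (single curve if omitted).
#' @return `km_curves`: data.frame `(group, time, n_risk, n_event,
#'   n_censor, surv)`.
#' @export
km_estimate <- function(sd, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(sd))
  if (!nrow(sd) || any(table(group) == 0)) stop("empty group")
  fit <- survival::survfit(survival::Surv(sd$time, sd$event) ~ group)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group), length(s$time))
         else sub("^group=", "", as.character(s$strata))
  structure(data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                       n_event = s$n.event, n_censor = s$n.censor,
                       surv = s$surv, stringsAsFactors = FALSE),
            class = c("km_curves", "data.frame"))
}

#' @export
plot.km_curves <- function(x, ...) {
  groups <- unique(x$group)
  plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
       xlab = "time (months)", ylab = "survival probability", ...)
  for (i in seq_along(groups)) {
    sub <- x[x$group == groups[i], ]
    lines(stats::stepfun(sub$time, c(1, sub$surv)), do.points = FALSE,
          col = i)
  }
  legend("bottomleft", legend = groups, col = seq_along(groups), lty = 1)
  invisible(x)
}

#' Log-rank test between two groups
#'
#' Standard observed-minus-expected log-rank statistic on 1 df.
#'
#' @param sd data.frame with `time` and `event`.
#' @param labels two-level group labels per row.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(sd, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("need exactly 2 non-empty groups")
  if (sum(sd$event) < 1L) stop("need at least one event")
  d <- survival::survdiff(survival::Surv(sd$time, sd$event) ~ labels)
  chi2 <- d$chisq
  list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling by default) of a single
#' covariate: binary (e.g. top-tertile label), continuous (a score) or
#' ordinal (grade group coded `<=6` -> 0, `7` -> 1, `>=8` -> 2, so the HR is
#' per unit increase). Monotone-likelihood / non-convergence is flagged on
#' the returned fit rather than thrown.
#'
#' @param sd data.frame with `time`, `event` and `covariate`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return `cox_fit`: list with `beta`, `hr`, `ci95`, `wald_p`, `score_chi2`,
#'   `n`, `n_events`, `ties_method`, `flag`.
#' @export
cox_univariate <- function(sd, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- sd$covariate
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (all(x %in% GRADE_GROUPS)) {
      x <- c("<=6" = 0, "7" = 1, ">=8" = 2)[x]
    } else {
      lev <- sort(unique(x))
      if (length(lev) != 2L)
        stop("character covariate must be binary or a grade group")
      x <- as.numeric(x == lev[2L])  # e.g. low=0, high=... alphabetical
      # label "high"/"low": make "high" the exposed level
      if (all(lev == c("high", "low"))) x <- 1 - x
    }
  }
  if (length(unique(x)) < 2L) stop("covariate is constant")
  n_events <- sum(sd$event)
  if (n_events < 5L)
    warning("fewer than 5 events (", n_events, "); estimates are unstable")
  flag <- NA_character_
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(sd$time, sd$event) ~ x, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      flag <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  z <- qnorm(0.975)
  structure(list(beta = beta, hr = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * z * se),
                 se = se,
                 wald_p = 2 * pnorm(abs(beta / se), lower.tail = FALSE),
                 score_chi2 = unname(fit$score),
                 n = nrow(sd), n_events = n_events,
                 ties_method = ties, flag = flag),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("univariate Cox fit (%s ties): HR = %.3f [%.3f, %.3f], p = %.3g, n = %d (%d events)\n",
              x$ties_method, x$hr, x$ci95[1], x$ci95[2], x$wald_p, x$n,
              x$n_events))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}
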