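#' Build event-free survival records from dated clinical events
#'
#' Event-free survival (EFS) is the time from start of the scheduled
#' treatment to the earliest of progressive disease, change of treatment,
#' or death; participants without an event are censored at the last
#' response/treatment assessment. Dates may be `Date`s or plain day
#' numbers.
#'
#' @param clinical data.frame with columns `sample_id`,
#'   `treatment_start`, and any of `pd_date`, `treatment_change_date`,
#'   `death_date`, `last_assessment_date` (missing = `NA`).
#' @return data.frame with `sample_id`, `time` (days), `event` (0/1).
#' @export
build_efs <- function(clinical) {
  req <- c("sample_id", "treatment_start")
  miss <- setdiff(req, names(clinical))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  evcols <- intersect(c("pd_date", "treatment_change_date", "death_date"),
                      names(clinical))
  as_days <- function(x) as.numeric(x)
  start <- as_days(clinical$treatment_start)
  ev <- sapply(evcols, function(cc) as_days(clinical[[cc]]))
  if (!is.matrix(ev)) ev <- matrix(ev, nrow = nrow(clinical))
  first_event <- suppressWarnings(apply(ev, 1, min, na.rm = TRUE))
  first_event[!is.finite(first_event)] <- NA_real_
  last_ass <- if ("last_assessment_date" %in% names(clinical))
    as_days(clinical$last_assessment_date) else rep(NA_real_, nrow(clinical))

  out <- data.frame(sample_id = as.character(clinical$sample_id),
                    time = NA_real_, event = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(clinical))) {
    if (is.na(start[i])) stop("missing treatment start for ", out$sample_id[i])
    if (!is.na(first_event[i])) {
      if (first_event[i] < start[i])
        stop("event before treatment start for ", out$sample_id[i])
      out$time[i] <- first_event[i] - start[i]
      out$event[i] <- 1L
    } else if (!is.na(last_ass[i])) {
      if (last_ass[i] < start[i])
        stop("last assessment before treatment start for ", out$sample_id[i])
      out$time[i] <- last_ass[i] - start[i]
      out$event[i] <- 0L
    } else {
      stop("neither event nor last assessment date for ", out$sample_id[i])
    }
  }
  out
}

#' Classify induction-therapy response in AML (validation-cohort rule)
#'
#' Responder: post-treatment marrow blasts below 10%, or a complete
#' response with white blood cells regenerated above 1e12 per cubic meter
#' and platelets above 1e14 per cubic meter. Non-responder: marrow blasts
#' dropped by less than 50% of the pre-treatment value, or disease
#' progression. Anything else is unevaluable.
#'
#' @param post_blast_pct post-treatment bone-marrow blasts (%).
#' @param pre_blast_pct pre-treatment blasts (%); may be `NA`.
#' @param wbc,platelets counts per cubic meter (used with
#'   `complete_response`).
#' @param progression logical: documented disease progression.
#' @param complete_response logical: morphologic complete response.
#' @return character vector: `"responder"`, `"non_responder"` or
#'   `"unevaluable"` (vectorized over the inputs).
#' @export
classify_aml_response <- function(post_blast_pct, pre_blast_pct = NA,
                                  wbc = NA, platelets = NA,
                                  progression = FALSE,
                                  complete_response = FALSE) {
  n <- max(lengths(list(post_blast_pct, pre_blast_pct, wbc, platelets,
                        progression, complete_response)))
  post <- rep_len(as.numeric(post_blast_pct), n)
  pre <- rep_len(as.numeric(pre_blast_pct), n)
  wbc <- rep_len(as.numeric(wbc), n)
  plt <- rep_len(as.numeric(platelets), n)
  prog <- rep_len(as.logical(progression), n)
  cr <- rep_len(as.logical(complete_response), n)
  if (any(c(post, pre[!is.na(pre)], wbc[!is.na(wbc)], plt[!is.na(plt)]) < 0,
          na.rm = TRUE))
    stop("negative blast percentages or counts")

  resp <- (!is.na(post) & post < 10) |
    (cr & !is.na(wbc) & !is.na(plt) & wbc > 1e12 & plt > 1e14)
  drop_lt_half <- !is.na(pre) & !is.na(post) & pre > 0 &
    (pre - post) / pre < 0.5
  nonresp <- (drop_lt_half | prog) & !resp
  out <- rep("unevaluable", n)
  out[nonresp] <- "non_responder"
  out[resp] <- "responder"
  out
}

## product-limit estimate via survival::survfit; median convention:
## earliest time with S(t) <= 0.5 (NA when S never reaches 0.5)
km_median_from_fit <- function(fit) {
  i <- which(fit$surv <= 0.5)
  if (!length(i)) NA_real_ else min(fit$time[i])
}

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator of the survival function. The median is
#' reported as the earliest time at which the estimated survival drops
#' to 0.5 or below, `NA` if the curve never reaches 0.5.
#'
#' @param records data.frame with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @return list of class `km_estimate`: `time`, `surv`, `n_risk`,
#'   `n_event` step-function vectors, `median`, and the underlying
#'   `survival::survfit` object as `fit`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1L, all(records$time >= 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = km_median_from_fit(fit),
                 fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate: ", length(x$time), " time points; median ",
      if (is.na(x$median)) "not reached" else format(x$median), "\n", sep = "")
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier estimate
#'
#' Kaplan-Meier median with the roles of event and censoring swapped:
#' censored observations become "events" (end of follow-up), true events
#' become censored. `NA` means the median follow-up was not reached.
#'
#' @param records data.frame with `time` and `event` columns.
#' @return median follow-up time (scalar, `NA` if not reached).
#' @export
reverse_km_median_followup <- function(records) {
  rev <- records
  rev$event <- 1L - as.integer(records$event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rev)
  km_median_from_fit(fit)
}

#' Cox proportional-hazards regression with recorded covariate scalings
#'
#' Thin wrapper over `survival::coxph` (Efron ties) that applies and
#' records the covariate scalings used in reporting: `"per_10pct_viability"`
#' multiplies an AUC by 10 so a unit change of the regressor is a 10%
#' change in cell viability; `"center_2sd"` centers by the mean and
#' divides by twice the standard deviation (to put continuous covariates
#' on a scale comparable with binary factors); `"categorical"` produces
#' treatment-contrast dummies against a configurable reference level
#' (e.g. ELN-22 intermediate risk); `"none"` leaves the covariate as is.
#'
#' @param records data.frame with `time`, `event` and covariate columns.
#' @param covariates named character vector: covariate name -> scaling
#'   (one of `"per_10pct_viability"`, `"center_2sd"`, `"categorical"`,
#'   `"none"`).
#' @param reference named list of reference levels for categorical
#'   covariates (e.g. `list(eln22 = "intermediate")`).
#' @param conf_level Wald confidence level, default 0.95.
#' @return object of class `cox_result`: `terms` data.frame (`term`,
#'   `hr`, `lower`, `upper`, `p`, `beta`, `se`), `loglik` (at the
#'   estimate), `loglik_null`, `scalings`, `converged`, `n`, `n_events`,
#'   and the `survival::coxph` fit as `fit`.
#' @export
cox_fit <- function(records, covariates, reference = list(),
                    conf_level = 0.95) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (sum(records$event) < 1L) stop("no events; Cox model undefined")
  miss <- setdiff(names(covariates), names(records))
  if (length(miss)) stop("covariates not in records: ", paste(miss, collapse = ", "))

  dat <- records[, c("time", "event"), drop = FALSE]
  for (nm in names(covariates)) {
    x <- records[[nm]]
    sc <- covariates[[nm]]
    dat[[nm]] <- switch(sc,
      per_10pct_viability = {
        if (stats::sd(x, na.rm = TRUE) == 0) stop("covariate '", nm, "' is constant")
        x * 10
      },
      center_2sd = {
        s <- stats::sd(x, na.rm = TRUE)
        if (s == 0) stop("covariate '", nm, "' is constant")
        (x - mean(x, na.rm = TRUE)) / (2 * s)
      },
      categorical = {
        f <- factor(x)
        if (nlevels(f) < 2L) stop("covariate '", nm, "' is constant")
        if (!is.null(reference[[nm]])) f <- stats::relevel(f, ref = reference[[nm]])
        f
      },
      none = {
        if (is.numeric(x) && stats::sd(x, na.rm = TRUE) == 0)
          stop("covariate '", nm, "' is constant")
        x
      },
      stop("unknown scaling '", sc, "' for covariate '", nm, "'"))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(names(covariates), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  terms <- data.frame(term = names(beta), hr = exp(beta),
                      lower = exp(beta - z * se), upper = exp(beta + z * se),
                      p = 2 * stats::pnorm(-abs(beta / se)),
                      beta = beta, se = se,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms,
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 scalings = covariates,
                 converged = converged && all(is.finite(beta)),
                 n = fit$n, n_events = fit$nevent, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox PH fit (Efron ties): n=", x$n, ", events=", x$n_events, "\n", sep = "")
  print(transform(x$terms[, c("term", "hr", "lower", "upper", "p")],
                  hr = signif(hr, 3), lower = signif(lower, 3),
                  upper = signif(upper, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

## standardized two-sample log-rank statistic for group = (marker <= mu):
## sum over event times of (observed - expected) events in group 1,
## divided by the square root of the summed hypergeometric variances
logrank_standardized <- function(in_group, time, event) {
  et <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_group)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in_group)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(NA_real_)
  o_minus_e / sqrt(v)
}

#' Maximally selected log-rank cutpoint for a continuous marker
#'
#' Scans candidate cutpoints of a continuous marker (e.g. a drug's AUC)
#' and returns the one maximizing the absolute standardized two-sample
#' log-rank statistic between the induced groups. Candidates are the
#' unique marker values whose split keeps the low group's proportion
#' inside the quantile range. Used for visualization: participants with
#' marker above the cutpoint are labelled "weak responders" (higher
#' surviving fraction ex vivo), those at or below it "responders". No
#' p-value for the maximal statistic is computed.
#'
#' @param marker numeric marker vector, one value per record.
#' @param records data.frame with `time` and `event` columns, aligned
#'   with `marker`.
#' @param range quantile pair bounding admissible splits; default
#'   `c(0.1, 0.9)`.
#' @return object of class `cutpoint_result`: `cutpoint`, `statistic`
#'   (max |standardized log-rank|), `n_responder` (marker <= cutpoint),
#'   `n_weak_responder` (marker > cutpoint), `range`, `candidates`
#'   (data.frame of all scanned cutpoints and statistics).
#' @export
maxstat_cutpoint <- function(marker, records, range = c(0.1, 0.9)) {
  stopifnot(length(marker) == nrow(records))
  ok <- stats::complete.cases(marker, records$time, records$event)
  marker <- marker[ok]
  time <- records$time[ok]; event <- as.integer(records$event[ok])
  n <- length(marker)
  if (n < 10L) stop("need at least 10 records")
  if (sum(event) < 1L) stop("need at least 1 event")
  u <- sort(unique(marker))
  if (length(u) < 2L) stop("constant marker: no admissible cutpoint")
  prop_low <- vapply(u, function(m) mean(marker <= m), numeric(1))
  cand <- u[prop_low >= range[1] & prop_low <= range[2]]
  if (!length(cand)) stop("no admissible cutpoint within the quantile range")

  stat <- vapply(cand, function(m)
    abs(logrank_standardized(marker <= m, time, event)), numeric(1))
  if (all(is.na(stat))) stop("log-rank statistic undefined for all candidates")
  best <- which(stat == max(stat, na.rm = TRUE))[1] # ties -> smaller cutpoint
  mu <- cand[best]
  structure(list(cutpoint = mu, statistic = stat[best],
                 n_responder = sum(marker <= mu),
                 n_weak_responder = sum(marker > mu),
                 range = range,
                 candidates = data.frame(cutpoint = cand, statistic = stat)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("maximally selected log-rank cutpoint: ", format(signif(x$cutpoint, 4)),
      " (|S| = ", format(round(x$statistic, 3)), ")\n",
      "  responders (marker <= cutpoint): ", x$n_responder,
      "; weak responders (marker > cutpoint): ", x$n_weak_responder, "\n",
      sep = "")
  invisible(x)
}

#' Export a Kaplan-Meier curve as a step-function table
#'
#' @param km a [km_estimate()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(km, path) {
  stopifnot(inherits(km, "km_estimate"))
  utils::write.table(
    data.frame(time = km$time, survival = km$surv, n_risk = km$n_risk,
               n_event = km$n_event),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
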