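#' Per-drug two-sample comparison of ex vivo response between in vivo groups
#'
#' For every drug column, runs a two-sided two-sample t-test of AUC between
#' two in vivo response groups (e.g. responders R vs progressive disease
#' PD). The reported `mean_diff` is signed `g1 - g2`, so with `g1 = "R"`
#' a negative difference means responders were more drug-sensitive ex vivo
#' (lower surviving fraction).
#'
#' @param matrix a [assemble_matrix()] result (or plain numeric matrix with
#'   sample rownames).
#' @param labels named character/factor vector mapping sample_id to group.
#' @param g1,g2 the two group labels to compare.
#' @param var_equal `FALSE` (Welch, default) or `TRUE` (pooled variance).
#' @param adjust `"none"` (default; exploratory-cohort convention) or
#'   `"BH"` to add Benjamini-Hochberg adjusted p-values
#'   (validation-cohort convention, 10% FDR).
#' @return data.frame with one row per testable drug: `drug_id`, `n1`,
#'   `n2`, `mean_diff`, `t`, `p`, and `p_adj` if requested. Drugs with
#'   fewer than 2 observations in either group are skipped; skipped drugs
#'   and reasons are in `attr(, "skipped")`.
#' @export
compare_groups <- function(matrix, labels, g1, g2, var_equal = FALSE,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  vals <- response_values(matrix)
  labels <- labels[rownames(vals)]
  res <- list(); skipped <- list()
  for (d in colnames(vals)) {
    x1 <- vals[which(labels == g1), d]
    x2 <- vals[which(labels == g2), d]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L) {
      skipped[[d]] <- sprintf("fewer than 2 observations in a group (n1=%d, n2=%d)",
                              length(x1), length(x2))
      next
    }
    if (stats::var(x1) + stats::var(x2) == 0) {
      ## identical constant groups: no evidence of difference
      tt <- list(statistic = c(t = 0), p.value = 1)
      if (mean(x1) != mean(x2)) {
        skipped[[d]] <- "zero within-group variance with different means"
        next
      }
    } else {
      tt <- stats::t.test(x1, x2, var.equal = var_equal)
    }
    res[[d]] <- data.frame(drug_id = d, n1 = length(x1), n2 = length(x2),
                           mean_diff = mean(x1) - mean(x2),
                           t = unname(tt$statistic), p = tt$p.value,
                           stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(drug_id = character(0), n1 = integer(0), n2 = integer(0),
               mean_diff = numeric(0), t = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  if (adjust == "BH" && nrow(out)) out$p_adj <- adjust_bh(out$p)
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Pathway-level response matrix
#'
#' Averages AUC values over the drugs of each pathway/mode-of-action class
#' per sample, giving a pathway-level response matrix. Missing drugs are
#' dropped from the per-sample mean (available-case average); a pathway
#' with no measured drug for a sample yields `NA`.
#'
#' @param matrix a `drug_response_matrix` or numeric matrix.
#' @param classes named character vector mapping drug_id to pathway; drugs
#'   without a mapping are ignored.
#' @return a `drug_response_matrix` whose columns are pathways.
#' @export
pathway_average <- function(matrix, classes) {
  vals <- response_values(matrix)
  classes <- classes[names(classes) %in% colnames(vals)]
  if (!length(classes)) stop("no annotated drug found in the matrix")
  pw <- sort(unique(unname(classes)))
  out <- matrix(NA_real_, nrow(vals), length(pw),
                dimnames = list(rownames(vals), pw))
  for (p in pw) {
    d <- names(classes)[classes == p]
    out[, p] <- rowMeans(vals[, d, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  structure(list(values = out, sample_ids = rownames(out), drug_ids = pw,
                 excluded = data.frame(sample_id = character(0),
                                       reason = character(0))),
            class = "drug_response_matrix")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; order-preserving wrapper with
#' input validation. Validation-cohort analyses call associations with
#' adjusted p below 0.1 significant (10% FDR).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlation between two numeric vectors
#'
#' Pearson product-moment or Kendall rank correlation with a two-sided
#' p-value.
#'
#' @param x,y numeric vectors of equal length (>= 3); pairs with missing
#'   values are dropped.
#' @param method `"pearson"` or `"kendall"`.
#' @return list with `estimate`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = method)
}

#' Group test with a blocking factor
#'
#' Tests the group effect on a response while adjusting for a blocking
#' factor (e.g. tumor infiltration) via a two-factor additive linear model
#' `response ~ group + stratum`; the returned p-value is the partial
#' t/F test on the group term. A continuous blocking variable is binned
#' into quartile strata first.
#'
#' @param auc numeric response vector.
#' @param group two-level grouping (factor/character/logical).
#' @param stratum blocking factor; numeric input is cut at its quartiles.
#' @return list with `p`, `estimate` (group effect), `df_residual`,
#'   `strata_used`.
#' @export
blocked_group_test <- function(auc, group, stratum) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (is.numeric(stratum)) {
    qs <- unique(stats::quantile(stratum, probs = c(0.25, 0.5, 0.75), na.rm = TRUE))
    stratum <- cut(stratum, breaks = c(-Inf, qs, Inf), labels = FALSE)
  }
  stratum <- factor(stratum)
  if (nlevels(stratum) < 2L) stop("need at least 2 strata")
  fit <- stats::lm(auc ~ group + stratum)
  cf <- summary(fit)$coefficients
  gterm <- paste0("group", levels(group)[2])
  if (anyNA(stats::coef(fit)) || !(gterm %in% rownames(cf)))
    stop("group is aliased with the blocking factor; effect not estimable")
  list(p = cf[gterm, "Pr(>|t|)"], estimate = cf[gterm, "Estimate"],
       df_residual = fit$df.residual, strata_used = nlevels(stratum))
}

#' Pairwise drug-drug correlation matrix
#'
#' Pairwise-complete Pearson correlations between the AUC columns of a
#' response matrix; a plausibility check that drugs with a shared mode of
#' action (e.g. vinca alkaloids, BTK or BCL-2 inhibitors) correlate
#' strongly. Pairs with fewer than `min_pairs` complete samples are `NA`.
#'
#' @param matrix a `drug_response_matrix` or numeric matrix.
#' @param min_pairs minimum complete pairs per correlation (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
drug_correlation_matrix <- function(matrix, min_pairs = 3L) {
  vals <- response_values(matrix)
  r <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(vals))
  r[npair < min_pairs] <- NA_real_
  diag(r) <- 1
  r
}

## accept either the classed container or a bare matrix
response_values <- function(matrix) {
  if (inherits(matrix, "drug_response_matrix")) matrix$values
  else as.matrix(matrix)
}
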