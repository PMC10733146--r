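#' Trapezoidal area under the dose-response curve
#'
#' Summarizes a drug's effect across its tested concentrations as the
#' trapezoidal integral of relative viability over concentration *ranks*
#' (1..n), normalized by the rank span. A constant viability v therefore
#' gives AUC = v, and AUC is directly interpretable as an average surviving
#' fraction: higher AUC = more ex vivo resistance. The rank axis makes
#' drugs with different (and partly unpublished) concentration ranges
#' comparable; an explicit axis can be supplied via `x`.
#'
#' @param viabilities numeric vector ordered from lowest to highest
#'   concentration; no missing values (no imputation is performed).
#' @param x optional numeric axis (e.g. log10 molar concentrations),
#'   strictly increasing, same length; default is the rank axis `1..n`.
#' @return the normalized trapezoidal AUC (scalar).
#' @export
auc_trapezoid <- function(viabilities, x = NULL) {
  v <- as.numeric(viabilities)
  if (length(v) < 2L) stop("need at least 2 viability values")
  if (anyNA(v)) stop("missing viability value; AUC requires complete curves")
  if (is.null(x)) x <- seq_along(v)
  if (length(x) != length(v)) stop("x and viabilities differ in length")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  sum(diff(x) * (v[-length(v)] + v[-1]) / 2) / (x[length(x)] - x[1])
}

#' Trapezoidal volume under a two-drug viability surface
#'
#' The combination analogue of [auc_trapezoid()]: a composite 2-D
#' trapezoidal integral of viability over the concentration-rank grid of
#' the two drugs, normalized by the grid area so a constant surface v
#' gives VUC = v.
#'
#' @param grid numeric matrix of viabilities; rows = concentration ranks of
#'   drug A (low to high), columns = ranks of drug B. Must be complete and
#'   at least 2 x 2.
#' @return the normalized VUC (scalar).
#' @export
vuc_trapezoid <- function(grid) {
  g <- as.matrix(grid)
  if (anyNA(g)) stop("ragged or incomplete combination grid")
  if (nrow(g) < 2L || ncol(g) < 2L) stop("grid must be at least 2x2")
  wr <- c(0.5, rep(1, nrow(g) - 2L), 0.5)
  wc <- c(0.5, rep(1, ncol(g) - 2L), 0.5)
  as.numeric(wr %*% g %*% wc) / ((nrow(g) - 1L) * (ncol(g) - 1L))
}

## five-parameter logistic, LL.5 parameterization:
## v(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))^f
ll5 <- function(x, b, c, d, e, f) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))^f
}

#' Fit a five-parameter logistic dose-response curve
#'
#' Least-squares fit of the 5PL model
#' \deqn{v(x) = c + \frac{d - c}{\left(1 + e^{b(\log x - \log e)}\right)^f}}
#' with slope b, lower asymptote c, upper asymptote d, inflection
#' concentration e and asymmetry f. Fitting uses Levenberg-Marquardt
#' (minpack.lm) with box constraints and up to three starting points;
#' curves are used for visualization, so robustness is favoured over
#' precision. Flat data (zero variance) are returned directly as the
#' degenerate constant curve.
#'
#' @param concs strictly increasing positive concentrations.
#' @param viabilities matching viability values.
#' @param bounds list with elements `cd` (range for both asymptotes,
#'   default `c(-0.5, 2)`), `e_factor` (e constrained to
#'   `[min(concs)/e_factor, max(concs)*e_factor]`, default 100),
#'   `f` (default `c(0.1, 10)`), `b` (default `c(-50, 50)`).
#' @return object of class `curve_5pl`: list with `drug_id` (if set via
#'   attribute), coefficients `b`, `c`, `d`, `e`, `f`, `rss`, `converged`,
#'   and `fitted` values.
#' @export
fit_5pl <- function(concs, viabilities, bounds = list()) {
  x <- as.numeric(concs); v <- as.numeric(viabilities)
  if (length(x) != length(v)) stop("concs and viabilities differ in length")
  if (any(x <= 0)) stop("concentrations must be positive")
  if (any(diff(x) <= 0)) stop("concentrations must be strictly increasing")
  if (anyNA(v)) stop("missing viability values")

  flat <- function(level, converged) {
    structure(list(b = 0, c = level, d = level, e = exp(mean(log(x))), f = 1,
                   rss = sum((v - level)^2), converged = converged,
                   fitted = rep(level, length(v)), concs = x, viabilities = v),
              class = "curve_5pl")
  }
  if (stats::var(v) < 1e-20) return(flat(mean(v), TRUE))

  b_cd <- bounds$cd %||% c(-0.5, 2)
  b_e <- c(min(x) / (bounds$e_factor %||% 100), max(x) * (bounds$e_factor %||% 100))
  b_f <- bounds$f %||% c(0.1, 10)
  b_b <- bounds$b %||% c(-50, 50)
  lower <- c(b = b_b[1], c = b_cd[1], d = b_cd[1], e = b_e[1], f = b_f[1])
  upper <- c(b = b_b[2], c = b_cd[2], d = b_cd[2], e = b_e[2], f = b_f[2])

  e0 <- exp(mean(log(x)))
  starts <- list(
    c(b = 1,   c = min(v), d = max(v), e = e0, f = 1),
    c(b = 3,   c = min(v), d = max(v), e = exp(stats::weighted.mean(log(x), abs(diff(c(v[1], v))))), f = 1),
    c(b = 0.5, c = min(v), d = max(v), e = sqrt(b_e[1] * b_e[2]), f = 2))

  best <- NULL
  dat <- data.frame(x = x, v = v)
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ ll5(x, b, c, d, e, f), data = dat,
                        start = as.list(st), lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
      if (best$rss < 1e-12) break
    }
  }
  if (is.null(best)) return(flat(mean(v), FALSE))
  cf <- stats::coef(best$fit)
  structure(list(b = unname(cf["b"]), c = unname(cf["c"]), d = unname(cf["d"]),
                 e = unname(cf["e"]), f = unname(cf["f"]),
                 rss = best$rss, converged = TRUE,
                 fitted = as.numeric(stats::fitted(best$fit)),
                 concs = x, viabilities = v),
            class = "curve_5pl")
}

#' @export
predict.curve_5pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$concs else as.numeric(newdata)
  ll5(x, object$b, object$c, object$d, object$e, object$f)
}

#' @export
print.curve_5pl <- function(x, ...) {
  cat("5PL fit: b=", signif(x$b, 3), " c=", signif(x$c, 3),
      " d=", signif(x$d, 3), " e=", signif(x$e, 3), " f=", signif(x$f, 3),
      " rss=", format(x$rss, digits = 3),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the sample x drug response matrix
#'
#' Collapses QC-passed viability tables into a numeric matrix of
#' trapezoidal AUC values (samples in rows, drugs in columns). Declared
#' drug combinations are added as pseudo-drug columns `"A+B"` holding the
#' VUC of the combination grid. Samples lacking a drug's panel get `NA`
#' in that column; analyses that need complete rows (e.g.
#' [stability_select()]) restrict to complete cases.
#'
#' @param tables list of `viability_table`s, one per sample (use
#'   [average_replicates()] first if a sample has replicate plates).
#'   Tables with `qc_status == "fail"` are excluded and recorded.
#' @param combinations optional list of 2-element character vectors
#'   declaring combination pseudo-drugs to extract from `combo_entries`.
#' @return object of class `drug_response_matrix`: list with `values`
#'   (numeric matrix), `sample_ids`, `drug_ids`, and `excluded`
#'   (data.frame of dropped samples and reason codes).
#' @export
assemble_matrix <- function(tables, combinations = NULL) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "viability_table")))
  sids <- vapply(tables, `[[`, character(1), "sample_id")
  if (anyDuplicated(sids))
    stop("duplicate sample_id: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "),
         " (average replicates first)")
  qc <- vapply(tables, `[[`, character(1), "qc_status")
  excluded <- data.frame(sample_id = sids[qc == "fail"],
                         reason = rep("qc_control_sd", sum(qc == "fail")),
                         stringsAsFactors = FALSE)
  tables <- tables[qc != "fail"]
  sids <- sids[qc != "fail"]
  if (!length(tables)) stop("no QC-passed samples to assemble")

  drugs <- sort(unique(unlist(lapply(tables, function(t) unique(t$entries$drug_id)))))
  combo_names <- character(0)
  if (!is.null(combinations))
    combo_names <- vapply(combinations, function(p) paste(p, collapse = "+"), character(1))
  all_cols <- c(drugs, combo_names)

  values <- matrix(NA_real_, nrow = length(tables), ncol = length(all_cols),
                   dimnames = list(sids, all_cols))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    for (d in unique(t$entries$drug_id)) {
      e <- t$entries[t$entries$drug_id == d, ]
      e <- e[order(e$conc_index), ]
      values[i, d] <- auc_trapezoid(e$viability)
    }
    if (length(combo_names) && nrow(t$combo_entries)) {
      for (k in seq_along(combinations)) {
        p <- combinations[[k]]
        cb <- t$combo_entries[t$combo_entries$drug_a == p[1] &
                                t$combo_entries$drug_b == p[2], ]
        if (!nrow(cb)) { # allow reversed order in the layout
          cb <- t$combo_entries[t$combo_entries$drug_a == p[2] &
                                  t$combo_entries$drug_b == p[1], ]
          if (nrow(cb)) cb <- data.frame(drug_a = cb$drug_b, conc_a = cb$conc_b,
                                         drug_b = cb$drug_a, conc_b = cb$conc_a,
                                         viability = cb$viability)
        }
        if (nrow(cb)) {
          ia <- sort(unique(cb$conc_a)); ib <- sort(unique(cb$conc_b))
          g <- matrix(NA_real_, length(ia), length(ib))
          g[cbind(match(cb$conc_a, ia), match(cb$conc_b, ib))] <- cb$viability
          values[i, combo_names[k]] <- vuc_trapezoid(g)
        }
      }
    }
  }
  structure(list(values = values, sample_ids = sids, drug_ids = all_cols,
                 excluded = excluded),
            class = "drug_response_matrix")
}

#' @export
print.drug_response_matrix <- function(x, ...) {
  cat("drug_response_matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " drugs; ", sum(is.na(x$values)), " missing entries; ",
      nrow(x$excluded), " samples excluded by QC\n", sep = "")
  invisible(x)
}

#' Write a drug response matrix as TSV
#'
#' Samples in rows, drugs in columns, `NA` for panel-missing entries.
#'
#' @param matrix a `drug_response_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "drug_response_matrix"))
  out <- data.frame(sample_id = rownames(matrix$values), matrix$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
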