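#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or two-level factor; the
#'   larger/second level is the positive class).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as_binary(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.factor(labels)) as.integer(labels) - 1L
  else if (is.logical(labels)) as.integer(labels)
  else {
    u <- sort(unique(labels))
    if (length(u) > 2L) stop("labels must be binary")
    as.integer(labels == u[length(u)])
  }
}

#' Configuration for elastic-net stability selection
#'
#' Bundles the tuning constants of the repeated cross-validated
#' elastic-net logistic regression: the mixing parameter alpha (0.3
#' balances ridge-like shrinkage against lasso variable selection),
#' the number of refitted models, the fold count (3, chosen small
#' because of the limited cohort size), and the regressor unit
#' (`unit_scale = 0.10` means coefficients are log odds ratios per 10%
#' change in ex vivo viability).
#'
#' @param alpha elastic-net mixing parameter in \[0, 1\]; default 0.3.
#' @param n_models number of random cross-validation splits; default 1000.
#' @param n_folds folds per split; default 3.
#' @param lambda_path optional decreasing penalty path; default: 100
#'   log-spaced values from the data-derived lambda_max down to
#'   lambda_max * 1e-3.
#' @param n_lambda,lambda_min_ratio path resolution when `lambda_path`
#'   is computed from the data.
#' @param unit_scale viability units per regressor unit; default 0.10.
#' @param seed master seed for the random fold splits.
#' @return list of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.3, n_models = 1000L, n_folds = 3L,
                        lambda_path = NULL, n_lambda = 100L,
                        lambda_min_ratio = 1e-3, unit_scale = 0.10,
                        seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n_folds >= 2L, n_models >= 1L,
            unit_scale > 0)
  if (!is.null(lambda_path) && any(diff(lambda_path) >= 0))
    stop("lambda_path must be strictly decreasing")
  structure(list(alpha = alpha, n_models = as.integer(n_models),
                 n_folds = as.integer(n_folds), lambda_path = lambda_path,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 unit_scale = unit_scale, seed = as.integer(seed)),
            class = "enet_config")
}

## lambda_max: smallest penalty with all coefficients zero, computed on
## internally standardized columns (glmnet convention)
lambda_max_binomial <- function(X, y, alpha) {
  n <- nrow(X)
  xs <- scale(X, center = TRUE, scale = apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))))
  p1 <- mean(y)
  g <- abs(crossprod(xs, y - p1)) / n
  max(g) / max(alpha, 1e-3)
}

default_lambda_path <- function(X, y, config) {
  if (!is.null(config$lambda_path)) return(config$lambda_path)
  lmax <- lambda_max_binomial(X, y, config$alpha)
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$n_lambda))
}

#' Elastic-net penalized logistic regression at fixed penalty
#'
#' Fits the penalized logistic log-likelihood
#' \deqn{\frac1n \sum_i -[y_i \eta_i - \log(1 + e^{\eta_i})] +
#'   \lambda\left(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right)}
#' with unpenalized intercept; columns are standardized internally and
#' coefficients are reported on the caller's scale (glmnet backend).
#'
#' @param X numeric matrix (n x p), complete.
#' @param y binary response.
#' @param alpha elastic-net mixing parameter.
#' @param lambda penalty value (scalar).
#' @return list with `beta` (length p, named), `intercept`, `alpha`,
#'   `lambda`.
#' @export
enet_logistic_fit <- function(X, y, alpha, lambda) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite and complete")
  y <- as_binary(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  path <- sort(unique(c(default_lambda_path(
    X, y, enet_config(alpha = alpha, seed = 1L)), lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = TRUE, thresh = 1e-12)
  cf <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  list(beta = stats::setNames(cf[-1], colnames(X)), intercept = cf[1],
       alpha = alpha, lambda = lambda)
}

#' Cross-validated AUROC model selection along a penalty path
#'
#' For each penalty on the path, pools the out-of-fold predicted
#' probabilities across the folds of one random split and computes the
#' AUROC; the selected penalty maximizes the pooled AUROC (ties broken
#' toward the larger, i.e. sparser, penalty). Final coefficients come
#' from a full-data fit at the selected penalty.
#'
#' @param X numeric matrix (n x p), complete.
#' @param y binary response.
#' @param config an [enet_config()].
#' @param fold_assignment integer vector in `1..n_folds` per sample;
#'   every fold must contain both classes (use [stratified_folds()]).
#' @return list with `lambda_best`, `auroc_at_best`, `beta`, `intercept`,
#'   `lambda_path`, `auroc_path`.
#' @export
cv_auroc_path <- function(X, y, config, fold_assignment) {
  X <- as.matrix(X)
  y <- as_binary(y)
  folds <- as.integer(fold_assignment)
  stopifnot(length(folds) == nrow(X))
  path <- default_lambda_path(X, y, config)
  pred <- matrix(NA_real_, nrow(X), length(path))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2L)
      stop("fold ", k, ": training data contains a single class; ",
           "use stratified fold assignment")
    ## glmnet warns when a class has < 8 observations; with a rare
    ## progression endpoint that is the expected operating regime
    fit <- suppressWarnings(
      glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                     alpha = config$alpha, lambda = path,
                     standardize = TRUE))
    pr <- stats::predict(fit, X[!tr, , drop = FALSE], s = path,
                         type = "response", exact = FALSE)
    pred[!tr, ] <- as.matrix(pr)
  }
  aur <- apply(pred, 2, auroc, labels = y)
  best <- which.max(aur) # first max = largest lambda (path is decreasing)
  full <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = config$alpha,
                   lambda = path, standardize = TRUE))
  cf <- as.numeric(stats::coef(full, s = path[best], exact = FALSE))
  list(lambda_best = path[best], auroc_at_best = aur[best],
       beta = stats::setNames(cf[-1], colnames(X)), intercept = cf[1],
       lambda_path = path, auroc_path = aur)
}

#' Stratified fold assignment
#'
#' Random fold labels preserving the class proportions, so every fold
#' contains both classes even with a strongly imbalanced endpoint.
#'
#' @param y binary response.
#' @param n_folds number of folds.
#' @return integer vector of fold labels in `1..n_folds`.
#' @export
stratified_folds <- function(y, n_folds) {
  y <- as_binary(y)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    ## a class smaller than n_folds simply spreads over its first folds
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Elastic-net stability selection of predictive drug responses
#'
#' The covariate-selection procedure for the in vivo endpoint: an
#' elastic-net logistic regression of binary response (R vs PD) on
#' ex vivo drug AUCs is refit over `n_models` independent random
#' stratified cross-validation splits, selecting the penalty by pooled
#' out-of-fold AUROC each time. Per covariate the procedure reports the
#' fraction of models in which it received a nonzero coefficient
#' (selection proportion), the median log odds ratio over all models
#' (zeros included) and over selected models only, and the median
#' cross-validation AUROC of the models that selected it.
#'
#' Regressors are divided by `config$unit_scale` (default 0.10) before
#' fitting, so odds ratios refer to a 10% change in ex vivo viability.
#' Only complete-case samples (all requested drugs measured) enter.
#'
#' @param matrix a `drug_response_matrix` or numeric matrix of AUCs.
#' @param labels named vector mapping sample_id to in vivo response;
#'   samples labelled `g_pos` are the positive class, `g_neg` the
#'   reference; all other labels (e.g. `"SD"`) are dropped.
#' @param drug_subset columns to use as covariates (e.g. the
#'   chemotherapeutics); default all columns.
#' @param config an [enet_config()]; `config$seed` makes the whole
#'   procedure deterministic.
#' @param g_pos,g_neg positive / reference class labels (default
#'   `"PD"` / `"R"`: the model predicts progressive disease).
#' @return object of class `stability_selection`: list with `covariates`
#'   (data.frame: `covariate`, `selection_proportion`, `median_log_or`,
#'   `median_or`, `median_log_or_selected`, `median_cv_auroc_when_selected`,
#'   ordered by decreasing selection proportion), `global_median_cv_auroc`,
#'   `n_complete_samples`, `n_models`, `config`.
#' @export
stability_select <- function(matrix, labels, drug_subset = NULL,
                             config = enet_config(),
                             g_pos = "PD", g_neg = "R") {
  vals <- response_values(matrix)
  if (is.null(drug_subset)) drug_subset <- colnames(vals)
  missing_drugs <- setdiff(drug_subset, colnames(vals))
  if (length(missing_drugs))
    stop("drugs not in matrix: ", paste(missing_drugs, collapse = ", "))
  labels <- labels[rownames(vals)]
  keep <- !is.na(labels) & labels %in% c(g_pos, g_neg)
  X <- vals[keep, drug_subset, drop = FALSE]
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  y <- as.integer(labels[keep][cc] == g_pos)
  n <- nrow(X)
  if (n < config$n_folds)
    stop("fewer complete-case samples (", n, ") than folds (", config$n_folds, ")")
  if (length(unique(y)) < 2L) stop("both response classes required")

  X <- X / config$unit_scale
  path <- default_lambda_path(X, y, config)
  cfg <- config; cfg$lambda_path <- path

  set.seed(config$seed)
  model_seeds <- sample.int(.Machine$integer.max - 1L, config$n_models)
  p <- ncol(X)
  betas <- matrix(NA_real_, config$n_models, p,
                  dimnames = list(NULL, colnames(X)))
  aurocs <- numeric(config$n_models)
  for (m in seq_len(config$n_models)) {
    set.seed(model_seeds[m])
    folds <- stratified_folds(y, config$n_folds)
    res <- cv_auroc_path(X, y, cfg, folds)
    betas[m, ] <- res$beta
    aurocs[m] <- res$auroc_at_best
  }

  sel <- betas != 0
  med_all <- apply(betas, 2, stats::median)
  med_sel <- vapply(seq_len(p), function(j)
    if (any(sel[, j])) stats::median(betas[sel[, j], j]) else NA_real_, numeric(1))
  auroc_sel <- vapply(seq_len(p), function(j)
    if (any(sel[, j])) stats::median(aurocs[sel[, j]]) else NA_real_, numeric(1))

  cov_df <- data.frame(covariate = colnames(X),
                       selection_proportion = colMeans(sel),
                       median_log_or = med_all,
                       median_or = exp(med_all),
                       median_log_or_selected = med_sel,
                       median_cv_auroc_when_selected = auroc_sel,
                       stringsAsFactors = FALSE)
  cov_df <- cov_df[order(-cov_df$selection_proportion, cov_df$covariate), ]
  rownames(cov_df) <- NULL
  structure(list(covariates = cov_df,
                 global_median_cv_auroc = stats::median(aurocs),
                 n_complete_samples = n,
                 n_models = config$n_models,
                 config = config),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("stability_selection: ", x$n_models, " models on ",
      x$n_complete_samples, " complete-case samples; global median CV AUROC ",
      round(x$global_median_cv_auroc, 3), "\n", sep = "")
  top <- x$covariates[x$covariates$selection_proportion > 0.5, ]
  if (nrow(top)) {
    cat("covariates with selection proportion > 0.5:\n")
    print(top[, c("covariate", "selection_proportion", "median_or")],
          row.names = FALSE, digits = 3)
  } else cat("no covariate selected in more than half of the models\n")
  invisible(x)
}

#' Write stability-selection results as TSV
#'
#' @param result a [stability_select()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_stability_selection <- function(result, path) {
  stopifnot(inherits(result, "stability_selection"))
  utils::write.table(result$covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
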