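#' Per-sample drug ranking report
#'
#' Orders a sample's drugs by ascending AUC (most ex vivo-sensitive
#' first; ties broken alphabetically) and, when a reference response
#' matrix is supplied, adds the cohort-relative percentile of each AUC
#' (fraction of reference samples with AUC at or below the sample's,
#' in percent).
#'
#' @param aucs named numeric vector of the sample's AUC values, or a
#'   `viability_table` (AUCs are then computed per drug).
#' @param reference optional `drug_response_matrix` (or matrix) used for
#'   percentiles.
#' @return data.frame `rank`, `drug_id`, `auc`, and `percentile` when a
#'   reference is given.
#' @export
drug_ranking <- function(aucs, reference = NULL) {
  if (inherits(aucs, "viability_table")) {
    e <- aucs$entries
    if (!nrow(e)) stop("empty viability table")
    aucs <- vapply(split(e, e$drug_id), function(d)
      auc_trapezoid(d$viability[order(d$conc_index)]), numeric(1))
  }
  if (!length(aucs)) stop("no drugs to rank")
  ord <- order(aucs, names(aucs))
  out <- data.frame(rank = seq_along(aucs), drug_id = names(aucs)[ord],
                    auc = unname(aucs[ord]), stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    vals <- response_values(reference)
    out$percentile <- vapply(seq_len(nrow(out)), function(i) {
      col <- vals[, out$drug_id[i]]
      col <- col[!is.na(col)]
      if (!length(col)) return(NA_real_)
      100 * mean(col <= out$auc[i])
    }, numeric(1))
  }
  out
}

#' Exact binomial rate with Clopper-Pearson confidence interval
#'
#' Estimates a success rate with the exact (Clopper-Pearson) interval
#' from Beta quantiles: `lower = qbeta(a/2, x, n-x+1)`,
#' `upper = qbeta(1-a/2, x+1, n-x)`, with the conventions lower = 0 at
#' x = 0 and upper = 100% at x = n. Used for feasibility-style endpoint
#' rates. Percentages are rounded half away from zero to one decimal.
#'
#' @param successes,n counts, `0 <= successes <= n`.
#' @param level confidence level, default 0.95.
#' @return named numeric vector `rate`, `lower`, `upper` (percent, one
#'   decimal); unrounded percentages in `attr(, "raw")`.
#' @export
binomial_rate_ci <- function(successes, n, level = 0.95) {
  x <- successes
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      x != round(x) || n != round(n) || n < 1 || x < 0 || x > n)
    stop("need integer counts with 0 <= successes <= n, n >= 1")
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  raw <- 100 * c(rate = x / n, lower = lower, upper = upper)
  out <- sign(raw) * floor(abs(raw) * 10 + 0.5) / 10 # round half away from zero
  attr(out, "raw") <- raw
  out
}

#' Run the full ex vivo profiling pipeline on files
#'
#' Orchestrates normalize -> QC -> dose-response summarization ->
#' association -> stability selection -> survival over delimited-text
#' inputs, writing result TSVs and a JSON run manifest (config echo,
#' seed, package version, input/output checksums, QC exclusions with
#' reason codes). Stages whose inputs are absent are skipped with a
#' notice; upstream stages still run. Deterministic given the seed.
#'
#' @param config named list or path to a YAML/key-value file with
#'   entries: `layout_file`, `reads_files` (vector, one per
#'   sample/plate), `clinical_file` (optional; columns `sample_id`,
#'   `response`, optional `time`, `event`, covariates),
#'   `annotation_file` (optional; columns `drug_id`, `pathway`),
#'   `out_dir`, and optional `seed` (default 1), `qc_threshold` (0.3),
#'   `alpha` (0.3), `n_models` (1000), `n_folds` (3), `g_pos` ("PD"),
#'   `g_neg` ("R"), `selection_classes` (pathway values whose drugs enter
#'   stability selection; default `"chemotherapeutic"`).
#' @return list with the computed objects (`matrix`, `associations`,
#'   `selection`, `cox`, `manifest`, ...), invisibly; results are also
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  need <- c("layout_file", "reads_files", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  cfg <- utils::modifyList(
    list(seed = 1L, qc_threshold = 0.3, alpha = 0.3, n_models = 1000L,
         n_folds = 3L, g_pos = "PD", g_neg = "R",
         selection_classes = "chemotherapeutic"), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  notices <- character(0)

  ## stage: normalize + QC
  layout <- load_plate_layout(cfg$layout_file)
  tables <- lapply(cfg$reads_files, function(f) {
    read <- tryCatch(load_plate_reads(f, layout),
                     error = function(e) stop("stage normalize failed on '", f,
                                              "': ", conditionMessage(e)))
    normalize_viability(read, layout, qc_threshold = cfg$qc_threshold)
  })
  sids <- vapply(tables, `[[`, character(1), "sample_id")
  ## average technical replicates per sample
  tables <- lapply(split(tables, sids), average_replicates)

  qc <- data.frame(sample_id = names(tables),
                   control_sd = vapply(tables, function(t)
                     t$control_stats$control_sd_viability, numeric(1)),
                   qc_status = vapply(tables, `[[`, character(1), "qc_status"))
  utils::write.table(qc, file.path(cfg$out_dir, "qc_controls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: summarize
  mat <- assemble_matrix(unname(tables))
  write_response_matrix(mat, file.path(cfg$out_dir, "response_matrix.tsv"))

  annotation <- NULL
  if (!is.null(cfg$annotation_file) && file.exists(cfg$annotation_file %||% "")) {
    ann <- read_delimited(cfg$annotation_file)
    annotation <- stats::setNames(as.character(ann$pathway), ann$drug_id)
  }

  associations <- selection <- cox <- km_groups <- NULL
  clinical <- NULL
  if (!is.null(cfg$clinical_file) && file.exists(cfg$clinical_file %||% "")) {
    clinical <- read_delimited(cfg$clinical_file)
  } else {
    notices <- c(notices, "clinical table absent: association and survival stages skipped")
  }

  if (!is.null(clinical) && "response" %in% names(clinical)) {
    labels <- stats::setNames(as.character(clinical$response), clinical$sample_id)
    ## stage: associate (per drug, exploratory convention: raw p)
    associations <- compare_groups(mat, labels, cfg$g_neg, cfg$g_pos)
    utils::write.table(associations,
                       file.path(cfg$out_dir, "associations_drug.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(annotation)) {
      pw <- pathway_average(mat, annotation)
      assoc_pw <- compare_groups(pw, labels, cfg$g_neg, cfg$g_pos)
      utils::write.table(assoc_pw,
                         file.path(cfg$out_dir, "associations_pathway.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ## stage: select
    sel_drugs <- if (!is.null(annotation))
      names(annotation)[annotation %in% cfg$selection_classes] else colnames(mat$values)
    sel_drugs <- intersect(sel_drugs, colnames(mat$values))
    selection <- tryCatch(
      stability_select(mat, labels, drug_subset = sel_drugs,
                       config = enet_config(alpha = cfg$alpha,
                                            n_models = cfg$n_models,
                                            n_folds = cfg$n_folds,
                                            seed = cfg$seed),
                       g_pos = cfg$g_pos, g_neg = cfg$g_neg),
      error = function(e) {
        notices <<- c(notices, paste("stability selection skipped:",
                                     conditionMessage(e)))
        NULL
      })
    if (!is.null(selection))
      write_stability_selection(selection,
                                file.path(cfg$out_dir, "stability_selection.tsv"))
  }

  if (!is.null(clinical) && all(c("time", "event") %in% names(clinical))) {
    ## stage: survival — continuous Cox per top drug + maxstat display split.
    ## Reported p-values come from the continuous Cox model; the
    ## dichotomization is for Kaplan-Meier display only.
    surv_rec <- clinical[!is.na(clinical$time) & !is.na(clinical$event) &
                           clinical$sample_id %in% rownames(mat$values), ]
    top <- if (!is.null(selection)) {
      sel <- selection$covariates
      sel$covariate[sel$selection_proportion > 0.5]
    } else character(0)
    if (!length(top) && !is.null(associations) && nrow(associations))
      top <- associations$drug_id[order(associations$p)][seq_len(min(2, nrow(associations)))]
    cox_rows <- list(); km_groups <- list()
    for (d in top) {
      a <- unname(mat$values[match(surv_rec$sample_id, rownames(mat$values)), d])
      rec <- data.frame(time = surv_rec$time, event = surv_rec$event, auc = a)
      rec <- rec[!is.na(rec$auc), ]
      if (nrow(rec) < 10L || sum(rec$event) < 1L) next
      cx <- cox_fit(rec, c(auc = "per_10pct_viability"))
      cox_rows[[d]] <- data.frame(drug_id = d, cx$terms)
      mc <- tryCatch(maxstat_cutpoint(rec$auc, rec), error = function(e) NULL)
      if (!is.null(mc))
        km_groups[[d]] <- data.frame(drug_id = d, cutpoint = mc$cutpoint,
                                     n_responder = mc$n_responder,
                                     n_weak_responder = mc$n_weak_responder,
                                     cox_p_continuous = cx$terms$p[1])
    }
    if (length(cox_rows)) {
      cox <- do.call(rbind, cox_rows); rownames(cox) <- NULL
      utils::write.table(cox, file.path(cfg$out_dir, "cox_univariate.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(km_groups)) {
      km_groups <- do.call(rbind, km_groups); rownames(km_groups) <- NULL
      utils::write.table(km_groups,
                         file.path(cfg$out_dir, "km_dichotomizations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else if (!is.null(clinical)) {
    notices <- c(notices, "no time/event columns: survival stage skipped")
  }

  ## manifest
  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  inputs <- c(cfg$layout_file, unlist(cfg$reads_files),
              cfg$clinical_file, cfg$annotation_file)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("drpscreen")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "reads_files")],
    n_reads_files = length(cfg$reads_files),
    input_checksums = as.list(tools::md5sum(inputs)),
    output_checksums = as.list(tools::md5sum(sort(outputs))),
    exclusions = if (nrow(mat$excluded)) mat$excluded else NULL,
    notices = notices,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (msg in notices) message(msg)
  invisible(list(matrix = mat, qc = qc, associations = associations,
                 selection = selection, cox = cox, km_groups = km_groups,
                 manifest = manifest))
}
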