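#' Summarize DMSO solvent controls on a plate
#'
#' Computes the control luminescence median and the standard deviation of
#' the control viabilities (control luminescence divided by the control
#' median). The control s.d. is the plate's technical-noise estimate and
#' feeds the QC gate ([qc_gate()]). By default only controls off the outer
#' well ring are used, because edge wells are the most artefact-prone.
#'
#' @param read a [plate_read()].
#' @param layout the matching [plate_layout()].
#' @param control_subset `"inner"` (controls not on the outer boundary,
#'   the default), `"all"`, or `"listed"` with explicit `wells`.
#' @param wells for `control_subset = "listed"`: data.frame of `row`, `col`.
#' @return object of class `control_stats`: list with `plate_id`,
#'   `n_controls_used`, `control_median_lum`, `control_sd_viability`
#'   (sample s.d., n-1 denominator).
#' @export
control_summary <- function(read, layout,
                            control_subset = c("inner", "all", "listed"),
                            wells = NULL) {
  stopifnot(inherits(read, "plate_read"), inherits(layout, "plate_layout"))
  control_subset <- match.arg(control_subset)
  w <- layout$wells
  ctrl <- w[w$kind == "control", , drop = FALSE]
  ctrl <- switch(control_subset,
    inner = ctrl[!ctrl$outer, , drop = FALSE],
    all = ctrl,
    listed = {
      if (is.null(wells)) stop("control_subset='listed' requires `wells`")
      ctrl[paste(ctrl$row, ctrl$col) %in% paste(wells$row, wells$col), , drop = FALSE]
    })
  if (nrow(ctrl) < 2L)
    stop("need at least 2 control wells in subset '", control_subset,
         "'; found ", nrow(ctrl))
  lum <- read$luminescence
  idx <- match(paste(ctrl$row, ctrl$col), paste(lum$row, lum$col))
  vals <- lum$luminescence[idx]
  med <- stats::median(vals)
  if (med == 0) stop("control median luminescence is 0; cannot normalize")
  structure(list(plate_id = read$plate_id,
                 n_controls_used = nrow(ctrl),
                 control_median_lum = med,
                 control_sd_viability = stats::sd(vals / med)),
            class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat("control_stats for plate '", x$plate_id, "': n=", x$n_controls_used,
      ", median luminescence=", format(x$control_median_lum),
      ", s.d.(viability)=", format(round(x$control_sd_viability, 4)), "\n", sep = "")
  invisible(x)
}

#' Gate a plate on control variability
#'
#' A plate fails quality control when the standard deviation of its
#' solvent-control viabilities exceeds the threshold (strictly greater
#' than); such plates carry too much technical noise and are excluded from
#' downstream response matrices.
#'
#' @param stats a [control_summary()] result.
#' @param threshold s.d. cutoff; default 0.3.
#' @return `"pass"` or `"fail"`.
#' @export
qc_gate <- function(stats, threshold = 0.3) {
  stopifnot(inherits(stats, "control_stats"))
  if (stats$control_sd_viability > threshold) "fail" else "pass"
}

#' Normalize raw luminescence to relative viability
#'
#' Every drug (and combination) well is divided by the median luminescence
#' of the plate's solvent controls, by default restricted to controls off
#' the outer boundary ring. Viability is dimensionless, 1 = untreated
#' baseline; values above 1 are retained (no capping).
#'
#' @param read a [plate_read()].
#' @param layout the matching [plate_layout()].
#' @param control_subset passed to [control_summary()]; default `"inner"`.
#' @param qc_threshold control-s.d. QC cutoff recorded in the result
#'   (see [qc_gate()]).
#' @return object of class `viability_table`: list with `sample_id`,
#'   `plate_id`, `entries` (data.frame `drug_id`, `conc_index`,
#'   `conc_value`, `viability`), `combo_entries` (data.frame `drug_a`,
#'   `conc_a`, `drug_b`, `conc_b`, `viability`), `qc_status`, and the
#'   `control_stats` used.
#' @export
normalize_viability <- function(read, layout, control_subset = "inner",
                                qc_threshold = 0.3) {
  stopifnot(inherits(read, "plate_read"), inherits(layout, "plate_layout"))
  cs <- control_summary(read, layout, control_subset = control_subset)
  w <- layout$wells
  lum <- read$luminescence
  idx <- match(paste(w$row, w$col), paste(lum$row, lum$col))
  v <- lum$luminescence[idx] / cs$control_median_lum

  single <- w$kind == "drug" & !w$is_combination
  entries <- data.frame(drug_id = w$drug_id[single],
                        conc_index = w$conc_index[single],
                        conc_value = w$conc_value[single],
                        viability = v[single],
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$drug_id, entries$conc_index), ]
  rownames(entries) <- NULL

  combo <- w$kind == "drug" & w$is_combination
  combo_entries <- data.frame(drug_a = w$drug_id[combo],
                              conc_a = w$conc_index[combo],
                              drug_b = w$partner_drug_id[combo],
                              conc_b = w$partner_conc_index[combo],
                              viability = v[combo],
                              stringsAsFactors = FALSE)
  rownames(combo_entries) <- NULL

  structure(list(sample_id = read$sample_id,
                 plate_id = read$plate_id,
                 entries = entries,
                 combo_entries = combo_entries,
                 qc_status = qc_gate(cs, qc_threshold),
                 control_stats = cs),
            class = "viability_table")
}

#' @export
print.viability_table <- function(x, ...) {
  cat("viability_table: sample '", x$sample_id, "', plate '", x$plate_id,
      "'\n  ", length(unique(x$entries$drug_id)), " drugs, ",
      nrow(x$combo_entries), " combination wells, QC: ", x$qc_status,
      "\n", sep = "")
  invisible(x)
}

#' Average technical replicates of one sample
#'
#' Replicate viability tables of the same participant sample are combined
#' by the arithmetic mean per drug and concentration; keys present in only
#' a subset of replicates pass through as the mean over the tables that
#' contain them.
#'
#' @param tables list of [normalize_viability()] results sharing one
#'   `sample_id`.
#' @return a single `viability_table`. The merged table's `qc_status` is
#'   `"pass"` if any replicate passed (failed replicates should be dropped
#'   before averaging); `plate_id` concatenates the replicate plates.
#' @export
average_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "viability_table")))
  sids <- unique(vapply(tables, `[[`, character(1), "sample_id"))
  if (length(sids) != 1L)
    stop("replicates belong to different samples: ", paste(sids, collapse = ", "))
  if (length(tables) == 1L) return(tables[[1]])

  ent <- do.call(rbind, lapply(tables, `[[`, "entries"))
  key <- paste(ent$drug_id, ent$conc_index, sep = "\r")
  agg <- stats::aggregate(ent$viability, by = list(key = key), FUN = mean)
  first <- ent[!duplicated(key), c("drug_id", "conc_index", "conc_value")]
  first$key <- key[!duplicated(key)]
  m <- merge(first, agg, by = "key")
  entries <- data.frame(drug_id = m$drug_id, conc_index = m$conc_index,
                        conc_value = m$conc_value, viability = m$x,
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$drug_id, entries$conc_index), ]
  rownames(entries) <- NULL

  cmb <- do.call(rbind, lapply(tables, `[[`, "combo_entries"))
  combo_entries <- cmb[0, , drop = FALSE]
  if (nrow(cmb)) {
    ckey <- paste(cmb$drug_a, cmb$conc_a, cmb$drug_b, cmb$conc_b, sep = "\r")
    cagg <- stats::aggregate(cmb$viability, by = list(key = ckey), FUN = mean)
    cfirst <- cmb[!duplicated(ckey), c("drug_a", "conc_a", "drug_b", "conc_b")]
    cfirst$key <- ckey[!duplicated(ckey)]
    cm <- merge(cfirst, cagg, by = "key")
    combo_entries <- data.frame(drug_a = cm$drug_a, conc_a = cm$conc_a,
                                drug_b = cm$drug_b, conc_b = cm$conc_b,
                                viability = cm$x, stringsAsFactors = FALSE)
  }
  rownames(combo_entries) <- NULL

  qc <- vapply(tables, `[[`, character(1), "qc_status")
  structure(list(sample_id = sids,
                 plate_id = paste(vapply(tables, `[[`, character(1), "plate_id"),
                                  collapse = "+"),
                 entries = entries,
                 combo_entries = combo_entries,
                 qc_status = if (any(qc == "pass")) "pass" else qc[1],
                 control_stats = tables[[1]]$control_stats),
            class = "viability_table")
}

#' Write a viability table as long-format TSV
#'
#' Columns: `sample_id`, `drug_id`, `conc_index`, `viability`, `qc_status`;
#' combination wells are written with `drug_id` of the form `"A+B"` and the
#' two concentration indices in `conc_index`/`conc_index_b`.
#'
#' @param table a `viability_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_viability_table <- function(table, path) {
  stopifnot(inherits(table, "viability_table"))
  e <- table$entries
  out <- data.frame(sample_id = table$sample_id, drug_id = e$drug_id,
                    conc_index = e$conc_index, conc_index_b = NA_integer_,
                    viability = e$viability, qc_status = table$qc_status)
  if (nrow(table$combo_entries)) {
    cb <- table$combo_entries
    out <- rbind(out, data.frame(
      sample_id = table$sample_id,
      drug_id = paste0(cb$drug_a, "+", cb$drug_b),
      conc_index = cb$conc_a, conc_index_b = cb$conc_b,
      viability = cb$viability, qc_status = table$qc_status))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
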