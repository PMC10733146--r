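#' Plate layout for a 384-well drug screen
#'
#' A plate layout maps every well of a microtiter plate to its role:
#' a drug at one of the panel's concentration indices, a DMSO solvent
#' control, a two-drug combination well, or empty. The screening design
#' modelled here uses 16 rows x 24 columns (384 wells), one well per drug
#' and concentration, and solvent controls distributed over the plate.
#'
#' @param wells data.frame with columns `row`, `col`, `kind`
#'   (one of `"drug"`, `"control"`, `"empty"`), `drug_id`, `conc_index`,
#'   `conc_value`, and optionally `partner_drug_id`, `partner_conc_index`
#'   for combination wells. Missing optional columns are filled with `NA`.
#' @param plate_id character scalar identifying the physical plate.
#' @param panel one of `"lymphoid"`, `"myeloid"`, `"validation"`.
#' @param n_rows,n_cols plate dimensions; default 16 x 24 (384-well).
#' @param n_concentrations number of concentrations per drug (default 5).
#'
#' @return An object of class `plate_layout`: a list with elements
#'   `plate_id`, `panel`, `wells` (validated data.frame), `drug_set`,
#'   `n_rows`, `n_cols`, `n_concentrations`. Control wells carry a logical
#'   `outer` column flagging the outermost well ring (row 1, row
#'   `n_rows`, col 1, col `n_cols`).
#' @export
plate_layout <- function(wells, plate_id = "plate1",
                         panel = c("lymphoid", "myeloid", "validation"),
                         n_rows = 16L, n_cols = 24L, n_concentrations = 5L) {
  panel <- match.arg(panel)
  stopifnot(is.data.frame(wells))
  req <- c("row", "col", "kind")
  miss <- setdiff(req, names(wells))
  if (length(miss))
    stop("layout is missing required columns: ", paste(miss, collapse = ", "))
  opt <- c("drug_id", "conc_index", "conc_value",
           "partner_drug_id", "partner_conc_index")
  for (cc in setdiff(opt, names(wells))) wells[[cc]] <- NA
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  wells$kind <- as.character(wells$kind)
  wells$drug_id <- as.character(wells$drug_id)
  wells$conc_index <- as.integer(wells$conc_index)
  wells$conc_value <- as.numeric(wells$conc_value)
  wells$partner_drug_id <- as.character(wells$partner_drug_id)
  wells$partner_conc_index <- as.integer(wells$partner_conc_index)

  bad_kind <- setdiff(unique(wells$kind), c("drug", "control", "empty"))
  if (length(bad_kind))
    stop("unknown well kind: ", paste(bad_kind, collapse = ", "))
  if (any(wells$row < 1L | wells$row > n_rows | wells$col < 1L | wells$col > n_cols))
    stop("well coordinates outside the ", n_rows, "x", n_cols, " plate")
  key <- paste(wells$row, wells$col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("duplicate well coordinates: ", paste(unique(dup), collapse = "; "))
  }

  drg <- wells[wells$kind == "drug", , drop = FALSE]
  if (any(is.na(drg$drug_id)))
    stop("drug wells without drug_id at rows ",
         paste(which(wells$kind == "drug" & is.na(wells$drug_id)), collapse = ", "))
  if (any(is.na(drg$conc_index)))
    stop("drug wells without conc_index")
  if (any(!is.na(drg$conc_index) & (drg$conc_index < 1L | drg$conc_index > n_concentrations)))
    stop("conc_index outside 1..", n_concentrations)
  if (any(!is.na(wells$drug_id[wells$kind == "control"])))
    stop("control wells must not carry a drug_id")

  wells$is_combination <- wells$kind == "drug" & !is.na(wells$partner_drug_id)

  ## each single-agent drug must appear at every concentration index exactly once
  single <- drg[!(!is.na(drg$partner_drug_id)), , drop = FALSE]
  if (nrow(single)) {
    for (d in unique(single$drug_id)) {
      ci <- sort(single$conc_index[single$drug_id == d])
      if (!identical(ci, seq_len(n_concentrations))) {
        missing_idx <- setdiff(seq_len(n_concentrations), ci)
        stop("drug '", d, "' does not cover all ", n_concentrations,
             " concentration indices exactly once (missing/duplicated: ",
             paste(if (length(missing_idx)) missing_idx else "duplicates",
                   collapse = ", "), ")")
      }
      cv <- single$conc_value[single$drug_id == d][order(single$conc_index[single$drug_id == d])]
      if (!any(is.na(cv)) && any(diff(cv) <= 0))
        stop("drug '", d, "' concentrations must be strictly increasing with conc_index")
    }
  }

  out <- outer_ring(n_rows, n_cols)
  wells$outer <- paste(wells$row, wells$col) %in% paste(out$row, out$col)

  structure(list(
    plate_id = plate_id,
    panel = panel,
    wells = wells,
    drug_set = sort(unique(drg$drug_id)),
    n_rows = as.integer(n_rows),
    n_cols = as.integer(n_cols),
    n_concentrations = as.integer(n_concentrations)
  ), class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  w <- x$wells
  cat("plate_layout '", x$plate_id, "' (", x$panel, " panel), ",
      x$n_rows, "x", x$n_cols, " wells\n", sep = "")
  cat("  drugs: ", length(x$drug_set), " (", x$n_concentrations,
      " concentrations each); combination wells: ", sum(w$is_combination), "\n", sep = "")
  cat("  controls: ", sum(w$kind == "control"),
      " (", sum(w$kind == "control" & !w$outer), " inner); empty: ",
      sum(w$kind == "empty"), "\n", sep = "")
  invisible(x)
}

## coordinates of the outermost well ring
outer_ring <- function(n_rows, n_cols) {
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  g[g$row == 1L | g$row == n_rows | g$col == 1L | g$col == n_cols, ]
}

#' Wells on the outer boundary of a plate
#'
#' Returns the coordinates of the outermost ring of wells (row 1, last row,
#' column 1, last column). Solvent controls in this ring are excluded from
#' viability normalization because they are the wells most affected by
#' evaporation/edge artefacts.
#'
#' @param layout a [plate_layout()].
#' @return data.frame with columns `row`, `col`; for a 16 x 24 plate,
#'   84 wells.
#' @export
outer_boundary_wells <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  out <- outer_ring(layout$n_rows, layout$n_cols)
  rownames(out) <- NULL
  out
}

#' Read a plate layout from a delimited text file
#'
#' The file must have a header with columns `row`, `col`, `kind`
#' (`drug`/`control`/`empty`) and, where applicable, `drug_id`,
#' `conc_index`, `conc_value_molar` (or `conc_value`), `partner_drug_id`,
#' `partner_conc_index`. Tab- and comma-separated files are both accepted.
#'
#' @param path file path.
#' @inheritParams plate_layout
#' @return a validated [plate_layout()].
#' @export
load_plate_layout <- function(path, plate_id = NULL,
                              panel = c("lymphoid", "myeloid", "validation"),
                              n_rows = 16L, n_cols = 24L, n_concentrations = 5L) {
  tab <- read_delimited(path)
  if (!is.null(tab$conc_value_molar) && is.null(tab$conc_value))
    tab$conc_value <- tab$conc_value_molar
  if (is.null(plate_id)) {
    plate_id <- if (!is.null(tab$plate_id)) as.character(tab$plate_id[1]) else
      sub("\\.[^.]*$", "", basename(path))
  }
  if (!is.null(tab$panel)) panel <- as.character(tab$panel[1])
  plate_layout(tab, plate_id = plate_id, panel = panel, n_rows = n_rows,
               n_cols = n_cols, n_concentrations = n_concentrations)
}

#' Write a plate layout back to TSV
#'
#' Inverse of [load_plate_layout()]; round-trips the well table.
#'
#' @param layout a [plate_layout()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$wells
  out <- data.frame(plate_id = layout$plate_id, panel = layout$panel,
                    row = w$row, col = w$col, kind = w$kind,
                    drug_id = w$drug_id, conc_index = w$conc_index,
                    conc_value_molar = w$conc_value,
                    partner_drug_id = w$partner_drug_id,
                    partner_conc_index = w$partner_conc_index)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Raw luminescence readings for one plate of one sample
#'
#' @param luminescence data.frame with columns `row`, `col`, `luminescence`.
#' @param layout the [plate_layout()] the readings belong to.
#' @param sample_id participant sample identifier.
#' @return object of class `plate_read`: list with `plate_id`, `sample_id`
#'   and the validated readings.
#' @export
plate_read <- function(luminescence, layout, sample_id) {
  stopifnot(inherits(layout, "plate_layout"), is.data.frame(luminescence))
  req <- c("row", "col", "luminescence")
  miss <- setdiff(req, names(luminescence))
  if (length(miss))
    stop("read table is missing columns: ", paste(miss, collapse = ", "))
  lum <- luminescence
  lum$row <- as.integer(lum$row); lum$col <- as.integer(lum$col)
  lum$luminescence <- as.numeric(lum$luminescence)
  if (any(is.na(lum$luminescence)))
    stop("non-numeric or missing luminescence values")
  if (any(lum$luminescence < 0)) {
    i <- which(lum$luminescence < 0)[1]
    stop("negative luminescence at well (", lum$row[i], ",", lum$col[i], ")")
  }
  key <- paste(lum$row, lum$col)
  if (anyDuplicated(key))
    stop("duplicate readings for wells: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  w <- layout$wells
  need <- w[w$kind != "empty", c("row", "col")]
  missing_wells <- !(paste(need$row, need$col) %in% key)
  if (any(missing_wells)) {
    m <- need[missing_wells, , drop = FALSE][1, ]
    stop("missing reading (", m$row, ",", m$col, ")",
         if (sum(missing_wells) > 1) paste0(" and ", sum(missing_wells) - 1, " more"))
  }
  structure(list(plate_id = layout$plate_id, sample_id = sample_id,
                 luminescence = lum[, req]),
            class = "plate_read")
}

#' Read raw plate luminescence from a delimited text file
#'
#' Expects header columns `plate_id`, `sample_id`, `row`, `col`,
#' `luminescence`. All non-empty wells of the layout must be covered.
#'
#' @param path file path.
#' @param layout the matching [plate_layout()].
#' @return a `plate_read` object (see [plate_read()]).
#' @export
load_plate_reads <- function(path, layout) {
  tab <- read_delimited(path)
  sid <- if (!is.null(tab$sample_id)) as.character(tab$sample_id[1]) else "sample"
  plate_read(tab, layout, sample_id = sid)
}

## minimal delimiter-sniffing reader for TSV/CSV with header
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), quote = "\"", comment.char = "")
}
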