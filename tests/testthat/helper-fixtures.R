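# in-code fixtures shared across the test files

# small layout: a 16x24 plate carrying `n_drugs` drugs at 5 concentrations
# plus `n_inner_ctrl` inner and `n_outer_ctrl` boundary controls
toy_layout <- function(n_drugs = 3, n_inner_ctrl = 4, n_outer_ctrl = 2,
                       plate_id = "toy") {
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  drg <- expand.grid(conc_index = 1:5, drug_id = drugs,
                     stringsAsFactors = FALSE)
  inner <- expand.grid(row = c(4L, 8L), col = c(6L, 12L, 18L))
  inner <- inner[seq_len(n_inner_ctrl), , drop = FALSE]
  outer <- data.frame(row = rep(1L, n_outer_ctrl),
                      col = seq_len(n_outer_ctrl))
  free <- expand.grid(row = 2:15, col = 2:23)
  free <- free[!(paste(free$row, free$col) %in% paste(inner$row, inner$col)), ]
  free <- free[seq_len(nrow(drg)), ]
  wells <- data.frame(
    row = c(inner$row, outer$row, free$row),
    col = c(inner$col, outer$col, free$col),
    kind = c(rep("control", n_inner_ctrl + n_outer_ctrl),
             rep("drug", nrow(drg))),
    drug_id = c(rep(NA, n_inner_ctrl + n_outer_ctrl), drg$drug_id),
    conc_index = c(rep(NA, n_inner_ctrl + n_outer_ctrl), drg$conc_index),
    conc_value = c(rep(NA, n_inner_ctrl + n_outer_ctrl),
                   10^(drg$conc_index - 3)))
  plate_layout(wells, plate_id = plate_id)
}

# a read where every control is `ctrl_lum` and every drug well is
# `ctrl_lum * viability[drug, conc]`
toy_read <- function(layout, viability = 0.5, ctrl_lum = 1000,
                     sample_id = "S1") {
  w <- layout$wells
  lum <- ifelse(w$kind == "control", ctrl_lum, ctrl_lum * viability)
  plate_read(data.frame(row = w$row, col = w$col, luminescence = lum)[w$kind != "empty", ],
             layout, sample_id = sample_id)
}

# viability_table built directly from a named list of length-5 numeric
# vectors (low -> high concentration)
toy_vtable <- function(sample_id, drugs, qc_status = "pass") {
  entries <- do.call(rbind, lapply(names(drugs), function(d)
    data.frame(drug_id = d, conc_index = 1:5, conc_value = 10^(1:5 - 3),
               viability = drugs[[d]])))
  structure(list(sample_id = sample_id, plate_id = "toy",
                 entries = entries,
                 combo_entries = data.frame(drug_a = character(0),
                                            conc_a = integer(0),
                                            drug_b = character(0),
                                            conc_b = integer(0),
                                            viability = numeric(0)),
                 qc_status = qc_status, control_stats = NULL),
            class = "viability_table")
}

# textbook step-up BH oracle (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# all-pairs AUROC oracle
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive maximally-selected log-rank oracle via survival::survdiff
maxstat_oracle <- function(marker, time, event, range = c(0.1, 0.9)) {
  u <- sort(unique(marker))
  cand <- u[vapply(u, function(m) {
    pr <- mean(marker <= m); pr >= range[1] && pr <= range[2]
  }, logical(1))]
  stats <- vapply(cand, function(m) {
    g <- factor(marker <= m, levels = c(FALSE, TRUE))
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    sqrt(sd$chisq)
  }, numeric(1))
  best <- which(stats == max(stats, na.rm = TRUE))[1]
  list(cutpoint = cand[best], statistic = stats[best])
}
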