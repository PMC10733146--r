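#' Configuration for the synthetic screening-study generator
#'
#' Bundles every knob of the simulated study: plate design, noise model
#' and the cohort-level links between a latent chemosensitivity, the
#' binary in vivo response and event-free survival. Defaults mirror the
#' screening design being modelled: 384-well plates with 63 drugs at
#' 5 concentrations plus 64 DMSO controls (16 of them off the outer
#' ring), multiplicative log-normal well noise with sigma = 0.08 (the
#' typical control s.d. of a good plate), and a chemotherapy cohort of
#' 43 participants (around 5 stable disease; response vs progression for
#' the rest via a logistic link targeting 5 progressors among 38) with
#' 15 chemotherapeutic drugs of which 5 truly drive outcome.
#'
#' @param seed master seed; every draw of the generator derives from it.
#' @param n_samples cohort size (default 43).
#' @param n_drugs panel size (default 63).
#' @param n_concentrations concentrations per drug (default 5).
#' @param class_sizes named integer vector of drug-class sizes; must sum
#'   to `n_drugs`. The class named `"chemotherapeutic"` hosts the planted
#'   effects.
#' @param n_effect_drugs number of chemotherapeutics with true effects on
#'   response and survival (default 5).
#' @param sigma multiplicative log-normal well noise s.d. (default 0.08).
#' @param edge_effect additive luminescence shift on outer-ring wells,
#'   as a fraction of baseline (default 0).
#' @param baseline_lum luminescence of an untreated well (default 30000).
#' @param auc_mean_range range of per-drug mean AUC levels (default
#'   `c(0.4, 0.9)`).
#' @param class_loading loading of the shared per-class latent factor on
#'   AUC (default 0.05); creates the within-class drug-drug correlation
#'   blocks seen in real screens.
#' @param effect_loading loading of the latent chemosensitivity factor on
#'   the effect drugs' AUCs (default 0.14). The same latent quantity
#'   drives the in vivo response and EFS links, so each effect drug is a
#'   strong, mutually correlated readout of the chemosensitivity the
#'   clinic observes.
#' @param auc_idio_sd idiosyncratic per-drug AUC s.d. (default 0.03).
#' @param gamma_effect log odds ratio of progression per 10% viability
#'   increase, for each effect drug (default 0.7).
#' @param pd_target expected number of progressors among non-SD samples
#'   (default 5); fixes the logistic intercept.
#' @param sd_fraction fraction of the cohort labelled stable disease
#'   (default 5/43); SD samples are excluded from R-vs-PD fitting but
#'   keep survival records.
#' @param beta_effect log hazard ratio per 10% viability increase for
#'   each effect drug (default 0.3).
#' @param baseline_hazard daily baseline event hazard (default
#'   `log(2)/365`: median EFS of one year at the AUC average).
#' @param censoring_rate target fraction censored (default 0.3).
#' @return list of class `sim_config`, including the derived drug `panel`
#'   (data.frame `drug_id`, `class`, `conc_base`) and `effect_drugs`.
#' @export
sim_config <- function(seed = 1L, n_samples = 43L, n_drugs = 63L,
                       n_concentrations = 5L,
                       class_sizes = c(chemotherapeutic = 15L,
                                       BTK_inhibitor = 5L,
                                       BCL2_inhibitor = 5L,
                                       kinase_inhibitor = 10L,
                                       HDAC_inhibitor = 5L,
                                       proteasome_inhibitor = 5L,
                                       mTOR_inhibitor = 5L,
                                       CDK_inhibitor = 5L,
                                       HSP_inhibitor = 4L,
                                       other = 4L),
                       n_effect_drugs = 5L,
                       sigma = 0.08, edge_effect = 0,
                       baseline_lum = 30000,
                       auc_mean_range = c(0.4, 0.9),
                       class_loading = 0.05, effect_loading = 0.14,
                       auc_idio_sd = 0.03,
                       gamma_effect = 0.7, pd_target = 5L,
                       sd_fraction = 5 / 43,
                       beta_effect = 0.3,
                       baseline_hazard = log(2) / 365,
                       censoring_rate = 0.3) {
  stopifnot(sigma >= 0, censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0, sum(class_sizes) == n_drugs,
            n_effect_drugs <= class_sizes[["chemotherapeutic"]])
  cls <- rep(names(class_sizes), class_sizes)
  ids <- unlist(lapply(names(class_sizes), function(cn)
    sprintf("%s_%02d", cn, seq_len(class_sizes[[cn]]))))
  ## per-drug constants are part of the design: drawn from a seed stream
  ## separate from the sampling streams so the panel is stable
  rs <- local({ set.seed(seed + 1000L)
                list(mu = stats::runif(n_drugs, auc_mean_range[1], auc_mean_range[2]),
                     conc_base = 10^stats::runif(n_drugs, -3, -1)) })
  panel <- data.frame(drug_id = ids, class = cls,
                      auc_mean = rs$mu, conc_base = rs$conc_base,
                      stringsAsFactors = FALSE)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_drugs = as.integer(n_drugs),
                 n_concentrations = as.integer(n_concentrations),
                 panel = panel,
                 effect_drugs = ids[cls == "chemotherapeutic"][seq_len(n_effect_drugs)],
                 sigma = sigma, edge_effect = edge_effect,
                 baseline_lum = baseline_lum,
                 class_loading = class_loading,
                 effect_loading = effect_loading,
                 auc_idio_sd = auc_idio_sd,
                 gamma_effect = gamma_effect, pd_target = pd_target,
                 sd_fraction = sd_fraction, beta_effect = beta_effect,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate),
            class = "sim_config")
}

#' Concentration grid of a panel drug
#'
#' Five ten-fold dilution steps from the drug's base concentration.
#'
#' @param config a [sim_config()].
#' @param drug_id drug identifier from the panel.
#' @return increasing numeric vector of length `n_concentrations` (molar).
#' @export
drug_concentrations <- function(config, drug_id) {
  i <- match(drug_id, config$panel$drug_id)
  if (is.na(i)) stop("unknown drug: ", drug_id)
  config$panel$conc_base[i] * 10^(seq_len(config$n_concentrations) - 1L)
}

## map a target AUC (on the rank axis) to a monotone-decreasing viability
## curve whose normalized trapezoidal AUC equals the target exactly.
## Reference shape: logistic in rank with AUC exactly 0.5.
auc_to_viabilities <- function(a, n = 5L) {
  i <- seq_len(n)
  s <- 1 / (1 + exp(1.5 * (i - (n + 1) / 2))) # symmetric: AUC(s) = 0.5
  if (a <= 0.5) 2 * a * s
  else if (a <= 1) (2 * a - 1) + (2 - 2 * a) * s
  else s + (a - 0.5)
}

#' Build the standard simulated 384-well plate layout
#'
#' 63 drugs x 5 concentrations (315 wells), 64 DMSO controls of which 16
#' sit off the outer boundary ring (the normalization controls) and 48 on
#' it, remaining wells empty.
#'
#' @param config a [sim_config()].
#' @param plate_id,panel passed through to [plate_layout()].
#' @return a [plate_layout()].
#' @export
make_study_layout <- function(config, plate_id = "sim_plate",
                              panel = "myeloid") {
  n_rows <- 16L; n_cols <- 24L
  inner_ctrl <- expand.grid(row = c(3L, 7L, 10L, 14L), col = c(4L, 10L, 15L, 21L))
  ring <- outer_ring(n_rows, n_cols)
  ring <- ring[order(ring$row, ring$col), ]
  outer_ctrl <- ring[round(seq(1, nrow(ring), length.out = 48L)), ]
  ctrl <- rbind(inner_ctrl, outer_ctrl[, c("row", "col")])

  all_wells <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  all_wells <- all_wells[order(all_wells$row, all_wells$col), ]
  ckey <- paste(ctrl$row, ctrl$col)
  free <- all_wells[!(paste(all_wells$row, all_wells$col) %in% ckey), ]

  drg <- expand.grid(conc_index = seq_len(config$n_concentrations),
                     drug_id = config$panel$drug_id,
                     stringsAsFactors = FALSE)
  drg <- drg[order(drg$drug_id, drg$conc_index), ]
  stopifnot(nrow(drg) <= nrow(free))
  conc <- mapply(function(d, i) drug_concentrations(config, d)[i],
                 drg$drug_id, drg$conc_index)

  wells <- data.frame(row = c(ctrl$row, free$row),
                      col = c(ctrl$col, free$col),
                      kind = c(rep("control", nrow(ctrl)),
                               rep("drug", nrow(drg)),
                               rep("empty", nrow(free) - nrow(drg))),
                      drug_id = c(rep(NA, nrow(ctrl)), drg$drug_id,
                                  rep(NA, nrow(free) - nrow(drg))),
                      conc_index = c(rep(NA, nrow(ctrl)), drg$conc_index,
                                     rep(NA, nrow(free) - nrow(drg))),
                      conc_value = c(rep(NA, nrow(ctrl)), conc,
                                     rep(NA, nrow(free) - nrow(drg))),
                      stringsAsFactors = FALSE)
  plate_layout(wells, plate_id = plate_id, panel = panel,
               n_concentrations = config$n_concentrations)
}

#' Simulate one screened plate with known ground truth
#'
#' Drug-well luminescence is `baseline * v_true * exp(eps)` with
#' `eps ~ Normal(0, sigma^2)`; control wells have true viability 1. An
#' optional additive edge effect perturbs all outer-ring wells, which is
#' exactly the artefact that normalizing against inner controls protects
#' against.
#'
#' @param config a [sim_config()].
#' @param sample_id sample identifier for the read.
#' @param auc_true optional named vector of true AUC values per panel
#'   drug; drawn from the latent model when omitted.
#' @param layout optional pre-built layout (defaults to
#'   [make_study_layout()]).
#' @return list with `layout`, `read` (a `plate_read`), and `truth`
#'   (data.frame `drug_id`, `conc_index`, `viability_true`).
#' @export
simulate_plate <- function(config, sample_id = "S001", auc_true = NULL,
                           layout = NULL) {
  if (is.null(layout)) layout <- make_study_layout(config)
  if (is.null(auc_true)) {
    auc_true <- draw_auc_matrix(config, 1L)[1, ]
  }
  w <- layout$wells
  v_true <- numeric(nrow(w))
  v_true[w$kind == "control"] <- 1
  vtab <- list()
  for (d in unique(stats::na.omit(w$drug_id))) {
    vd <- auc_to_viabilities(auc_true[[d]], config$n_concentrations)
    idx <- which(w$kind == "drug" & w$drug_id == d)
    v_true[idx] <- vd[w$conc_index[idx]]
    vtab[[d]] <- data.frame(drug_id = d,
                            conc_index = seq_len(config$n_concentrations),
                            viability_true = vd, stringsAsFactors = FALSE)
  }
  lum <- rep(NA_real_, nrow(w))
  nonempty <- w$kind != "empty"
  eps <- stats::rnorm(sum(nonempty), 0, config$sigma)
  lum[nonempty] <- config$baseline_lum * v_true[nonempty] * exp(eps)
  if (config$edge_effect != 0)
    lum[nonempty & w$outer] <- lum[nonempty & w$outer] +
      config$edge_effect * config$baseline_lum
  lum <- pmax(lum, 0)
  read <- plate_read(data.frame(row = w$row[nonempty], col = w$col[nonempty],
                                luminescence = lum[nonempty]),
                     layout, sample_id = sample_id)
  truth <- do.call(rbind, vtab); rownames(truth) <- NULL
  list(layout = layout, read = read, truth = truth)
}

## latent-factor AUC model: one shared Gaussian factor per drug class
## plus, for the effect drugs, a shared latent chemosensitivity factor
## that later drives the clinical outcomes; idiosyncratic noise on top,
## truncated to a plausible viability range
draw_auc_matrix <- function(config, n) {
  p <- config$panel
  classes <- unique(p$class)
  Z <- matrix(stats::rnorm(n * length(classes)), n, length(classes),
              dimnames = list(NULL, classes))
  L <- stats::rnorm(n) # latent chemosensitivity (higher = more resistant)
  E <- matrix(stats::rnorm(n * nrow(p), 0, config$auc_idio_sd), n, nrow(p))
  eff <- as.numeric(p$drug_id %in% config$effect_drugs)
  ## effect drugs load on the chemosensitivity latent in place of their
  ## class factor: their within-class correlation is carried by the
  ## latent itself, and the remaining class drugs stay outcome-independent
  A <- matrix(rep(p$auc_mean, each = n), n, nrow(p)) +
    config$class_loading * Z[, p$class, drop = FALSE] %*% diag(1 - eff) +
    config$effect_loading * (L %o% eff) + E
  A <- pmin(pmax(A, 0.05), 1.15)
  dimnames(A) <- list(sprintf("S%03d", seq_len(n)), p$drug_id)
  attr(A, "latent_chemosensitivity") <- L
  A
}

#' Simulate a clinical cohort with linked ex vivo and in vivo outcomes
#'
#' Draws per-sample true AUC profiles from a class-structured latent
#' factor model, then generates (i) the binary in vivo response through a
#' logistic link in which higher viability (resistance) of the effect
#' drugs raises the probability of progressive disease, (ii) event-free
#' survival times from an exponential proportional-hazards model on the
#' same effect drugs, with independent uniform censoring calibrated to
#' the target censoring rate, and (iii) optionally the raw screened
#' plates consistent with those AUC profiles.
#'
#' @param config a [sim_config()].
#' @param plates logical: also simulate one raw plate per sample
#'   (default `FALSE`; plate simulation dominates run time).
#' @return list with `auc_true` (samples x drugs matrix), `clinical`
#'   (data.frame `sample_id`, `response` in R/SD/PD, `infiltration`),
#'   `survival` (data.frame `sample_id`, `time`, `event`), `plates`
#'   (list of [simulate_plate()] results or `NULL`), `panel`,
#'   `effect_drugs`, and the `config`.
#' @export
simulate_cohort <- function(config, plates = FALSE) {
  set.seed(config$seed)
  n <- config$n_samples
  A <- draw_auc_matrix(config, n)
  eff <- config$effect_drugs

  ## in vivo response: logistic link on effect-drug viabilities (per 10%)
  lin_gamma <- rowSums(A[, eff, drop = FALSE]) * config$gamma_effect / 0.10
  n_sd <- round(config$sd_fraction * n)
  ## intercept calibrated so the EXPECTED progressor count among non-SD
  ## samples equals pd_target (solved on the realized linear predictors);
  ## tiny cohorts cap the target so at least one responder remains
  pd_target <- min(config$pd_target, max(n - n_sd - 1L, 1L))
  target_total <- pd_target * n / max(n - n_sd, 1L)
  gamma0 <- stats::uniroot(function(g0)
    sum(stats::plogis(g0 + lin_gamma)) - target_total,
    interval = range(-lin_gamma) + c(-50, 50))$root
  p_pd <- stats::plogis(gamma0 + lin_gamma)
  ## condition on the observed class sizes: exactly pd_target progressors
  ## among the non-SD samples, drawn with probability proportional to the
  ## logistic-link probabilities (case count fixed to the design regime)
  response <- rep("R", n)
  response[sample.int(n, n_sd)] <- "SD"
  non_sd <- which(response != "SD")
  pd_idx <- sample(non_sd, pd_target, prob = p_pd[non_sd])
  response[pd_idx] <- "PD"

  ## EFS: exponential PH on centered effect-drug viabilities (per 10%)
  lin_beta <- (rowSums(A[, eff, drop = FALSE]) -
                 mean(rowSums(A[, eff, drop = FALSE]))) * config$beta_effect / 0.10
  rate <- config$baseline_hazard * exp(lin_beta)
  t_event <- stats::rexp(n, rate)
  if (config$censoring_rate > 0) {
    target <- config$censoring_rate
    pcens <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax)) - target
    cmax <- tryCatch(stats::uniroot(pcens, c(1e-3, 1e7))$root,
                     error = function(e) stop("infeasible censoring target"))
    cens <- stats::runif(n, 0, cmax)
  } else cens <- rep(Inf, n)
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)

  clinical <- data.frame(sample_id = rownames(A), response = response,
                         infiltration = stats::runif(n, 52, 99),
                         stringsAsFactors = FALSE)
  surv <- data.frame(sample_id = rownames(A), time = time, event = event,
                     stringsAsFactors = FALSE)

  plate_list <- NULL
  if (plates) {
    layout <- make_study_layout(config)
    plate_list <- lapply(seq_len(n), function(i)
      simulate_plate(config, sample_id = rownames(A)[i],
                     auc_true = A[i, ], layout = layout))
    names(plate_list) <- rownames(A)
  }
  list(auc_true = A, clinical = clinical, survival = surv,
       plates = plate_list, panel = config$panel,
       effect_drugs = eff, config = config)
}
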