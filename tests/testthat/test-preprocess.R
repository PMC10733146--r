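test_that("control summary computes median and viability s.d.", {
  lay <- toy_layout(n_inner_ctrl = 4, n_outer_ctrl = 2)
  rd <- toy_read(lay, ctrl_lum = 1000)
  cs <- control_summary(rd, lay, "inner")
  expect_equal(cs$n_controls_used, 4)
  expect_equal(cs$control_median_lum, 1000)
  expect_equal(cs$control_sd_viability, 0)

  # hand-computed: controls {900, 1000, 1100} -> s.d. of {0.9, 1.0, 1.1} = 0.1
  lay3 <- toy_layout(n_inner_ctrl = 3, n_outer_ctrl = 0)
  rd3 <- toy_read(lay3, ctrl_lum = 1000)
  lum <- rd3$luminescence
  ctrl_idx <- which(paste(lum$row, lum$col) %in%
                      with(lay3$wells[lay3$wells$kind == "control", ],
                           paste(row, col)))
  lum$luminescence[ctrl_idx] <- c(900, 1000, 1100)
  cs3 <- control_summary(plate_read(lum, lay3, "S1"), lay3, "inner")
  expect_equal(cs3$control_median_lum, 1000)
  expect_equal(cs3$control_sd_viability, sd(c(0.9, 1.0, 1.1)))
  expect_equal(cs3$control_sd_viability, 0.1)
})

test_that("inner subset excludes boundary controls; degenerate inputs error", {
  lay <- toy_layout(n_inner_ctrl = 4, n_outer_ctrl = 2)
  rd <- toy_read(lay, ctrl_lum = 1000)
  # corrupt the two boundary controls: inner summary must ignore them
  lum <- rd$luminescence
  bnd <- which(paste(lum$row, lum$col) %in% c("1 1", "1 2"))
  lum$luminescence[bnd] <- 1e6
  cs_in <- control_summary(plate_read(lum, lay, "S1"), lay, "inner")
  cs_all <- control_summary(plate_read(lum, lay, "S1"), lay, "all")
  expect_equal(cs_in$control_median_lum, 1000)
  expect_gt(cs_all$control_sd_viability, cs_in$control_sd_viability)

  lay1 <- toy_layout(n_inner_ctrl = 1, n_outer_ctrl = 0)
  expect_error(control_summary(toy_read(lay1), lay1, "inner"),
               "at least 2 control")
  rd0 <- toy_read(lay, ctrl_lum = 1000)
  lum0 <- rd0$luminescence
  ctrl <- with(lay$wells[lay$wells$kind == "control" & !lay$wells$outer, ],
               paste(row, col))
  lum0$luminescence[paste(lum0$row, lum0$col) %in% ctrl] <- 0
  expect_error(control_summary(plate_read(lum0, lay, "S1"), lay, "inner"),
               "median luminescence is 0")
})

test_that("viability is luminescence over inner-control median", {
  lay <- toy_layout()
  rd <- toy_read(lay, viability = 0.4, ctrl_lum = 1000)
  vt <- normalize_viability(rd, lay)
  expect_true(all(abs(vt$entries$viability - 0.4) < 1e-12))

  # drug well equal to the control median -> 1; zero -> 0
  rd1 <- toy_read(lay, viability = 1, ctrl_lum = 777)
  expect_true(all(normalize_viability(rd1, lay)$entries$viability == 1))
  rd0 <- toy_read(lay, viability = 0, ctrl_lum = 777)
  expect_true(all(normalize_viability(rd0, lay)$entries$viability == 0))
})

test_that("normalization is invariant to plate-wide scaling", {
  lay <- toy_layout()
  set.seed(11)
  base <- toy_read(lay)
  lum <- base$luminescence
  lum$luminescence <- runif(nrow(lum), 200, 2000)
  v0 <- normalize_viability(plate_read(lum, lay, "S1"), lay)
  for (k in c(0.25, 3, 17)) {
    lk <- lum; lk$luminescence <- lk$luminescence * k
    vk <- normalize_viability(plate_read(lk, lay, "S1"), lay)
    expect_equal(vk$entries$viability, v0$entries$viability, tolerance = 1e-12)
  }
})

test_that("QC gate fails strictly above the control-s.d. threshold", {
  mk <- function(sd_v) structure(list(plate_id = "p", n_controls_used = 16,
                                      control_median_lum = 1000,
                                      control_sd_viability = sd_v),
                                 class = "control_stats")
  expect_equal(qc_gate(mk(0.08)), "pass")
  expect_equal(qc_gate(mk(0.30)), "pass") # boundary is strict >
  expect_equal(qc_gate(mk(0.31)), "fail")
  # monotone: failing s.d. stays failing for any higher value
  sds <- sort(runif(20, 0, 0.6))
  states <- vapply(sds, function(s) qc_gate(mk(s)), character(1))
  expect_true(all(diff(states == "fail") >= 0))
})

test_that("technical replicates average per drug and concentration", {
  t1 <- toy_vtable("S1", list(drugA = rep(0.4, 5)))
  t2 <- toy_vtable("S1", list(drugA = rep(0.6, 5)))
  avg <- average_replicates(list(t1, t2))
  expect_true(all(avg$entries$viability == 0.5))

  expect_identical(average_replicates(list(t1)), t1)

  t3 <- toy_vtable("S1", list(drugA = rep(0.2, 5)))
  t4 <- toy_vtable("S1", list(drugA = rep(0.3, 5)))
  t5 <- toy_vtable("S1", list(drugA = rep(0.7, 5)))
  expect_true(all(abs(average_replicates(list(t3, t4, t5))$entries$viability - 0.4) < 1e-12))

  # keys present in only one replicate pass through
  t6 <- toy_vtable("S1", list(drugA = rep(0.4, 5), drugB = rep(0.9, 5)))
  avg2 <- average_replicates(list(t1, t6))
  eB <- avg2$entries[avg2$entries$drug_id == "drugB", ]
  expect_true(all(eB$viability == 0.9))

  expect_error(average_replicates(list(t1, toy_vtable("S2", list(drugA = rep(1, 5))))),
               "different samples")
})
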