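# ASBMR histomorphometry and growth-plate morphometry.

make_rec <- function(dl_mm = 2, sl_mm = 0, oc_mm = 1.2, ost_mm = 0.5,
                     er_mm = 2.5, b_pm_mm = 10, widths = c(2, 4, 6),
                     inter = rep(4, 10), interval = 2, n_oc = 5) {
  plain <- b_pm_mm - dl_mm - sl_mm - oc_mm - ost_mm - er_mm
  seg <- data.frame(
    segment_id = 1:6,
    length_um = c(dl_mm, sl_mm, oc_mm, ost_mm, er_mm, plain) * 1000,
    flag = c("double_label", "single_label", "osteoclast", "osteoid",
             "eroded", "plain"),
    width_um = c(NA, NA, NA, mean(widths), NA, NA),
    interlabel_um = NA
  )
  # osteoid widths as separate osteoid rows carrying zero length
  wrows <- seg[rep(4, length(widths)), ]
  if (length(widths)) { wrows$length_um <- 0; wrows$width_um <- widths }
  irows <- seg[rep(1, length(inter)), ]
  if (length(inter)) { irows$length_um <- 0; irows$interlabel_um <- inter }
  seg$width_um[4] <- NA
  all <- rbind(seg, wrows, irows)
  all$segment_id <- seq_len(nrow(all))
  histomorph_record(all, label_interval_days = interval,
                    n_osteoclasts = n_oc)
}

test_that("worked definitional example: MS, MAR, BFR", {
  rec <- make_rec(dl_mm = 2, sl_mm = 0, inter = rep(4, 10), interval = 2)
  dyn <- dynamic_formation(rec)
  expect_equal(dyn$MS_percent, 20)
  expect_equal(dyn$MAR_um_day, 2)
  expect_equal(dyn$BFR_um_day, 0.4)
  # single labels get half weight
  rec2 <- make_rec(dl_mm = 0, sl_mm = 2)
  expect_equal(dynamic_formation(rec2)$MS_percent, 10)
  # pure-double mode ignores single labels
  expect_equal(dynamic_formation(rec2, pure_double = TRUE)$MS_percent, 0)
})

test_that("BFR identity holds on randomized records", {
  set.seed(7)
  for (i in 1:50) {
    rec <- make_rec(dl_mm = runif(1, 0, 3), sl_mm = runif(1, 0, 1),
                    inter = runif(20, 1, 6), interval = runif(1, 1, 3))
    dyn <- dynamic_formation(rec)
    expect_identical(dyn$BFR_um_day, (dyn$MS_percent / 100) * dyn$MAR_um_day)
  }
})

test_that("no double labels: MAR undefined-flagged, BFR omitted", {
  rec <- make_rec(inter = numeric(0))
  dyn <- dynamic_formation(rec)
  expect_true(dyn$mar_undefined)
  expect_true(is.na(dyn$MAR_um_day))
  expect_true(is.na(dyn$BFR_um_day))
})

test_that("osteoclast, osteoid and erosion parameters are definitional", {
  rec <- make_rec(oc_mm = 1.2, n_oc = 5, b_pm_mm = 10)
  oc <- osteoclast_params(rec)
  expect_equal(oc$Oc.N_per_B.Pm, 0.5)
  expect_equal(oc$Oc.S_per_B.Pm, 12)
  os <- osteoid_params(rec)
  expect_equal(os$OS_per_B.Pm, 5)
  expect_equal(os$O.Th_um, 4)
  expect_equal(resorption_fraction(rec), 25)
  # 0 and 100% erosion limits
  seg0 <- data.frame(segment_id = 1, length_um = 10000, flag = "plain")
  expect_equal(resorption_fraction(histomorph_record(seg0)), 0)
  segF <- data.frame(segment_id = 1, length_um = 10000, flag = "eroded")
  expect_equal(resorption_fraction(histomorph_record(segF)), 100)
  # negative widths rejected
  segW <- data.frame(segment_id = 1:2, length_um = c(500, 9500),
                     flag = c("osteoid", "plain"), width_um = c(-1, NA),
                     interlabel_um = NA)
  expect_error(histomorph_record(segW), "width")
})

test_that("percentages live in [0,100] and rescale-invariance holds", {
  set.seed(3)
  for (i in 1:20) {
    rec <- make_rec(dl_mm = runif(1, 0, 2), sl_mm = runif(1, 0, 1),
                    oc_mm = runif(1, 0, 2), ost_mm = runif(1, 0, 2),
                    er_mm = runif(1, 0, 2))
    vals <- c(osteoclast_params(rec)$Oc.S_per_B.Pm,
              dynamic_formation(rec)$MS_percent,
              osteoid_params(rec)$OS_per_B.Pm,
              resorption_fraction(rec))
    expect_true(all(vals >= 0 & vals <= 100))
  }
  # um <-> mm rescale of every trace length leaves percentages unchanged
  cfg <- histomorph_config(jitter = 0.1)
  tabs <- gen_histomorph_tables(cfg, seed = 5)
  rec1 <- histomorph_record(tabs$segments, tabs$label_interval_days)
  segs2 <- tabs$segments
  segs2$length_um <- segs2$length_um * 1000
  rec2 <- histomorph_record(segs2, tabs$label_interval_days)
  expect_equal(osteoclast_params(rec2)$Oc.S_per_B.Pm,
               osteoclast_params(rec1)$Oc.S_per_B.Pm, tolerance = 1e-12)
  expect_equal(dynamic_formation(rec2)$MS_percent,
               dynamic_formation(rec1)$MS_percent, tolerance = 1e-12)
})

test_that("growth-plate morphometry averages four locations", {
  gp <- structure(list(
    boundaries = data.frame(x_location = 1:4, y_top = 0,
                            y_rz_pz = 50, y_pz_hz = 150, y_bottom = 200),
    cell_counts = c(RZ = 10, PZ = 20, HZ = 10),
    counting_region_um = 200), class = "growth_plate_raw")
  res <- growth_plate_heights(gp)
  expect_equal(unname(res$heights_um), c(50, 100, 50, 200))
  expect_equal(unname(res$fractions_percent), c(25, 50, 25))
  expect_equal(sum(res$fractions_percent), 100, tolerance = 1e-9)
  expect_equal(unname(res$cell_fractions_percent), c(25, 50, 25))
  # one zone with locations 40/60/50/50 -> mean 50
  gp2 <- gp
  gp2$boundaries$y_rz_pz <- c(40, 60, 50, 50)
  expect_equal(unname(growth_plate_heights(gp2)$heights_um["RZ"]), 50)
  # missing location rejected
  gp3 <- gp
  gp3$boundaries <- gp3$boundaries[1:3, ]
  expect_error(growth_plate_heights(gp3), "4 x-locations")
})

test_that("jittered sections recover heights without bias", {
  errs <- vapply(1:100, function(s) {
    tabs <- gen_histomorph_tables(histomorph_config(jitter = 0.08),
                                  seed = s)
    res <- growth_plate_heights(tabs$growth_plate)
    unname(res$heights_um["PZ"]) - 100
  }, numeric(1))
  expect_lt(abs(mean(errs)) / 100, 0.01)
})

test_that("section replicates average and keep the BFR identity", {
  recs <- list(make_rec(dl_mm = 2, inter = rep(4, 5)),
               make_rec(dl_mm = 1, inter = rep(2, 5)))
  avg <- average_sections(recs)
  expect_equal(avg$dynamic$MS_percent, mean(c(20, 10)))
  expect_identical(avg$dynamic$BFR_um_day,
                   (avg$dynamic$MS_percent / 100) * avg$dynamic$MAR_um_day)
})
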