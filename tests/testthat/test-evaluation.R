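test_that("arrival windows start same-day before noon JST, next day after", {
  # FT 12 from the 30 April evening run arrives 07:00 JST on 1 May
  a <- arrival_instant(as.Date("2021-05-01"), 12)
  expect_equal(jst_hour(a), 7)
  expect_equal(arrival_window_start(a), as.Date("2021-05-01"))
  # 16 May row, FT 20: 15:00 JST -> window starts 17 May
  b <- arrival_instant(as.Date("2021-05-16"), 20)
  expect_equal(arrival_window_start(b), as.Date("2021-05-17"))
  # 28 May row, FT 23: 18:00 JST -> 29 May
  c_ <- arrival_instant(as.Date("2021-05-28"), 23)
  expect_equal(arrival_window_start(c_), as.Date("2021-05-29"))
})

test_that("positive-day classification reproduces the published Koshi rows", {
  ko <- koshi_inputs()
  classify_row <- function(date, L) {
    row <- ko$pred[ko$pred$date == as.Date(date), ]
    ws <- arrival_window_start(arrival_instant(row$date, row$ft_h))
    classify_positive_day(ws, ko$catch, L)
  }
  # 1 May: hit at both windows (catches 34, 38 on 2-3 May)
  expect_equal(classify_row("2021-05-01", 3), "hit")
  expect_equal(classify_row("2021-05-01", 5), "hit")
  # 14 May (FT 32, arrival 03:00 JST 15 May): 3-day fail, 5-day hit
  expect_equal(classify_row("2021-05-14", 3), "fail")
  expect_equal(classify_row("2021-05-14", 5), "hit")
  # 26 May: fail at both
  expect_equal(classify_row("2021-05-26", 3), "fail")
  expect_equal(classify_row("2021-05-26", 5), "fail")
  # a window with no catch coverage at all is unevaluable
  expect_equal(classify_positive_day(as.Date("2021-07-01"), ko$catch, 3),
               "unevaluable")
})

test_that("negative-day classification applies the exclusion guard", {
  ko <- koshi_inputs()
  pos_dates <- ko$pred$date[ko$pred$predicted]
  # 31 May: outside every 3-day positive span (28 May covers 28-30),
  # catch of 1 recorded -> evaluated fail
  expect_equal(
    classify_negative_day(as.Date("2021-05-31"), pos_dates, ko$catch, 3),
    "fail")
  # ... but inside the 28 May 5-day span -> excluded
  expect_equal(
    classify_negative_day(as.Date("2021-05-31"), pos_dates, ko$catch, 5),
    "excluded")
  # 2 May sits in the 1 May positive span
  expect_equal(
    classify_negative_day(as.Date("2021-05-02"), pos_dates, ko$catch, 3),
    "excluded")
  # catch-free covered day with no nearby positive row: negative hit
  expect_equal(
    classify_negative_day(as.Date("2021-05-30"),
                          as.Date("2021-05-10"), ko$catch, 3),
    "hit")
  # a day with no catch coverage at all cannot be verified catch-free
  expect_equal(
    classify_negative_day(as.Date("2021-05-31"),
                          as.Date("2021-05-10"), ko$catch[-31, ], 3),
    "unevaluated")
})

test_that("interval collections credit hits on the collection date and
          certify zero intervals catch-free", {
  catches <- tibble::tibble(
    site = "X",
    collection_date = as.Date(c("2021-05-12", "2021-05-17")),
    count = c(0L, 7L), interval_days = c(5L, 5L))
  # window 13-15 May overlaps the positive interval but not its
  # collection date: fail
  expect_equal(classify_positive_day(as.Date("2021-05-13"), catches, 3),
               "fail")
  # window 13-17 May contains the 17 May collection date: hit
  expect_equal(classify_positive_day(as.Date("2021-05-13"), catches, 5),
               "hit")
  # zero interval certifies 8-12 May catch-free
  expect_equal(classify_positive_day(as.Date("2021-05-08"), catches, 3),
               "fail")
  # negative day inside the positive interval contradicts catch-free
  expect_equal(classify_negative_day(as.Date("2021-05-14"),
                                     as.Date("2020-01-01"), catches, 3),
               "fail")
  expect_equal(classify_negative_day(as.Date("2021-05-09"),
                                     as.Date("2020-01-01"), catches, 3),
               "hit")
})

test_that("full Koshi evaluation reproduces every published mark and both
          hitting ratios", {
  ko <- koshi_inputs()
  ev <- evaluate_predictions(ko$pred, ko$catch)
  got <- eval_marks(ev)
  cmp <- dplyr::left_join(ko$marks, got, by = c("site", "date"))
  expect_identical(cmp$eval_3, cmp$mark_3day)
  expect_identical(cmp$eval_5, cmp$mark_5day)
  r <- ev$ratios
  expect_equal(r$hits[r$window == 3], 14)
  expect_equal(r$evaluated[r$window == 3], 18)
  expect_equal(r$ratio[r$window == 3], 0.78)
  expect_equal(r$hits[r$window == 5], 16)
  expect_equal(r$evaluated[r$window == 5], 17)
  expect_equal(r$ratio[r$window == 5], 0.94)
})

test_that("Isahaya evaluation reproduces the published marks and ratios", {
  isa <- isahaya_inputs()
  ev <- evaluate_predictions(isa$pred, isa$catch,
                             period = as.Date(c("2021-05-01",
                                                "2021-05-31")))
  got <- eval_marks(ev)
  cmp <- dplyr::left_join(isa$marks, got, by = c("site", "date"))
  expect_identical(cmp$eval_3, cmp$mark_3day)
  expect_identical(cmp$eval_5, cmp$mark_5day)
  r <- ev$ratios
  expect_equal(r$ratio[r$window == 3], 0.44)   # 8 / 18
  expect_equal(r$ratio[r$window == 5], 0.59)   # 10 / 17
})

test_that("widening the window never demotes a positive hit and the day
          partition is complete", {
  for (inputs in list(koshi_inputs(), isahaya_inputs())) {
    ev <- evaluate_predictions(inputs$pred, inputs$catch,
                               period = as.Date(c("2021-05-01",
                                                  "2021-05-31")))
    d3 <- ev$days[ev$days$window == 3 & ev$days$case == "positive", ]
    d5 <- ev$days[ev$days$window == 5 & ev$days$case == "positive", ]
    m <- dplyr::left_join(d3, d5, by = c("site", "date"))
    expect_false(any(m$category.x == "hit" & m$category.y == "fail"))
    # every calendar day classified exactly once per window
    for (L in c(3, 5)) {
      sub <- ev$days[ev$days$window == L, ]
      expect_equal(nrow(sub), 31)
      expect_setequal(as.character(sub$date),
                      as.character(seq(as.Date("2021-05-01"),
                                       as.Date("2021-05-31"), "day")))
    }
  }
})

test_that("hitting ratios round half-up and aggregate to the published
          summary", {
  expect_equal(site_hitting_ratio(rep("hit", 4)), 1)
  expect_equal(site_hitting_ratio(c(rep("hit", 14), rep("fail", 4))), 0.78)
  expect_error(site_hitting_ratio(c("excluded")), "no evaluated")
  expect_equal(round_half_up(0.765, 2), 0.77)  # half-up, not half-even
  expect_equal(round_half_up(0.875, 2), 0.88)

  rm_ <- read_csv_marks(mothwind_example("ratio_matrix.csv"))
  agg <- aggregate_ratios(rm_)
  expect_equal(agg$ratio_3day[agg$year == "2020"], 0.79)
  expect_equal(agg$ratio_5day[agg$year == "2020"], 0.87)
  expect_equal(agg$ratio_3day[agg$year == "2021"], 0.77)
  expect_equal(agg$ratio_5day[agg$year == "2021"], 0.85)
  expect_equal(agg$ratio_3day[agg$year == "total"], 0.78)
  expect_equal(agg$ratio_5day[agg$year == "total"], 0.86)
})

test_that("evaluation object supports tidy, glance and autoplot", {
  ko <- koshi_inputs()
  ev <- evaluate_predictions(ko$pred, ko$catch)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("site", "date", "window", "category", "mark") %in%
                    names(td)))
  gl <- glance(ev)
  expect_equal(nrow(gl), 2)
  expect_equal(gl$mean_ratio[gl$window == 3], 0.78)
  expect_s3_class(autoplot(ev), "ggplot")
})
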