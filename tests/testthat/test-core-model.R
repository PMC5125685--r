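test_that("running mean matches direct window averages", {
  expect_equal(running_mean(rep(5, 365), 10), rep(5, 365))
  expect_equal(running_mean(as.numeric(1:365), 10)[20], mean(11:20))
  expect_equal(running_mean(as.numeric(1:365), 10)[20], 15.5)
  # truncated start: day d averages days 1..d
  expect_equal(running_mean(as.numeric(1:365), 10)[1:9],
               vapply(1:9, function(d) mean(1:d), numeric(1)))
})

test_that("running mean agrees with the brute-force oracle", {
  set.seed(11)
  x <- random_series()
  rm10 <- running_mean(x, 10)
  oracle <- naive_running_mean(x, 10)
  days <- sample.int(365, 50)
  expect_equal(rm10[days], oracle[days])
  # other windows too
  for (w in c(1L, 3L, 30L)) {
    expect_equal(running_mean(x, w), naive_running_mean(x, w))
  }
})

test_that("running mean with window 1 is the identity and bad windows error", {
  x <- random_series()
  expect_equal(running_mean(x, 1), x)
  expect_error(running_mean(x, 0), "positive")
  expect_error(running_mean(x, -3), "positive")
})

test_that("pixel climate pools years and finds the coldest month", {
  cl <- pixel_climate(list(`2001` = rep(10, 365)))
  expect_equal(cl$t_avg, 10)
  expect_equal(cl$t_coldest_month, 10)

  jan <- rep(10, 365)
  jan[1:31] <- -3
  cl2 <- pixel_climate(list(`2001` = jan))
  expect_equal(cl2$t_coldest_month, -3)

  cl3 <- pixel_climate(list(`2001` = rep(0, 365), `2002` = rep(10, 365)))
  expect_equal(cl3$t_avg, 5)
  expect_error(pixel_climate(list()), "non-empty")
  # leap-length mismatch is rejected
  expect_error(pixel_climate(list(`2001` = rep(1, 366))), "length")
})

test_that("coldest month never exceeds the annual mean", {
  set.seed(3)
  for (i in 1:20) {
    cl <- pixel_climate(list(`2001` = random_series(),
                             `2002` = random_series()))
    expect_lte(cl$t_coldest_month, cl$t_avg)
  }
})

test_that("the adaptive threshold is linear in mean annual temperature", {
  expect_equal(tcrit(7, 0.02, 0), 7)
  expect_equal(tcrit(8, 0.02, 10), 8.2)
  expect_equal(tcrit(8, 0.272, -10), 5.28)
})

test_that("adaptive model finds the first sub-threshold day after midsummer", {
  expect_equal(predict_egs_novel(rep(5, 365), threshold = 8), 183L)
  expect_identical(predict_egs_novel(rep(5, 365), threshold = 0),
                   NA_integer_)
  # linear cooling: running mean crosses 10 degC after day 286.5
  d <- 1:365
  cooling <- 20 - 0.1 * (d - 182)
  expect_equal(predict_egs_novel(cooling, threshold = 10), 287L)
  expect_equal(naive_first_below(cooling, 10, 183, 10), 287L)
  # fractional mode interpolates the crossing: running mean of the linear
  # series equals its value at the window midpoint, 20 - 0.1 (d - 186.5)
  expect_equal(predict_egs_novel(cooling, threshold = 10, fractional = TRUE),
               286.5)
  expect_error(predict_egs_novel(rep(5, 365), 8, search_start = 0),
               "search_start")
  expect_error(predict_egs_novel(rep(5, 365), 8, search_start = 400),
               "search_start")
})

test_that("IBIS tree rule is the disjunction of its two triggers", {
  expect_equal(predict_egs_ibis_tree(rep(-1, 365), t_coldest_month = -20),
               183L)
  # warmer-than-coldest-month trigger fires even above freezing
  expect_equal(predict_egs_ibis_tree(rep(12, 365), t_coldest_month = 10),
               183L)
  expect_identical(predict_egs_ibis_tree(rep(3, 365), t_coldest_month = -20),
                   NA_integer_)
})

test_that("IBIS grass rule triggers at or below zero", {
  expect_equal(predict_egs_ibis_grass(rep(-0.5, 365)), 183L)
  expect_equal(predict_egs_ibis_grass(rep(0, 365)), 183L)  # boundary included
  expect_identical(predict_egs_ibis_grass(rep(2, 365)), NA_integer_)
})

test_that("empirical threshold is the running mean at the observed date", {
  expect_equal(observed_threshold(rep(6, 365), 250), 6)
  d <- 1:365
  cooling <- 20 - 0.1 * (d - 182)
  expect_equal(observed_threshold(cooling, 287), 9.95)
  expect_error(observed_threshold(rep(6, 365), 400), "day-of-year")
})

test_that("predicted date is monotone non-increasing in the threshold", {
  set.seed(21)
  for (i in 1:25) {
    x <- random_series()
    ths <- sort(runif(8, -5, 15))
    doys <- vapply(ths, function(th) {
      d <- predict_egs_novel(x, th)
      if (is.na(d)) Inf else as.numeric(d)
    }, numeric(1))
    expect_false(is.unsorted(rev(doys)))  # non-increasing in threshold
  }
})

test_that("adaptive model is equivariant under temperature translation", {
  set.seed(22)
  for (i in 1:100) {
    x <- random_series()
    th <- runif(1, -5, 15)
    cc <- runif(1, -20, 20)
    expect_identical(predict_egs_novel(x + cc, th + cc),
                     predict_egs_novel(x, th))
  }
})

test_that("predictions never precede the search start", {
  set.seed(23)
  for (i in 1:30) {
    x <- random_series()
    start <- sample(150:300, 1)
    d <- predict_egs_novel(x, runif(1, -5, 15), search_start = start)
    if (!is.na(d)) expect_gte(d, start)
  }
})
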