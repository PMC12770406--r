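# Synthetic measurement table: linear GA trend with Gaussian noise.
synthetic_table <- function(n, seed, intercept = 40, slope = -0.3, sd = 1) {
  set.seed(seed)
  ga <- runif(n, 16, 40)
  data.frame(
    case_id = sprintf("case%03d", seq_len(n)),
    ga_weeks = ga,
    field_strength = sample(c(0.55, 3.0), n, replace = TRUE),
    cervical_length_mm = intercept + slope * ga + rnorm(n, sd = sd)
  )
}

test_that("table validation enforces the schema", {
  tab <- synthetic_table(20, seed = 1)
  expect_silent(cervimetry:::validate_measurement_table(tab))
  bad_ga <- tab
  bad_ga$ga_weeks[1] <- 50
  expect_error(cervimetry:::validate_measurement_table(bad_ga), "16-40")
  dup <- rbind(tab, tab[1, ])
  expect_error(cervimetry:::validate_measurement_table(dup), "duplicate")
  neg <- tab
  neg$cervical_length_mm[3] <- -2
  expect_error(cervimetry:::validate_measurement_table(neg), "non-positive")
  bad_field <- tab
  bad_field$field_strength[1] <- 1.5
  expect_error(cervimetry:::validate_measurement_table(bad_field), "0.55 or 3")

  path <- file.path(withr::local_tempdir(), "tab.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  expect_equal(read_measurement_table(path)$ga_weeks, tab$ga_weeks)
})

test_that("a linear trend is recovered from noisy data", {
  tab <- synthetic_table(200, seed = 42)
  model <- fit_trend(tab, "cervical_length_mm", degree = 1)
  expect_equal(model$coefficients[2], -0.3, tolerance = 0.05 / 0.3)
  expect_equal(model$coefficients[1], 40, tolerance = 0.05)
  expect_equal(model$slope_sign, -1)
  expect_equal(model$n, 200)
})

test_that("noise-free linear data is interpolated exactly with zero-width bands", {
  tab <- synthetic_table(50, seed = 3, sd = 0)
  tab$cervical_length_mm <- 40 - 0.3 * tab$ga_weeks
  model <- fit_trend(tab, "cervical_length_mm")
  expect_equal(model$coefficients, c(40, -0.3), tolerance = 1e-8)
  expect_lt(diff(range(model$centile_offsets)), 1e-8)
})

test_that("trend fitting rejects unusable input", {
  tab <- synthetic_table(20, seed = 5)
  expect_error(fit_trend(tab, "no_such_metric"), "not found")
  expect_error(fit_trend(tab[1:5, ], "cervical_length_mm"), "at least 10")
  const <- tab
  const$ga_weeks <- 25
  expect_error(fit_trend(const, "cervical_length_mm"), "constant")
})

test_that("slope recovery is unbiased across repeated simulations", {
  slopes <- sapply(1:100, function(r) {
    tab <- synthetic_table(200, seed = 1000 + r)
    fit_trend(tab, "cervical_length_mm")$coefficients[2]
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.3)), 3 * se)
})

test_that("exported charts and centile tables are consistent", {
  tab <- synthetic_table(100, seed = 7)
  model <- fit_trend(tab, "cervical_length_mm")
  out_dir <- file.path(withr::local_tempdir(), "charts")
  files <- export_charts(list(model), tab, out_dir)
  expect_length(files$figures, 1)
  expect_length(files$csv, 1)
  expect_true(file.exists(files$figures))

  centiles <- utils::read.csv(files$csv)
  expect_named(centiles, c("ga", "p5", "p50", "p95"))
  expect_equal(diff(centiles$ga[1:2]), 0.5)
  # centile monotonicity row-wise
  expect_true(all(centiles$p5 <= centiles$p50))
  expect_true(all(centiles$p50 <= centiles$p95))
  # CSV p50 matches the model evaluation
  expect_equal(centiles$p50, evaluate_trend(model, centiles$ga, "p50"),
               tolerance = 1e-6)
})

test_that("quadratic trends can be fitted when requested", {
  set.seed(11)
  ga <- runif(150, 16, 40)
  tab <- data.frame(case_id = as.character(1:150), ga_weeks = ga,
                    canal_mm3 = 100 + 5 * ga + 0.3 * ga^2 + rnorm(150, sd = 4))
  model <- fit_trend(tab, "canal_mm3", degree = 2)
  expect_equal(model$coefficients[3], 0.3, tolerance = 0.15)
  expect_error(fit_trend(tab, "canal_mm3", degree = 3), "degree")
})
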