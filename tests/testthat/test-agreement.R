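# agreement: pairing, correlation with normality gate, Bland-Altman,
# sensitivity analysis and report rendering

test_that("pair_records inner-joins on (specimen, slide, measure)", {
  us <- toy_record("P1", "US-manual", 1:4, c(5, 6, 7, 8),
                   anterior = 4, posterior = 8)
  hi <- toy_record("P1", "histology", 1:4, c(4, 5, 6, 7),
                   anterior = 4, posterior = 12)
  pairs <- pair_records(us, hi)
  expect_equal(nrow(pairs), 4 * 4 + 2)
  expect_identical(unname(attr(pairs, "discordant")), c(0L, 0L))

  hi2 <- toy_record("P1", "histology", 5:6, c(4, 5),
                    anterior = 4, posterior = 12)
  pairs2 <- pair_records(us, hi2)
  expect_equal(nrow(pairs2), 2)
  expect_setequal(pairs2$region, c("anterior", "posterior"))
  expect_equal(unname(attr(pairs2, "discordant")["us_only"]), 16)

  dup <- rbind(us, us[1, ])
  class(dup) <- class(us)
  expect_error(pair_records(dup, hi), "duplicate")
})

test_that("perfect monotone pairs give Spearman +-1", {
  x <- c(1, 2.5, 3, 7, 11, 15)
  p1 <- data.frame(us = x, histo = x + 1)
  expect_equal(correlation(p1, "spearman")$r, 1)
  p2 <- data.frame(us = x, histo = -x)
  expect_equal(correlation(p2, "spearman")$r, -1)
  # invariance under strictly monotone transforms
  p3 <- data.frame(us = x, histo = exp(x / 5))
  expect_equal(correlation(p3, "spearman")$r, 1)
})

test_that("tied ranks reproduce the hand-computed rank-formula value", {
  x <- c(1, 2, 2, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 6)
  got <- correlation(data.frame(us = x, histo = y), "spearman")
  expect_equal(got$r, hand_spearman(x, y), tolerance = 1e-12)
  # and the t-approximation p-value follows from r and n
  tstat <- got$r * sqrt((6 - 2) / (1 - got$r^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)
})

test_that("exact permutation p agrees with cor.test's exact Spearman p", {
  x <- c(3, 1, 4, 1.5, 5, 9, 2.6)
  y <- c(2, 7, 1.8, 2.8, 1, 8, 2.9)
  got <- correlation(data.frame(us = x, histo = y), "spearman", exact = TRUE)
  want <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$r, unname(want$estimate), tolerance = 1e-12)
  expect_equal(got$p, want$p.value, tolerance = 1e-9)
})

test_that("the normality gate selects Pearson only when both sides look normal", {
  xn <- qnorm(ppoints(30)) * 2 + 10
  pn <- data.frame(us = xn, histo = xn * 0.9 + qnorm(ppoints(30))[order(xn)] * 0.1)
  expect_identical(correlation(pn)$type, "pearson")
  xs <- exp(qnorm(ppoints(30)) * 1.5)
  ps <- data.frame(us = xs, histo = xs * 0.8)
  expect_identical(correlation(ps)$type, "spearman")
  expect_error(correlation(data.frame(us = 1:2, histo = 1:2)), "n >= 3")
  cz <- correlation(data.frame(us = rep(1, 5), histo = 1:5), "spearman")
  expect_true(is.na(cz$r))
  expect_match(cz$note, "zero variance")
})

test_that("bland_altman matches hand computations and edge cases", {
  x <- c(2, 4, 9)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd, 0)
  expect_equal(unname(ba0$limits), c(0, 0))

  ba <- bland_altman(c(3, 5, 8), c(2, 3, 5))   # differences 1, 2, 3
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd, 1)
  expect_equal(unname(ba$limits), c(0.04, 3.96))
  expect_error(bland_altman(1, 2), "n >= 2")
})

test_that("swapping modality roles negates the mean difference and mirrors limits", {
  withr::with_seed(7, {
    u <- runif(25, 2, 12)
    h <- 0.8 * u + rnorm(25, sd = 0.3)
  })
  a <- bland_altman(u, h)
  b <- bland_altman(h, u)
  expect_equal(b$mean_diff, -a$mean_diff)
  expect_equal(unname(b$limits), -rev(unname(a$limits)))
  expect_equal(correlation(data.frame(us = u, histo = h), "spearman")$r,
               correlation(data.frame(us = h, histo = u), "spearman")$r)
})

make_pairs <- function() {
  withr::with_seed(42, {
    rows <- list()
    for (sp in paste0("P", 1:6)) {
      for (rg in c("TT", "caudal", "deep", "cranial")) {
        u <- runif(5, 2, 12)
        rows[[paste(sp, rg)]] <- data.frame(
          specimen = sp, slide = 1:5, region = rg, us = u,
          histo = 0.8 * u + rnorm(5, sd = 0.4))
      }
      u2 <- runif(2, 3, 10)
      rows[[paste(sp, "ends")]] <- data.frame(
        specimen = sp, slide = NA_integer_,
        region = c("anterior", "posterior"), us = u2,
        histo = 0.8 * u2 + rnorm(2, sd = 0.6))
    }
    p <- do.call(rbind, rows)
    rownames(p) <- NULL
    class(p) <- c("paired_measurements", "data.frame")
    p
  })
}

test_that("agreement_report stratifies per region with one pooled gate", {
  pairs <- make_pairs()
  rep_ <- agreement_report(pairs)
  expect_equal(nrow(rep_), 7)
  expect_identical(rep_$region[7], "all")
  expect_length(unique(na.omit(rep_$type)), 1L)
  expect_true(all(rep_$loa_lower <= rep_$mean_diff &
                    rep_$mean_diff <= rep_$loa_upper, na.rm = TRUE))
  expect_true(all(abs(rep_$r) <= 1, na.rm = TRUE))
  expect_equal(sum(rep_$n[1:6]), rep_$n[7])
  # empty region keeps its row with n = 0 and blanks
  rep2 <- agreement_report(pairs[pairs$region != "caudal", ])
  expect_equal(rep2$n[rep2$region == "caudal"], 0L)
  expect_true(is.na(rep2$r[rep2$region == "caudal"]))
})

test_that("sensitivity_exclude recomputes and keeps both reports", {
  pairs <- make_pairs()
  sa <- sensitivity_exclude(pairs, "P6")
  expect_equal(sa$base$n[sa$base$region == "all"], nrow(pairs))
  expect_equal(sa$excluded$n[sa$excluded$region == "all"],
               sum(pairs$specimen != "P6"))
  expect_identical(sa$excluded_ids, "P6")
  # excluding nothing is the identity
  none <- agreement_report(pairs, exclude = character(0))
  expect_equal(as.data.frame(none), as.data.frame(agreement_report(pairs)),
               ignore_attr = TRUE)
  expect_error(agreement_report(pairs, exclude = paste0("P", 1:6)), "all data")
  expect_error(agreement_report(pairs, exclude = "P99"), "not present")
})

test_that("render_report writes tables, markdown and one plot per row", {
  pairs <- make_pairs()
  rep_ <- agreement_report(pairs)
  d <- withr::local_tempdir()
  paths <- render_report(rep_, d)
  expect_true(file.exists(file.path(d, "report.csv")))
  expect_true(file.exists(file.path(d, "report.md")))
  pngs <- list.files(d, pattern = "^bland_altman_.*png$")
  expect_length(pngs, nrow(rep_))
  tab <- read.csv(file.path(d, "report.csv"))
  expect_equal(nrow(tab), nrow(rep_))

  # significance bolding at p < 0.05
  fake <- rep_[rep_$region %in% c("TT", "deep"), ]
  fake$region <- c("sig", "nsig")
  fake$r <- c(0.5, 0.5); fake$p <- c(0.04, 0.06); fake$n <- c(10L, 10L)
  class(fake) <- class(rep_)
  attr(fake, "pairs") <- pairs[0, ]
  d2 <- withr::local_tempdir()
  render_report(fake, d2)
  md <- readLines(file.path(d2, "report.md"))
  expect_match(md[grepl("\\| sig \\|", md)], "\\*\\*0.500\\*\\*")
  expect_false(grepl("\\*\\*", md[grepl("\\| nsig \\|", md)]))
})
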