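# Statistical comparison of the two modalities: normality gate, Pearson or
# Spearman correlation, Bland-Altman agreement with 95% limits, per-region
# stratification and exclusion sensitivity analysis. The difference
# direction is fixed throughout as US - histology (US measures larger on
# average after fixation shrinkage) and stated in every output header.

REGIONS <- c("TT", "caudal", "deep", "cranial", "anterior", "posterior")

#' Pair US and histology measurement records
#'
#' Inner join on (specimen, slide, measure). Entries present in only one
#' modality (discordant detections) are excluded from the pairs and
#' counted in the `discordant` attribute.
#'
#' @param us,histo [measurement_record()]s (single specimen or pooled).
#' @return data.frame of class `paired_measurements` with columns
#'   `specimen`, `slide`, `region`, `us`, `histo`.
#' @export
pair_records <- function(us, histo) {
  key <- function(r) paste(r$specimen, ifelse(is.na(r$slide), "spec", r$slide),
                           r$measure, sep = "|")
  ku <- key(us); kh <- key(histo)
  if (anyDuplicated(ku) || anyDuplicated(kh))
    stopf("duplicate (specimen, slide, measure) keys in a record")
  common <- intersect(ku, kh)
  iu <- match(common, ku); ih <- match(common, kh)
  pairs <- data.frame(specimen = us$specimen[iu], slide = us$slide[iu],
                      region = us$measure[iu], us = us$value_mm[iu],
                      histo = histo$value_mm[ih])
  class(pairs) <- c("paired_measurements", "data.frame")
  attr(pairs, "discordant") <- c(us_only = length(ku) - length(common),
                                 histo_only = length(kh) - length(common))
  pairs
}

#' Combine paired measurements from several specimens
#'
#' @param ... `paired_measurements` objects (or a single list of them).
#' @return pooled `paired_measurements`; discordant counts are summed.
#' @export
pool_pairs <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && !inherits(lst[[1]], "data.frame")) lst <- lst[[1]]
  disc <- Reduce(`+`, lapply(lst, function(p)
    attr(p, "discordant") %||% c(us_only = 0, histo_only = 0)))
  pooled <- do.call(rbind, lapply(lst, as.data.frame))
  class(pooled) <- c("paired_measurements", "data.frame")
  attr(pooled, "discordant") <- disc
  pooled
}

# Spearman coefficient with average ranks for ties; two-sided p via the
# t-approximation, or exact permutation enumeration for small n.
spearman_r <- function(x, y, exact = FALSE) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_, note = "zero variance"))
  r <- stats::cor(rx, ry)
  p <- if (exact && n <= 10) {
    .spearman_perm_p(rx, ry)
  } else if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, note = NA_character_)
}

#' Correlation between modalities with normality gate
#'
#' Shapiro-Wilk on both members of the pairs at alpha = 0.05 selects
#' Pearson (both normal) or Spearman (otherwise). Spearman uses average
#' ranks for ties and a two-sided t-approximation p-value; for n <= 10 an
#' exact permutation p is available.
#'
#' @param pairs a [pair_records()] result (or any data.frame with `us`,
#'   `histo`).
#' @param method `"auto"` applies the normality gate; or force
#'   `"pearson"` / `"spearman"`.
#' @param exact use exact permutation p for Spearman when n <= 10.
#' @return list with `type`, `r`, `p`, `n`, `shapiro_p` (both modalities),
#'   and `note` (e.g. zero variance, r undefined).
#' @export
correlation <- function(pairs, method = c("auto", "pearson", "spearman"),
                        exact = FALSE) {
  method <- match.arg(method)
  x <- pairs$us; y <- pairs$histo
  n <- length(x)
  if (n < 3) stopf("correlation requires n >= 3, got %d", n)
  sw <- c(us = NA_real_, histo = NA_real_)
  if (method == "auto") {
    sw <- vapply(list(us = x, histo = y), function(v) {
      if (stats::sd(v) == 0 || n < 3 || n > 5000) return(0)
      stats::shapiro.test(v)$p.value
    }, 0.0)
    method <- if (all(sw > 0.05)) "pearson" else "spearman"
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(type = method, r = NA_real_, p = NA_real_, n = n,
                shapiro_p = sw, note = "zero variance: r undefined"))
  if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson")
    list(type = "pearson", r = unname(ct$estimate), p = ct$p.value, n = n,
         shapiro_p = sw, note = NA_character_)
  } else {
    s <- spearman_r(x, y, exact = exact)
    list(type = "spearman", r = s$r, p = s$p, n = n, shapiro_p = sw,
         note = s$note)
  }
}

#' Bland-Altman agreement
#'
#' Differences are US - histology; reports the mean difference, the
#' sample standard deviation (n - 1) of the differences, and the 95%
#' limits of agreement `mean +- 1.96 * SD`.
#'
#' @param pairs a [pair_records()] result, or a numeric vector of US
#'   values (then `histo` must be given).
#' @param histo histology values when `pairs` is a numeric vector.
#' @return object of class `bland_altman`: `mean_diff`, `sd`, `limits`
#'   (lower, upper), `n`, plus the differences and pairwise means for
#'   plotting.
#' @export
bland_altman <- function(pairs, histo = NULL) {
  if (is.numeric(pairs) && !is.null(histo)) {
    us <- pairs
  } else {
    us <- pairs$us; histo <- pairs$histo
  }
  n <- length(us)
  if (n < 2) stopf("Bland-Altman requires n >= 2, got %d", n)
  d <- us - histo
  m <- (us + histo) / 2
  mean_diff <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mean_diff = mean_diff, sd = sdd,
                 limits = c(lower = mean_diff - 1.96 * sdd,
                            upper = mean_diff + 1.96 * sdd),
                 n = n, differences = d, means = m,
                 direction = "US - histology"),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> (%s) n = %d: mean %.2f mm (SD %.2f), 95%% LoA [%.2f, %.2f]\n",
              x$direction, x$n, x$mean_diff, x$sd, x$limits[1], x$limits[2]))
  invisible(x)
}

#' Per-region and pooled agreement report
#'
#' Applies the normality gate once to the pooled pairs (selecting one
#' correlation type for all regions, as the study does after finding the
#' pooled data non-normal), then computes correlation and Bland-Altman
#' agreement pooled ("all") and per region. Regions without pairs appear
#' with n = 0 and blank statistics.
#'
#' @param pairs a [pair_records()] / [pool_pairs()] result.
#' @param exclude specimen ids to drop before computing (echoed in the
#'   report).
#' @param exact exact Spearman permutation p for n <= 10.
#' @return data.frame of class `agreement_report`, one row per region plus
#'   "all": `region`, `n`, `type`, `r`, `p`, `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`. Attributes: `pairs`, `excluded`,
#'   `shapiro_p`, `discordant`.
#' @export
agreement_report <- function(pairs, exclude = NULL, exact = FALSE) {
  if (!is.null(exclude)) {
    missing_ids <- setdiff(exclude, unique(pairs$specimen))
    if (length(missing_ids))
      stopf("exclusion ids not present: %s", paste(missing_ids, collapse = ", "))
    pairs <- pairs[!pairs$specimen %in% exclude, , drop = FALSE]
    if (!nrow(pairs)) stopf("exclusion removes all data")
  }
  pooled_cor <- correlation(pairs, "auto", exact = exact)
  type <- pooled_cor$type
  row_for <- function(p, label) {
    n <- nrow(p)
    if (n == 0)
      return(data.frame(region = label, n = 0L, type = NA_character_,
                        r = NA_real_, p = NA_real_, mean_diff = NA_real_,
                        sd_diff = NA_real_, loa_lower = NA_real_,
                        loa_upper = NA_real_))
    r <- if (n >= 3) correlation(p, type, exact = exact)
    else list(r = NA_real_, p = NA_real_)
    ba <- if (n >= 2) bland_altman(p) else
      list(mean_diff = NA_real_, sd = NA_real_,
           limits = c(NA_real_, NA_real_))
    data.frame(region = label, n = n, type = if (n >= 3) type else NA_character_,
               r = r$r, p = r$p, mean_diff = ba$mean_diff, sd_diff = ba$sd,
               loa_lower = ba$limits[1], loa_upper = ba$limits[2])
  }
  rows <- lapply(REGIONS, function(rg)
    row_for(pairs[pairs$region == rg, , drop = FALSE], rg))
  rep_ <- do.call(rbind, c(rows, list(row_for(pairs, "all"))))
  rownames(rep_) <- NULL
  class(rep_) <- c("agreement_report", "data.frame")
  attr(rep_, "pairs") <- pairs
  attr(rep_, "excluded") <- exclude
  attr(rep_, "shapiro_p") <- pooled_cor$shapiro_p
  attr(rep_, "discordant") <- attr(pairs, "discordant")
  rep_
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (differences are US - histology, mm)\n")
  ex <- attr(x, "excluded")
  if (!is.null(ex)) cat("  excluded specimens:", paste(ex, collapse = ", "), "\n")
  df <- as.data.frame(x)
  df$r <- round(df$r, 3); df$p <- signif(df$p, 3)
  df$mean_diff <- round(df$mean_diff, 2)
  df$loa_lower <- round(df$loa_lower, 2); df$loa_upper <- round(df$loa_upper, 2)
  print(df[, c("region", "n", "type", "r", "p", "mean_diff",
               "loa_lower", "loa_upper")], row.names = FALSE)
  invisible(x)
}

#' Exclusion sensitivity analysis
#'
#' Recomputes the full agreement report after dropping the given
#' specimens (the study's patient-8 re-analysis) and returns both reports
#' side by side.
#'
#' @param pairs a `paired_measurements` object.
#' @param specimens specimen ids to exclude (must be present; excluding
#'   everything is an error).
#' @param exact exact Spearman permutation p for small n.
#' @return list of class `sensitivity_analysis`: `base`, `excluded`
#'   (reports) and `excluded_ids`.
#' @export
sensitivity_exclude <- function(pairs, specimens, exact = FALSE) {
  base <- agreement_report(pairs, exact = exact)
  excl <- agreement_report(pairs, exclude = specimens, exact = exact)
  structure(list(base = base, excluded = excl, excluded_ids = specimens),
            class = "sensitivity_analysis")
}

#' @export
print.sensitivity_analysis <- function(x, ...) {
  cat("=== all specimens ===\n"); print(x$base)
  cat(sprintf("=== excluding %s ===\n", paste(x$excluded_ids, collapse = ", ")))
  print(x$excluded)
  invisible(x)
}
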