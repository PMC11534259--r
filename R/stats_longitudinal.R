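#' Published cohort characteristics (lesion-level)
#'
#' The printed characteristics of the 12-patient, 14-metastasis SRS
#' cohort used as worked-example input: lesion location, GTV volume
#' (cm^3), prescribed dose (Gy), primary histology, progression during
#' follow-up, and completion of the three sodium scans.
#'
#' @return a data.frame with one row per brain metastasis.
#' @export
cohort_table1 <- function() {
  data.frame(
    patient = c(1, 1, 2, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    bm = 1:14,
    location = c("Frontal left", "Frontal left", "Frontal left",
                 "Frontal right", "Occipital right", "Occipital right",
                 "Occipital left", "Postcentral right", "Occipital right",
                 "Cerebellar right", "Frontal left", "Frontal right",
                 "Temporal left", "Occipital right"),
    gtv_cm3 = c(0.423, 0.315, 0.264, 1.456, 0.124, 1.637, 0.416, 0.411,
                0.723, 0.428, 0.197, 0.891, 1.075, 2.272),
    dose_gy = c(22, 22, 22, 22, 16, 22, 22, 22, 22, 22, 22, 22, 22, 20),
    histology = c("NSCLC", "NSCLC", "Mammary carcinoma",
                  "Mammary carcinoma", "NSCLC", "NSCLC",
                  "Malignant melanoma", "Renal cell carcinoma",
                  "Soft tissue sarcoma", "Esophageal cancer",
                  "Renal cell carcinoma", "CUP-syndrome",
                  "Mammary carcinoma", "NSCLC"),
    progressive = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    scan1 = rep(TRUE, 14),
    scan2 = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
              FALSE, TRUE, TRUE, TRUE, TRUE),
    scan3 = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
              FALSE, FALSE, TRUE, TRUE, TRUE))
}

#' Published group-mean TSC values (mM) for the stable metastases
#'
#' Reported mean tissue sodium concentrations of the gross tumour volume
#' at the three scans, used as worked-example inputs for the
#' percent-change routine.
#'
#' @return named numeric vector (`I`, `II`, `III`, in mM).
#' @export
published_gtv_means <- function() c(I = 61, II = 68, III = 58)

#' Integer percent change between two values
#'
#' `round(100 * (to - from) / from)`, the integer-precision convention
#' used in clinical result summaries.
#'
#' @param from,to numeric values (e.g. group means at two scans).
#' @return integer percent change.
#' @export
percent_change <- function(from, to) {
  stopifnot(from != 0)
  round(100 * (to - from) / from)
}

#' Kolmogorov-Smirnov normality check (Lilliefors)
#'
#' One-sample KS test against a normal with parameters estimated from
#' the sample (Lilliefors correction, via `nortest::lillie.test`). Used
#' as a gate-with-warning before the paired t-tests, not as a hard stop.
#' Samples of fewer than four values or with (near-)zero variance are
#' returned flagged degenerate with `p = NA`.
#'
#' @param values numeric vector, n >= 3.
#' @return list with `statistic`, `p`, `n`, `degenerate`, `normal`
#'   (logical at alpha = 0.05, NA when degenerate).
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("ks_normality requires at least 3 values")
  if (stats::sd(values) < 1e-12 || n < 4)
    return(list(statistic = NA_real_, p = NA_real_, n = n,
                degenerate = TRUE, normal = NA))
  t <- nortest::lillie.test(values)
  list(statistic = unname(t$statistic), p = t$p.value, n = n,
       degenerate = FALSE, normal = t$p.value > 0.05)
}

#' Paired two-sided t-test for a longitudinal comparison
#'
#' Wraps the paired Student t-test with the bookkeeping the longitudinal
#' report needs: matched pairs, mean difference `y - x`, direction arrow,
#' and the significance flag at alpha = 0.05. Identical pairs (zero
#' variance of the differences) return the exact-tie convention `p = 1`,
#' flagged.
#'
#' @param x,y matched measurement vectors (same lesions, two scans);
#'   pairs with a missing member are dropped (pairwise-available
#'   analysis).
#' @param region,pair labels carried into the record.
#' @return object of class `paired_comparison`.
#' @export
paired_t_test <- function(x, y, region = NA, pair = NA) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("paired_t_test requires at least 2 complete pairs")
  d <- y - x
  ties <- stats::sd(d) < 1e-12
  if (ties) {
    t_stat <- if (mean(d) == 0) 0 else Inf
    p <- 1
  } else {
    ht <- stats::t.test(y, x, paired = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(region = region, pair = pair, n = n,
                 mean_diff = mean(d),
                 direction = if (mean(d) > 0) "\u2191"
                             else if (mean(d) < 0) "\u2193" else "=",
                 t = t_stat, p = p, significant = is.finite(p) && p < 0.05,
                 flag_ties = ties),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("%s %s: n=%d, diff %+0.2f %s, t=%.3f, p=%.4f%s\n",
              as.character(x$region), as.character(x$pair), x$n,
              x$mean_diff, x$direction, x$t, x$p,
              if (x$significant) " *" else ""))
}

#' Pearson correlation between dose levels and shell mean TSC
#'
#' Two-sided Pearson test (t-distribution, n-2 df) between the isodose
#' levels and the corresponding shell mean concentrations of one scan.
#'
#' @param levels dose levels (Gy), >= 3 values.
#' @param shell_means mean TSC per shell (mM), matched to `levels`.
#' @param scan_id label carried into the record.
#' @return list with `scan`, `r`, `p`, `n`, `flag_degenerate`.
#' @export
dose_tsc_correlation <- function(levels, shell_means, scan_id = NA) {
  ok <- is.finite(levels) & is.finite(shell_means)
  levels <- levels[ok]; shell_means <- shell_means[ok]
  if (length(levels) < 3) stop("need >= 3 paired values for a correlation")
  if (stats::sd(levels) < 1e-12 || stats::sd(shell_means) < 1e-12)
    return(list(scan = scan_id, r = NA_real_, p = NA_real_,
                n = length(levels), flag_degenerate = TRUE))
  ct <- stats::cor.test(levels, shell_means, method = "pearson")
  list(scan = scan_id, r = unname(ct$estimate), p = ct$p.value,
       n = length(levels), flag_degenerate = FALSE)
}
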