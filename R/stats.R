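#' Paired simulated/measured comparison
#'
#' @param a simulated values (mmHg).
#' @param b measured values (mmHg).
#' @param labels optional case labels.
#' @return A `paired_comparison`.
#' @export
paired_comparison <- function(a, b, labels = NULL) {
  if (length(a) != length(b))
    stop("paired_comparison: series lengths differ")
  if (length(a) < 2L) stop("paired_comparison: need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) stop("paired_comparison: missing entries")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 labels = labels %||% as.character(seq_along(a))),
            class = "paired_comparison")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Bland-Altman agreement statistics
#'
#' Mean difference (bias) of simulated minus measured values, its sample SD
#' (n-1 denominator), a t-based 95% confidence interval for the bias, and
#' 1.96-SD limits of agreement.
#'
#' @param pc a [paired_comparison] (or two vectors via `a`, `b`).
#' @return A `bland_altman` list: `mean_diff`, `sd_diff`, `ci95_mean_diff`,
#'   `loa95`, `n`, and the per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(pc) {
  if (!inherits(pc, "paired_comparison"))
    stop("bland_altman: expected a paired_comparison")
  d <- pc$a - pc$b
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  se <- sdd / sqrt(n)
  tq <- stats::qt(0.975, df = n - 1L)
  structure(list(mean_diff = md, sd_diff = sdd,
                 ci95_mean_diff = c(md - tq * se, md + tq * se),
                 loa95 = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 n = n,
                 means = (pc$a + pc$b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
#' @method print bland_altman
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("Bland-Altman (n = %d):\n",
                     "  mean difference %.3f mmHg, SD %.3f\n",
                     "  95%% CI of mean difference [%.3f, %.3f]\n",
                     "  95%% limits of agreement  [%.3f, %.3f]\n"),
              x$n, x$mean_diff, x$sd_diff,
              x$ci95_mean_diff[1L], x$ci95_mean_diff[2L],
              x$loa95[1L], x$loa95[2L]))
  invisible(x)
}

#' Pearson correlation of a paired comparison
#'
#' @param pc a [paired_comparison] with n >= 3 and non-degenerate variance.
#' @return Sample correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(pc) {
  if (!inherits(pc, "paired_comparison"))
    stop("pearson_r: expected a paired_comparison")
  if (length(pc$a) < 3L) stop("pearson_r: need at least 3 pairs")
  if (stats::sd(pc$a) == 0 || stats::sd(pc$b) == 0)
    stop("pearson_r: zero variance in a series")
  stats::cor(pc$a, pc$b)
}

#' Join simulated and measured pressure losses
#'
#' One row per matched (CO, model) case with both values and their
#' difference; unmatched keys are reported in attributes.
#'
#' @param cfd data.frame with columns `CO_L_min`, `model`, `dP_max_mmHg`
#'   (an endpoint-report table).
#' @param mcl an `mcl_dataset` (columns `CO_L_min`, `model`, `dP_mmHg`).
#' @return Data frame with columns `CO_L_min`, `model`, `dP_cfd`, `dP_mcl`,
#'   `difference`; attribute `unmatched` lists unmatched keys.
#' @export
comparison_table <- function(cfd, mcl) {
  key <- function(df) paste(df$CO_L_min, df$model, sep = "|")
  if (anyDuplicated(key(cfd)) || anyDuplicated(key(mcl)))
    stop("comparison_table: duplicate (CO, model) keys")
  m <- merge(cfd[, c("CO_L_min", "model", "dP_max_mmHg")],
             mcl[, c("CO_L_min", "model", "dP_mmHg")],
             by = c("CO_L_min", "model"))
  out <- data.frame(CO_L_min = m$CO_L_min, model = m$model,
                    dP_cfd = m$dP_max_mmHg, dP_mcl = m$dP_mmHg,
                    difference = m$dP_max_mmHg - m$dP_mmHg,
                    stringsAsFactors = FALSE)
  out <- out[order(out$model, out$CO_L_min), , drop = FALSE]
  rownames(out) <- NULL
  un <- c(setdiff(key(cfd), key(mcl)), setdiff(key(mcl), key(cfd)))
  attr(out, "unmatched") <- un
  out
}
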