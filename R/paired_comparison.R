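#' Pair left/right circumference measurements of one element
#'
#' Collects the circumference pairs used by the bilateral tests: every
#' growth-mark level (`cgm1` ... `cgm5`) and the periosteal surface at which
#' both sides are fully traceable. The medullary and hatchling levels are
#' not growth records of the sampled bone and are excluded.
#'
#' @param left,right `element_record`s of the same individual and element.
#' @return Data frame with columns `level`, `left`, `right` (mm); zero rows
#'   when no level is mutually traceable.
#' @export
pair_measurements <- function(left, right) {
  stopifnot(inherits(left, "element_record"), inherits(right, "element_record"))
  if (left$individual != right$individual || left$element != right$element)
    stop("records are not a left/right pair of the same element")
  lev_l <- c(paste0("cgm", left$marks$index), "surface")
  val_l <- c(ifelse(left$marks$status == "fully_traceable",
                    left$marks$circumference_mm, NA_real_),
             left$surface_circumference)
  lev_r <- c(paste0("cgm", right$marks$index), "surface")
  val_r <- c(ifelse(right$marks$status == "fully_traceable",
                    right$marks$circumference_mm, NA_real_),
             right$surface_circumference)
  common <- intersect(lev_l[!is.na(val_l)], lev_r[!is.na(val_r)])
  common <- common[order(match(common, .level_order))]
  data.frame(level = common,
             left = val_l[match(common, lev_l)],
             right = val_r[match(common, lev_r)],
             stringsAsFactors = FALSE)
}

#' Paired t-test on left/right measurement pairs
#'
#' Two-tailed paired Student's t-test on the differences `left - right`.
#' Reports the absolute value of the mean signed difference (the published
#' tables are non-negative), the sample standard deviation of the
#' differences (n - 1 denominator), the p-value, and the 95% confidence
#' half-width `t_{1 - alpha/2, n-1} * sd / sqrt(n)`.
#'
#' Degenerate cases are reported with `degenerate = TRUE`: identical pairs
#' (sd = 0, mean = 0) give p = 1; constant nonzero differences give p = 0.
#'
#' @param pairs A [pair_measurements()] data frame with at least 2 rows.
#' @param alpha Significance level, default 0.05.
#' @return A one-row data frame of class `paired_comparison` with columns
#'   `n_pairs`, `mean_abs_difference`, `sd_differences`, `p_value`,
#'   `ci_half_width`, `reject`, `degenerate`.
#' @export
paired_t <- function(pairs, alpha = 0.05) {
  stopifnot(is.data.frame(pairs), alpha > 0, alpha <= 1)
  if (nrow(pairs) < 2L)
    stop("paired test requires at least 2 pairs; got ", nrow(pairs))
  d <- pairs$left - pairs$right
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1L)
  degenerate <- s == 0
  if (degenerate) {
    p <- if (m == 0) 1 else 0
  } else {
    p <- stats::t.test(pairs$left, pairs$right, paired = TRUE)$p.value
  }
  out <- data.frame(n_pairs = n, mean_abs_difference = abs(m),
                    sd_differences = s, p_value = p,
                    ci_half_width = tcrit * s / sqrt(n),
                    reject = p < alpha, degenerate = degenerate)
  class(out) <- c("paired_comparison", class(out))
  out
}

#' Bilateral paired comparison of every element of every individual
#'
#' Builds the published-table-2 analogue: for each individual and element
#' with both sides measured, pairs the mutually fully-traceable levels
#' ([pair_measurements()]) and, when at least two pairs exist, runs
#' [paired_t()]. Elements with fewer than two common levels are skipped from
#' testing (and listed in the `skipped` attribute) but their pairs remain
#' available to [left_right_regression()].
#'
#' @param x Measurement data frame.
#' @param alpha Significance level, default 0.05.
#' @return Data frame with columns `individual`, `element`, `n_pairs`,
#'   `mean_abs_difference`, `sd_differences`, `p_value`, `ci_half_width`,
#'   `reject`, `degenerate`; attribute `skipped` lists element pairs with
#'   fewer than two common levels.
#' @export
compare_elements <- function(x, alpha = 0.05) {
  recs <- element_records(x)
  key <- data.frame(
    individual = vapply(recs, `[[`, character(1L), "individual"),
    element = vapply(recs, `[[`, character(1L), "element"),
    side = vapply(recs, `[[`, character(1L), "side"),
    stringsAsFactors = FALSE
  )
  out <- list(); skipped <- character(0L)
  for (ie in unique(paste(key$individual, key$element, sep = "|"))) {
    parts <- strsplit(ie, "|", fixed = TRUE)[[1L]]
    il <- which(key$individual == parts[1L] & key$element == parts[2L] &
                  key$side == "left")
    ir <- which(key$individual == parts[1L] & key$element == parts[2L] &
                  key$side == "right")
    if (!length(il) || !length(ir)) next
    pr <- pair_measurements(recs[[il]], recs[[ir]])
    if (nrow(pr) < 2L) {
      skipped <- c(skipped, paste(parts[1L], parts[2L]))
      message("skipping ", parts[1L], " ", parts[2L], ": ",
              nrow(pr), " mutually traceable level(s)")
      next
    }
    res <- paired_t(pr, alpha = alpha)
    out[[ie]] <- cbind(individual = parts[1L], element = parts[2L], res,
                       stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$individual, out$element), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Pooled left-versus-right regression
#'
#' Ordinary least-squares regression of right-side on left-side
#' circumference over every mutually fully-traceable growth-mark and
#' surface level, pooled across all individuals and elements (including
#' elements with a single common level, which the paired tests skip). A
#' slope of 1 with intercept 0 and high R-squared indicates no appreciable
#' bilateral asymmetry.
#'
#' @param x Measurement data frame.
#' @return List of class `lr_regression` with `slope`, `intercept`,
#'   `r_squared`, `n_points`, the pooled `points` data frame, and the
#'   underlying `lm` fit.
#' @export
left_right_regression <- function(x) {
  recs <- element_records(x)
  key <- data.frame(
    individual = vapply(recs, `[[`, character(1L), "individual"),
    element = vapply(recs, `[[`, character(1L), "element"),
    side = vapply(recs, `[[`, character(1L), "side"),
    stringsAsFactors = FALSE
  )
  pts <- list()
  for (ie in unique(paste(key$individual, key$element, sep = "|"))) {
    parts <- strsplit(ie, "|", fixed = TRUE)[[1L]]
    il <- which(key$individual == parts[1L] & key$element == parts[2L] &
                  key$side == "left")
    ir <- which(key$individual == parts[1L] & key$element == parts[2L] &
                  key$side == "right")
    if (!length(il) || !length(ir)) next
    pr <- pair_measurements(recs[[il]], recs[[ir]])
    if (nrow(pr))
      pts[[ie]] <- cbind(individual = parts[1L], element = parts[2L], pr,
                         stringsAsFactors = FALSE)
  }
  pts <- do.call(rbind, pts)
  rownames(pts) <- NULL
  if (is.null(pts) || nrow(pts) < 3L)
    stop("regression requires at least 3 pooled pairs")
  if (stats::var(pts$left) < 1e-12)
    stop("degenerate regression: left-side measurements have no variance")
  fit <- stats::lm(right ~ left, data = pts)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = summary(fit)$r.squared,
    n_points = nrow(pts),
    points = pts,
    fit = fit
  ), class = "lr_regression")
}

#' @export
print.lr_regression <- function(x, ...) {
  cat(sprintf("Left/right pooled OLS: right = %.3f * left %+.3f  (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Plot the pooled left-versus-right circumferences
#'
#' @param x An [left_right_regression()] result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_left_right <- function(x, ...) {
  stopifnot(inherits(x, "lr_regression"))
  graphics::plot(x$points$left, x$points$right,
                 xlab = "left circumference (mm)",
                 ylab = "right circumference (mm)", pch = 16, ...)
  graphics::abline(x$fit, col = "red3")
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
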