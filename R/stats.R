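#' Student-t coverage multipliers
#'
#' The symmetric (two-sided) Student-t coverage multiplier `m` such that
#' `P(|T| <= m) = p` for `T ~ t(dof)`, i.e. `qt((1 + p)/2, dof)`. This is
#' the multiplier conventionally quoted in RSA precision and accuracy
#' summaries - "the 95% quantile of the t-distribution" in the RSA
#' literature refers to this central 95% limit: 2.45 with 6 degrees of
#' freedom (precision from six double-examination differences, SD about
#' zero) and 2.57 with 5 degrees of freedom (accuracy from six paired
#' differences, one d.o.f. spent on the mean).
#'
#' @param p Coverage probability in (0, 1).
#' @param dof Degrees of freedom (>= 1).
#' @return The multiplier.
#' @examples
#' round(t_quantile(0.95, 6), 2) # 2.45
#' round(t_quantile(0.95, 5), 2) # 2.57
#' @export
t_quantile <- function(p, dof) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("p must be a probability strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(dof) || length(dof) != 1L || is.na(dof) || dof < 1)
    stop("dof must be >= 1", call. = FALSE)
  qt((1 + p) / 2, df = dof)
}

migration_components <- c("dx", "dy", "dz", "rx", "ry", "rz")

component_units <- function(comp)
  ifelse(comp %in% c("dx", "dy", "dz"), "mm", "deg")

as_component_frame <- function(x) {
  if (inherits(x, "migration_result")) x <- list(x)
  if (is.list(x) && !is.data.frame(x)) x <- migrations_frame(x)
  if (!all(migration_components %in% names(x)))
    stop("expected migration results with components dx, dy, dz, rx, ry, rz",
         call. = FALSE)
  x
}

#' Precision from double examinations
#'
#' Summarises the within-position series differences of a double-examination
#' study. Each row of `double_exam_migrations` is one position's apparent
#' migration between series 1 and 2 - zero in truth - so per component the
#' precision is `multiplier * SD` of those differences, with the SD taken
#' about zero (`sqrt(sum(d^2)/n)`) so that n differences carry n degrees of
#' freedom and the multiplier is the 95% t-quantile with n d.o.f. (2.45 for
#' the six-position design). Set `about_zero = FALSE` for the conventional
#' mean-subtracted SD with n-1 d.o.f. Mean, min and max of the differences
#' are reported alongside, per component.
#'
#' @param double_exam_migrations Output of [double_exam_migrations()] (or
#'   any list/data frame of migration results whose true value is zero).
#' @param about_zero Compute the SD about zero (default) or about the mean.
#' @param conf Coverage probability for the multiplier (default 0.95).
#' @return Data frame of class `precision_summary`: one row per component
#'   with columns `component`, `unit`, `n`, `dof`, `multiplier`,
#'   `precision` (multiplier x SD), `mean`, `min`, `max`.
#' @export
precision_summary <- function(double_exam_migrations, about_zero = TRUE,
                              conf = 0.95) {
  df <- as_component_frame(double_exam_migrations)
  n <- nrow(df)
  if (n < 2L)
    stop("precision needs at least 2 double-examination differences",
         call. = FALSE)
  rows <- lapply(migration_components, function(comp) {
    d <- df[[comp]]
    if (about_zero) {
      s <- sqrt(sum(d^2) / n); dof <- n
    } else {
      s <- sd(d); dof <- n - 1L
    }
    mult <- t_quantile(conf, dof)
    data.frame(component = comp, unit = component_units(comp), n = n,
               dof = dof, multiplier = mult, precision = mult * s,
               mean = mean(d), min = min(d), max = max(d),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("precision_summary", "data.frame"))
}

#' @export
print.precision_summary <- function(x, ...) {
  cat(sprintf("Precision (%.2f x SD of double-examination differences, %d d.o.f.)\n",
              x$multiplier[1], x$dof[1]))
  print_component_table(x, "precision")
  invisible(x)
}

print_component_table <- function(x, value_col) {
  df <- data.frame(component = paste0(x$component, " (", x$unit, ")"),
                   value = sprintf("%.3f", x[[value_col]]),
                   mean = sprintf("% .3f", x$mean),
                   min = sprintf("% .3f", x$min),
                   max = sprintf("% .3f", x$max))
  names(df)[2] <- value_col
  print(df, row.names = FALSE)
}

#' Accuracy against a gold standard
#'
#' Summarises the component-wise differences `d = gold - method` between
#' matched pairwise migrations measured by the method under test and by a
#' gold-standard modality. Per component the accuracy is
#' `multiplier * RMS(d)` with `RMS = sqrt(mean(d^2))` and the multiplier
#' the 95% t-quantile with n-1 d.o.f. (2.57 for six paired differences);
#' RMS is used because the differences may be of either sign and contain
#' both systematic and random error. Rows are matched by position pair and
#' series.
#'
#' @param method_migrations,gold_migrations Data frames from
#'   [pairwise_migrations()] (columns `pair`, `series_a`, components).
#' @param conf Coverage probability (default 0.95).
#' @return Data frame of class `accuracy_summary`: per component,
#'   `accuracy` (multiplier x RMS), `mean`, `min`, `max` of d.
#' @export
accuracy_summary <- function(method_migrations, gold_migrations,
                             conf = 0.95) {
  m <- as_component_frame(method_migrations)
  g <- as_component_frame(gold_migrations)
  key <- function(df) {
    if (!is.null(df$pair)) paste(df$pair, df$series_a)
    else paste(df$position_a, df$position_b, df$series_a)
  }
  km <- key(m); kg <- key(g)
  if (nrow(m) != nrow(g) || !setequal(km, kg) || anyDuplicated(km))
    stop("method and gold migration lists do not pair up (position pairs / series mismatch)",
         call. = FALSE)
  g <- g[match(km, kg), ]
  n <- nrow(m)
  if (n < 2L) stop("accuracy needs at least 2 matched pairs", call. = FALSE)
  rows <- lapply(migration_components, function(comp) {
    d <- g[[comp]] - m[[comp]]
    rms <- sqrt(mean(d^2))
    dof <- n - 1L
    mult <- t_quantile(conf, dof)
    data.frame(component = comp, unit = component_units(comp), n = n,
               dof = dof, multiplier = mult, accuracy = mult * rms,
               rms = rms, mean = mean(d), min = min(d), max = max(d),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("accuracy_summary", "data.frame"))
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("Accuracy (%.2f x RMS of gold-minus-method differences, %d d.o.f.)\n",
              x$multiplier[1], x$dof[1]))
  print_component_table(x, "accuracy")
  invisible(x)
}

#' CT effective dose from the dose-length product
#'
#' Effective dose (mSv) as the product of the scanner-reported dose-length
#' product (DLP, mGy cm) and the body-region conversion factor k
#' (mSv per mGy cm; ~0.015 for the adult pelvis).
#'
#' @param dlp Dose-length product (mGy cm), >= 0.
#' @param k Conversion factor (mSv / (mGy cm)), >= 0.
#' @return Effective dose in mSv.
#' @examples
#' effective_dose(22, 0.015) # 0.33 mSv
#' @export
effective_dose <- function(dlp, k) {
  if (!is.numeric(dlp) || !is.numeric(k) || anyNA(dlp) || anyNA(k))
    stop("dlp and k must be numeric", call. = FALSE)
  if (any(dlp < 0) || any(k < 0))
    stop("dlp and k must be non-negative", call. = FALSE)
  dlp * k
}

#' Normality diagnostics for difference samples
#'
#' Advisory check that a sample of differences is compatible with a
#' Gaussian, as required before summarising by standard deviations:
#' histogram counts, quantile-quantile data, a Shapiro-Wilk test and a
#' robust tail heuristic (the sample SD against the slope of the
#' quartile-based Q-Q line; heavy tails inflate the ratio). Flags are
#' advisory only and never gate the computation.
#'
#' @param differences Numeric sample, n >= 3.
#' @return List of class `normality_check`: `n`, `mean`, `sd`,
#'   `shapiro_p`, `qq_slope`, `tail_ratio`, `hist` (counts + breaks),
#'   `qq` (theoretical vs sample quantiles), and logical flags
#'   `degenerate` and `departure`.
#' @export
normality_check <- function(differences) {
  d <- as.numeric(differences)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3L) stop("normality check needs n >= 3", call. = FALSE)
  s <- sd(d)
  h <- graphics::hist(d, plot = FALSE)
  qq <- list(theoretical = qnorm(stats::ppoints(n)), sample = sort(d))
  if (s == 0) {
    out <- list(n = n, mean = mean(d), sd = 0, shapiro_p = NA_real_,
                qq_slope = 0, tail_ratio = NA_real_,
                hist = list(counts = h$counts, breaks = h$breaks), qq = qq,
                degenerate = TRUE, departure = FALSE)
    return(structure(out, class = "normality_check"))
  }
  # slope of the line through the sample/theoretical quartiles (qqline)
  qs <- quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  qt_ <- qnorm(c(0.25, 0.75))
  qq_slope <- diff(qs) / diff(qt_)
  tail_ratio <- s / qq_slope
  shapiro_p <- if (n <= 5000) shapiro.test(d)$p.value else NA_real_
  departure <- (is.finite(tail_ratio) && tail_ratio > 1.5) ||
    (!is.na(shapiro_p) && shapiro_p < 0.01)
  structure(list(n = n, mean = mean(d), sd = s, shapiro_p = shapiro_p,
                 qq_slope = qq_slope, tail_ratio = tail_ratio,
                 hist = list(counts = h$counts, breaks = h$breaks), qq = qq,
                 degenerate = FALSE, departure = departure),
            class = "normality_check")
}

#' @export
print.normality_check <- function(x, ...) {
  cat(sprintf("<normality_check> n = %d, mean = %.4g, sd = %.4g\n",
              x$n, x$mean, x$sd))
  if (x$degenerate) {
    cat("  sample is constant (degenerate)\n")
  } else {
    cat(sprintf("  Shapiro-Wilk p = %.3g; sd / Q-Q slope = %.2f%s\n",
                x$shapiro_p, x$tail_ratio,
                if (x$departure) "  [departure from normality flagged]"
                else "  (no gross departure)"))
  }
  invisible(x)
}
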