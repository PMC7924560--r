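#' Intraclass correlation ICC(2,1) with confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (Shrout & Fleiss ICC(2,1)) for an n-subjects-by-k-sessions
#' rating matrix, as used for intra-observer reproducibility of repeated
#' cardiac-interval measurements. From the two-way ANOVA mean squares
#' (subjects MSR, raters/sessions MSC, error MSE):
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' The confidence interval is the standard F-based construction for this
#' form, with Satterthwaite degrees of freedom for the lower/upper bounds.
#'
#' @param ratings numeric matrix or data frame, subjects in rows, repeated
#'   sessions/raters in columns; n >= 3 subjects, k >= 2 columns, no missing
#'   values.
#' @param confidence confidence level in (0, 1); default 0.95.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `confidence`, `n`, `k`, and the mean squares `MSR`, `MSC`, `MSE`.
#' @examples
#' m <- cbind(c(9, 6, 8, 7, 10), c(9.5, 6.5, 8, 7.5, 9.5))
#' icc_2_1(m)
#' @export
icc_2_1 <- function(ratings, confidence = 0.95) {
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings)) stop("ratings must be numeric")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3L || k < 2L) stop("need at least 3 subjects and 2 sessions")
  if (anyNA(ratings) || !all(is.finite(ratings))) stop("ratings must be complete and finite")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")

  gm <- mean(ratings)
  if (sum((ratings - gm)^2) == 0) stop("degenerate ratings: zero total variance")
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, col_m, "+") + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - confidence
  if (mse == 0 && msc == 0) {
    # perfect agreement: no error or session variance, interval collapses
    ci <- c(icc, icc)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }

  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2], confidence = confidence,
         n = n, k = k, MSR = msr, MSC = msc, MSE = mse),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f, %g%% CI [%.4f, %.4f] (n = %d subjects, k = %d sessions)\n",
              x$icc, 100 * x$confidence, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Read a rating matrix from CSV
#'
#' Expects subjects in rows and repeated sessions/raters in columns, with a
#' header row naming the sessions.
#'
#' @param path CSV file path.
#' @return numeric matrix.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}
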