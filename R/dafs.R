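#' Kolmogorov-Smirnov sweep over truncation cutoffs for one sample
#'
#' Works on the log2 of the strictly positive TPM values of a sample. For a
#' grid of lower-quantile cutoffs, the values above each cutoff are fitted
#' with a single normal by maximum likelihood (sample mean and SD) and the
#' sup-norm (Kolmogorov-Smirnov) distance between their empirical CDF and
#' the fitted normal CDF is recorded. On a bimodal log-expression
#' distribution the distance peaks while the weakly-expressed mode is still
#' included and drops once the cutoff passes it; the knot fit in
#' [first_knot()] locates that drop.
#'
#' The grid starts at q0 = round(fraction of values equal to the minimum, 2)
#' and steps by 0.005 up to 0.50; quantiles use the linear-interpolation
#' ("type 7") convention.
#'
#' @param sample_tpm numeric vector of TPM values for one sample (zeros
#'   allowed; they are dropped before the log transform). At least 200
#'   strictly positive values are required.
#' @return data.frame with columns `q` (grid quantile), `cut` (cut value in
#'   log2 TPM) and `ks` (KS statistic), sorted by `cut`.
#' @export
ks_sweep <- function(sample_tpm) {
  x <- sample_tpm[sample_tpm > 0]
  if (length(x) < 200L)
    stop("insufficient expressed genes: need >= 200 positive values, got ",
         length(x))
  x <- log2(x)
  q0 <- round(mean(x == min(x)), 2L)
  qs <- seq(q0, 0.50, by = 0.005)
  out <- lapply(qs, function(q) {
    cq <- unname(stats::quantile(x, q, type = 7L))
    d <- x[x > cq]
    if (length(d) < 2L || stats::sd(d) == 0) {
      warning(sprintf("zero-variance tail at q = %.3f; skipped", q))
      return(NULL)
    }
    data.frame(q = q, cut = cq, ks = ks_statistic(d, mean(d), stats::sd(d)))
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    stop("KS sweep produced no usable grid points")
  out[order(out$cut), , drop = FALSE]
}

# Sup-norm distance between the empirical CDF of x and a N(mu, sd) CDF.
ks_statistic <- function(x, mu, sd) {
  x <- sort(x)
  n <- length(x)
  f <- stats::pnorm(x, mu, sd)
  max(pmax(seq_len(n) / n - f, f - (seq_len(n) - 1L) / n))
}

#' Locate the expression cutoff from a KS-sweep trace
#'
#' Fits a one-dimensional adaptive piecewise-linear regression of the KS
#' statistic on the cut value by forward stepwise addition of hinge-function
#' pairs (candidate knots at the observed cut values; each step adds the
#' pair that maximally reduces the residual sum of squares; stepping stops
#' when the relative RSS improvement falls below 0.005 or the model reaches
#' 21 terms). The cutoff is the smallest knot location greater than 0 (log2
#' TPM = 0, i.e. TPM = 1); with `knot_rule = "min-interior"` it is the
#' smallest knot regardless of sign. When no qualifying knot exists the
#' function falls back to the smallest cut value (no filtering) and raises
#' the fallback flag.
#'
#' @param trace data.frame from [ks_sweep()] (needs >= 10 rows).
#' @param knot_rule `"min-positive"` (default) or `"min-interior"`.
#' @return list with `cutoff` (log2 TPM), `knots` (sorted knot locations)
#'   and `fallback` (logical).
#' @export
first_knot <- function(trace, knot_rule = c("min-positive", "min-interior")) {
  knot_rule <- match.arg(knot_rule)
  if (nrow(trace) < 10L) stop("trace needs at least 10 points")
  x <- trace$cut
  y <- trace$ks
  knots <- numeric(0)
  tss <- sum((y - mean(y))^2)
  if (tss > 0) {
    # base model: intercept + linear trend, so a knot is only retained when
    # the trace genuinely bends (an exactly linear trace keeps no knots)
    basis <- cbind(1, x)
    rss <- sum(stats::lm.fit(basis, y)$residuals^2)
    candidates <- unique(x)
    repeat {
      if (rss <= tss * 1e-12) break   # already a numerically perfect fit
      if (ncol(basis) + 2L > 21L) break
      best <- NULL
      best_rss <- rss
      for (t in setdiff(candidates, knots)) {
        b <- cbind(basis, pmax(x - t, 0), pmax(t - x, 0))
        r <- tryCatch(stats::lm.fit(b, y)$residuals, error = function(e) NULL)
        if (is.null(r)) next
        cand_rss <- sum(r^2)
        if (cand_rss < best_rss) {
          best_rss <- cand_rss
          best <- t
        }
      }
      if (is.null(best) || (rss - best_rss) / rss < 0.005) break
      knots <- c(knots, best)
      basis <- cbind(basis, pmax(x - best, 0), pmax(best - x, 0))
      rss <- best_rss
    }
  }
  knots <- sort(knots)
  eligible <- if (knot_rule == "min-positive") knots[knots > 0] else knots
  if (length(eligible)) {
    list(cutoff = min(eligible), knots = knots, fallback = FALSE)
  } else {
    list(cutoff = min(x), knots = knots, fallback = TRUE)
  }
}

#' Per-sample data-adaptive expression cutoffs
#'
#' Applies [ks_sweep()] and [first_knot()] to every sample of a TPM matrix.
#'
#' @param tpm genes x samples TPM matrix.
#' @inheritParams first_knot
#' @return object of class `dafs_result`: list with `cutoffs` (data.frame
#'   `sample_id`, `cutoff` in log2 TPM, `fallback`), `traces` and `knots`
#'   (per-sample lists).
#' @export
dafs_cutoffs <- function(tpm, knot_rule = c("min-positive", "min-interior")) {
  knot_rule <- match.arg(knot_rule)
  m <- as.matrix(tpm)
  samples <- colnames(m)
  traces <- list()
  knots <- list()
  res <- lapply(samples, function(s) {
    tr <- tryCatch(ks_sweep(m[, s]), error = function(e)
      stop("sample '", s, "': ", conditionMessage(e), call. = FALSE))
    fk <- first_knot(tr, knot_rule)
    if (fk$fallback)
      warning("sample '", s,
              "': no qualifying knot; cutoff falls back to the minimum ",
              "cut value (no filtering)")
    traces[[s]] <<- tr
    knots[[s]] <<- fk$knots
    data.frame(sample_id = s, cutoff = fk$cutoff, fallback = fk$fallback,
               stringsAsFactors = FALSE)
  })
  structure(list(cutoffs = do.call(rbind, res), traces = traces,
                 knots = knots, knot_rule = knot_rule),
            class = "dafs_result")
}

#' @export
print.dafs_result <- function(x, ...) {
  cat("dafs_result: per-sample log2-TPM expression cutoffs\n")
  print(x$cutoffs, row.names = FALSE)
  invisible(x)
}
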