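# Proteome-scale nHU-MS statistics: normalization, imputation, per-protein
# testing, the hyperbolic volcano significance threshold, and conversion of
# depletion fold changes into an affinity-ranked interactome.

#' Construct an intensity table
#'
#' A protein-group x sample matrix of label-free quantification intensities
#' (the wide matrix exported by DIA search engines), together with a sample
#' sheet assigning each column to a condition (`"control"` or `"bait"`) and
#' a replicate index. Missing values are `NA`; detected values must be
#' positive.
#'
#' @param values numeric matrix, rows = protein groups (rownames required,
#'   unique), columns = samples.
#' @param condition character vector, one of `"control"`/`"bait"` per
#'   column.
#' @param replicate integer replicate index per column (defaults to 1..n
#'   within condition).
#' @return an object of class `"intensity_table"`: a list with elements
#'   `values` and `samples`.
#' @export
intensity_table <- function(values, condition, replicate = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique rownames (protein identifiers)")
  }
  condition <- match.arg(condition, c("control", "bait"), several.ok = TRUE)
  if (length(condition) != ncol(values)) {
    stop("one condition label per sample column is required")
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  if (any(values <= 0, na.rm = TRUE)) {
    stop("all detected (non-missing) intensities must be positive")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste(condition, replicate, sep = "_")
  }
  structure(
    list(
      values = values,
      samples = data.frame(
        sample = colnames(values), condition = condition,
        replicate = as.integer(replicate), stringsAsFactors = FALSE
      )
    ),
    class = "intensity_table"
  )
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(
    "intensity_table:", nrow(x$values), "protein groups x",
    ncol(x$values), "samples\n"
  )
  cat(
    " conditions:",
    paste(sprintf(
      "%s (n=%d)", unique(x$samples$condition),
      tabulate(factor(x$samples$condition))[seq_along(unique(x$samples$condition))]
    ), collapse = ", "), "\n"
  )
  cat(
    " missing:",
    sprintf("%.1f%%", 100 * mean(is.na(x$values))), "\n"
  )
  invisible(x)
}

#' Median normalization of sample columns
#'
#' Corrects minor loading differences by scaling each sample column so that
#' its median detected intensity equals a common target (the median of the
#' per-column medians, which makes the operation exactly idempotent).
#' Missing values are untouched.
#'
#' @param table an [intensity_table()].
#' @return a normalized `intensity_table`.
#' @export
normalize_medians <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  v <- table$values
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med))) {
    bad <- colnames(v)[!is.finite(med)]
    stop("column(s) with no detected values: ", paste(bad, collapse = ", "))
  }
  target <- stats::median(med)
  table$values <- sweep(v, 2, target / med, `*`)
  table
}

#' Impute missing intensities from the bottom decile
#'
#' Replaces every missing value with a random draw (with replacement) from
#' the empirical bottom 10% of all detected intensities in the entire
#' dataset, mimicking values at or below the detection limit. Detected
#' cells are untouched; the result is deterministic given the seed.
#'
#' @param table an [intensity_table()].
#' @param seed integer seed for the imputation draws.
#' @return an `intensity_table` without missing values.
#' @export
impute_missing <- function(table, seed) {
  stopifnot(inherits(table, "intensity_table"))
  v <- table$values
  detected <- v[!is.na(v)]
  if (length(detected) == 0) stop("all values missing; nothing to impute from")
  if (length(detected) < 10) stop("need at least 10 detected values")
  pool <- detected[detected <= stats::quantile(detected, 0.10)]
  miss <- which(is.na(v))
  if (length(miss) > 0) {
    v[miss] <- with_seed(
      seed,
      sample(pool, length(miss), replace = TRUE)
    )
  }
  table$values <- v
  table
}

#' Per-protein depletion test
#'
#' For every protein, the log2 fold change of the mean bait-condition
#' intensity over the mean control intensity (on the log2 scale) and the
#' two-tailed p-value of an unpaired equal-variance t-test on the log2
#' intensities. Imputation must already have been applied (no missing
#' values).
#'
#' @param table an [intensity_table()] without missing values and with at
#'   least 2 replicates per condition.
#' @return data.frame with columns `prey_id`, `log2_fc`, `p_value`, `flag`.
#'   Zero within-group variance in both groups gives `p = 1` when the means
#'   are equal and the machine-minimum p with flag `"zero-variance"`
#'   otherwise (imputation can create exact ties).
#' @export
test_depletion <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  v <- table$values
  if (anyNA(v)) stop("missing values present; run impute_missing() first")
  ctrl <- v[, table$samples$condition == "control", drop = FALSE]
  bait <- v[, table$samples$condition == "bait", drop = FALSE]
  n1 <- ncol(ctrl)
  n2 <- ncol(bait)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per condition")
  l_ctrl <- log2(ctrl)
  l_bait <- log2(bait)
  m1 <- rowMeans(l_ctrl)
  m2 <- rowMeans(l_bait)
  ss1 <- rowSums((l_ctrl - m1)^2)
  ss2 <- rowSums((l_bait - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  lfc <- m2 - m1
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  flag <- rep("ok", nrow(v))
  zv <- se == 0
  p[zv & lfc == 0] <- 1
  degenerate <- zv & lfc != 0
  p[degenerate] <- .Machine$double.xmin
  flag[degenerate] <- "zero-variance"
  data.frame(
    prey_id = rownames(v), log2_fc = lfc, p_value = p, flag = flag,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit the hyperbolic volcano significance threshold
#'
#' The volcano significance boundary
#' `y(|x|) = y0 + c / (|x| - x0)` for `|x| > x0` (infinite otherwise)
#' needs the fold-change width `x0`, defined as twice the standard
#' deviation of the fold-change distribution of all detected proteins. The
#' width is estimated by least-squares fitting a Gaussian to a histogram of
#' the log2 fold changes (Freedman-Diaconis bin widths); if the fit fails,
#' a robust sigma (scaled median absolute deviation) is used and flagged.
#'
#' @param log2_fcs numeric vector of log2 fold changes (>= 50 values).
#' @param p_floor minimal -log10(p) a significant point must reach
#'   (default 1.3, i.e. p = 0.05).
#' @param c curvature parameter (default 1, empirically fixed).
#' @return list of class `"threshold_curve"` with elements `y0`, `c`, `x0`,
#'   `sigma` and `flag` (`"gaussian-fit"` or `"mad-fallback"`).
#' @export
fit_threshold <- function(log2_fcs, p_floor = 1.3, c = 1) {
  log2_fcs <- log2_fcs[is.finite(log2_fcs)]
  if (length(log2_fcs) < 50) stop("need >= 50 finite fold-change values")
  if (stats::sd(log2_fcs) == 0) stop("degenerate (constant) fold changes")
  h <- graphics::hist(log2_fcs, breaks = "FD", plot = FALSE)
  d <- data.frame(x = h$mids, y = h$counts)
  sigma <- NA_real_
  flag <- "gaussian-fit"
  fit <- tryCatch(
    stats::nls(
      y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
      data = d,
      start = list(
        A = max(d$y), mu = stats::median(log2_fcs),
        s = stats::sd(log2_fcs)
      ),
      algorithm = "port",
      lower = c(A = 0, mu = -Inf, s = 1e-12)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    sigma <- abs(stats::coef(fit)[["s"]])
  } else {
    sigma <- stats::mad(log2_fcs)
    flag <- "mad-fallback"
    warning("Gaussian histogram fit failed; using MAD-based sigma")
  }
  structure(
    list(y0 = p_floor, c = c, x0 = 2 * sigma, sigma = sigma, flag = flag),
    class = "threshold_curve"
  )
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf(
    "hyperbolic threshold: y0 = %.3g, c = %.3g, x0 = %.4g (%s)\n",
    x$y0, x$c, x$x0, x$flag
  ))
  invisible(x)
}

#' Classify points against a hyperbolic threshold
#'
#' A point is significant iff `|log2_fc| > x0` and
#' `-log10(p) >= y0 + c / (|log2_fc| - x0)` (boundary inclusive), on the
#' requested side of the volcano. Depletion (binding) is the negative
#' fold-change side.
#'
#' @param log2_fc,p_value numeric vectors (recycled to common length).
#' @param curve a `"threshold_curve"` from [fit_threshold()] (or a list
#'   with `y0`, `c`, `x0`).
#' @param side which volcano arm(s) may be significant.
#' @return logical vector.
#' @export
is_significant <- function(log2_fc, p_value, curve,
                           side = c("depletion", "enrichment", "both")) {
  side <- match.arg(side)
  n <- max(length(log2_fc), length(p_value))
  log2_fc <- rep_len(log2_fc, n)
  p_value <- rep_len(p_value, n)
  ax <- abs(log2_fc)
  ok_side <- switch(side,
    depletion = log2_fc < 0,
    enrichment = log2_fc > 0,
    both = rep(TRUE, n)
  )
  beyond <- ax > curve$x0
  thr <- ifelse(beyond, curve$y0 + curve$c / (ax - curve$x0), Inf)
  ok_side & beyond & (-log10(p_value) >= thr)
}

#' Run the full nHU-MS quantification pipeline
#'
#' Composes the stages: median normalization, bottom-decile imputation,
#' per-protein equal-variance t-tests, hyperbolic threshold fitting,
#' significance classification on the depletion side, and conversion of
#' depletion-side fold changes into degrees of binding
#' (`theta = 1 - 2^log2_fc`) and apparent affinities via the hyperbolic
#' binding law at the supplied bait concentration. Enrichment-side proteins
#' get a negative theta and no affinity. A Benjamini-Hochberg adjusted
#' p-value column is emitted for reference only; classification uses the
#' hyperbolic curve, not an FDR cutoff.
#'
#' @param table an [intensity_table()].
#' @param C_bait bait concentration (uM unless you work in another unit
#'   consistently).
#' @param seed integer seed (drives the imputation draws).
#' @param side volcano side(s) eligible for significance (default
#'   depletion, i.e. binding).
#' @return data.frame of class `"holdup_result"` sorted by `K_app`, with
#'   columns `prey_id`, `log2_fc`, `p_value`, `neg_log10_p`, `p_adj_BH`,
#'   `theta`, `K_app`, `significant`, `flag`; attributes `threshold`
#'   (the fitted curve), `C_bait` and `seed`.
#' @export
run_nhu_pipeline <- function(table, C_bait, seed = 1L,
                             side = c("depletion", "enrichment", "both")) {
  side <- match.arg(side)
  stopifnot(inherits(table, "intensity_table"), C_bait > 0)
  table <- normalize_medians(table)
  table <- impute_missing(table, seed = seed)
  tests <- test_depletion(table)
  curve <- fit_threshold(tests$log2_fc)
  sig <- is_significant(tests$log2_fc, tests$p_value, curve, side = side)
  theta <- 1 - 2^tests$log2_fc
  K_app <- rep(Inf, nrow(tests))
  dep <- theta > 0
  if (any(dep)) {
    K_app[dep] <- kapp_from_theta(theta[dep], C_bait, clamp = TRUE)$K_app
  }
  out <- data.frame(
    prey_id = tests$prey_id,
    log2_fc = tests$log2_fc,
    p_value = tests$p_value,
    neg_log10_p = -log10(tests$p_value),
    p_adj_BH = stats::p.adjust(tests$p_value, method = "BH"),
    theta = theta,
    K_app = K_app,
    significant = sig,
    flag = tests$flag,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$K_app, out$prey_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- curve
  attr(out, "C_bait") <- C_bait
  attr(out, "seed") <- seed
  class(out) <- c("holdup_result", "data.frame")
  out
}
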