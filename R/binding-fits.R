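# Nonlinear fitting of titration holdup data (complete and partial
# binding) and of direct/competitive fluorescence polarization (FP)
# experiments.

#' Construct a titration series
#'
#' Degree-of-binding measurements at several bait concentrations, as
#' obtained by mixing control and bait-saturated resins at varying
#' proportions at constant total resin.
#'
#' @param C_bait bait concentrations (distinct, >= 0; a zero point is the
#'   control and should show theta ~ 0).
#' @param theta_mean mean degree of binding per concentration.
#' @param theta_sd replicate standard deviation (>= 0), or `NULL`.
#' @param n_replicates replicates per point (default 1).
#' @return data.frame of class `"titration_series"`.
#' @export
titration_series <- function(C_bait, theta_mean, theta_sd = NULL,
                             n_replicates = 1L) {
  stopifnot(length(C_bait) == length(theta_mean), all(C_bait >= 0))
  if (anyDuplicated(C_bait)) stop("C_bait values must be distinct")
  if (is.null(theta_sd)) theta_sd <- rep(NA_real_, length(C_bait))
  stopifnot(all(theta_sd >= 0, na.rm = TRUE))
  out <- data.frame(
    C_bait = C_bait, theta_mean = theta_mean, theta_sd = theta_sd,
    n_replicates = rep_len(as.integer(n_replicates), length(C_bait))
  )
  class(out) <- c("titration_series", "data.frame")
  out
}

# Titration model: theta(C) = f * C / (K + C). f is the fraction of
# binding-capable prey; the complete-binding model pins f at 1.
.titration_model <- function(C, K, f) f * C / (K + C)

#' Fit a titration holdup binding curve
#'
#' Weighted nonlinear least squares of
#' `theta(C_bait) = f * C_bait / (K_app + C_bait)` with `K_app > 0` and
#' `0 < f <= 1`. The complete-binding model fixes `f = 1`; the partial
#' model floats it (a sub-unity saturation plateau indicates that only a
#' fraction of the prey population is binding-competent). Weights are
#' `1/sd^2` where replicate sds are available and positive, else
#' unweighted. Three log-spaced starts in `K_app` guard against local
#' minima.
#'
#' @param series a [titration_series()] (>= 4 distinct concentrations for
#'   the complete model, >= 5 for partial).
#' @param model `"complete"` or `"partial"`.
#' @return list of class `"titration_fit"`: `K_app`, `f`, `model`, `se`
#'   (named standard errors), `residual_sd`, `flag` (`"ok"` or
#'   `"no-binding"`, the latter with `K_app = Inf`).
#' @export
fit_titration <- function(series, model = c("complete", "partial")) {
  model <- match.arg(model)
  stopifnot(inherits(series, "titration_series"))
  need <- if (model == "complete") 4L else 5L
  if (nrow(series) < need) {
    stop("need >= ", need, " distinct bait concentrations for the ",
      model, " model")
  }
  x <- series$C_bait
  y <- series$theta_mean
  w <- if (all(is.finite(series$theta_sd)) && all(series$theta_sd > 0)) {
    1 / series$theta_sd^2
  } else {
    rep(1, length(y))
  }
  # no curvature: every theta indistinguishable from zero
  noise <- if (all(is.finite(series$theta_sd))) {
    max(mean(series$theta_sd), 0.01)
  } else {
    0.01
  }
  if (max(abs(y)) < 2 * noise) {
    return(structure(
      list(
        K_app = Inf, f = if (model == "complete") 1 else NA_real_,
        model = model, se = c(K_app = NA_real_, f = NA_real_),
        residual_sd = stats::sd(y), flag = "no-binding"
      ),
      class = "titration_fit"
    ))
  }
  xs <- x[x > 0]
  starts_K <- exp(seq(log(min(xs) / 3), log(max(xs) * 3), length.out = 3))
  best <- NULL
  for (K0 in starts_K) {
    fit <- tryCatch(
      if (model == "complete") {
        stats::nls(y ~ .titration_model(x, K, 1),
          start = list(K = K0), weights = w,
          algorithm = "port", lower = c(K = 1e-12),
          control = stats::nls.control(warnOnly = FALSE, maxiter = 200)
        )
      } else {
        f0 <- min(max(max(y), 0.05), 1)
        stats::nls(y ~ .titration_model(x, K, f),
          start = list(K = K0, f = f0), weights = w,
          algorithm = "port",
          lower = c(K = 1e-12, f = 1e-6), upper = c(K = Inf, f = 1),
          control = stats::nls.control(warnOnly = FALSE, maxiter = 200)
        )
      },
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("titration fit failed from all starts")
  cf <- stats::coef(best$fit)
  se <- tryCatch(
    summary(best$fit)$coefficients[, "Std. Error"],
    error = function(e) rep(NA_real_, length(cf))
  )
  structure(
    list(
      K_app = unname(cf[["K"]]),
      f = if (model == "complete") 1 else unname(cf[["f"]]),
      model = model,
      se = c(
        K_app = unname(se[[1]]),
        f = if (model == "partial" && length(se) > 1) unname(se[[2]]) else NA_real_
      ),
      residual_sd = stats::sd(stats::residuals(best$fit)),
      flag = "ok"
    ),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf(
    "titration fit (%s): K_app = %.4g, f = %.4g [%s]\n",
    x$model, x$K_app, x$f, x$flag
  ))
  invisible(x)
}

#' Construct a fluorescence polarization experiment
#'
#' @param mode `"direct"` (a fixed fluorescent probe titrated with
#'   receptor) or `"competitive"` (fixed probe and receptor, titrated with
#'   an unlabeled competitor).
#' @param titrant_conc concentrations of the titrated species.
#' @param polarization polarization readings (mP), replicate-averaged.
#' @param probe_conc fluorescent probe concentration.
#' @param receptor_conc fixed receptor concentration (competitive mode).
#' @param polarization_sd replicate spreads, optional.
#' @param conc_unit unit of all concentrations in this object (converted
#'   to uM internally by the fitters).
#' @return list of class `"fp_experiment"`.
#' @export
fp_experiment <- function(mode = c("direct", "competitive"),
                          titrant_conc, polarization,
                          probe_conc, receptor_conc = NULL,
                          polarization_sd = NULL, conc_unit = "uM") {
  mode <- match.arg(mode)
  stopifnot(length(titrant_conc) == length(polarization),
    all(titrant_conc >= 0), probe_conc > 0)
  if (mode == "competitive" && is.null(receptor_conc)) {
    stop("competitive mode requires the fixed receptor concentration")
  }
  structure(
    list(
      mode = mode,
      titrant_conc = convert_conc(titrant_conc, conc_unit, "uM"),
      polarization = polarization,
      probe_conc = convert_conc(probe_conc, conc_unit, "uM"),
      receptor_conc = if (is.null(receptor_conc)) {
        NULL
      } else {
        convert_conc(receptor_conc, conc_unit, "uM")
      },
      polarization_sd = polarization_sd
    ),
    class = "fp_experiment"
  )
}

#' Quadratic direct-binding FP model
#'
#' Exact two-species equilibrium accounting for probe depletion: with
#' receptor total R, probe total L and dissociation constant Kd, the bound
#' probe fraction is
#' `b = ((R + L + Kd) - sqrt((R + L + Kd)^2 - 4 R L)) / (2 L)`,
#' and the polarization is `P_free + (P_bound - P_free) * b`.
#'
#' @param receptor_tot,probe_tot total concentrations (same unit as `Kd`).
#' @param Kd dissociation constant (> 0).
#' @param P_free,P_bound polarization of the free and fully bound probe
#'   (mP); a binding probe has `P_bound > P_free` (the complex tumbles
#'   more slowly).
#' @return predicted polarization (mP), vectorized over `receptor_tot`.
#' @export
fp_direct_model <- function(receptor_tot, probe_tot, Kd, P_free, P_bound) {
  stopifnot(all(receptor_tot >= 0), all(probe_tot >= 0), Kd > 0)
  n <- max(length(receptor_tot), length(probe_tot))
  R <- rep_len(receptor_tot, n)
  L <- rep_len(probe_tot, n)
  s <- R + L + Kd
  disc <- pmax(s^2 - 4 * R * L, 0)
  b <- numeric(n)
  pos <- L > 0
  b[pos] <- (s[pos] - sqrt(disc[pos])) / (2 * L[pos])
  # probe -> 0 limit: the ligand-depletion-free hyperbola
  b[!pos] <- R[!pos] / (R[!pos] + Kd)
  P_free + (P_bound - P_free) * b
}

#' Fit a direct FP titration
#'
#' Least-squares fit of the quadratic direct-binding model for
#' `(Kd, P_free, P_bound)`. `P_free` is initialized from the zero-receptor
#' reading; three log-spaced Kd starts protect against local minima. A
#' curve with no usable polarization change is returned as a
#' `"no-binding"` flag rather than a failed fit; a curve that does not
#' approach saturation is flagged `"non-saturating"` but still returned.
#'
#' @param exp an [fp_experiment()] with `mode = "direct"` and >= 6 titrant
#'   concentrations including a zero-receptor point.
#' @return list of class `"fp_fit"`: `Kd` (uM), `P_free`, `P_bound`,
#'   `mode`, `se`, `flag`.
#' @export
fit_fp_direct <- function(exp) {
  stopifnot(inherits(exp, "fp_experiment"), exp$mode == "direct")
  R <- exp$titrant_conc
  P <- exp$polarization
  if (length(R) < 6) stop("need >= 6 receptor concentrations")
  if (!any(R == 0)) stop("a zero-receptor (free probe) point is required")
  L <- exp$probe_conc
  span <- diff(range(P))
  noise <- if (!is.null(exp$polarization_sd)) {
    max(mean(exp$polarization_sd), 1e-6)
  } else {
    1e-6
  }
  if (span < 4 * noise || span == 0) {
    return(structure(
      list(
        Kd = Inf, P_free = mean(P[R == 0]), P_bound = NA_real_,
        mode = "direct", se = c(Kd = NA_real_), flag = "no-binding"
      ),
      class = "fp_fit"
    ))
  }
  p_free0 <- mean(P[R == 0])
  p_bound0 <- max(P) + 0.05 * span
  Rp <- R[R > 0]
  starts_K <- exp(seq(log(min(Rp) / 2), log(max(Rp) * 2), length.out = 3))
  best <- NULL
  for (K0 in starts_K) {
    fit <- tryCatch(
      stats::nls(
        P ~ fp_direct_model(R, L, Kd, Pf, Pb),
        start = list(Kd = K0, Pf = p_free0, Pb = p_bound0),
        algorithm = "port",
        lower = c(Kd = 1e-9, Pf = -Inf, Pb = -Inf),
        control = stats::nls.control(warnOnly = FALSE, maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (!is.null(best)) {
    cf <- stats::coef(best$fit)
    se <- tryCatch(
      summary(best$fit)$coefficients[, "Std. Error"],
      error = function(e) stats::setNames(rep(NA_real_, 3), names(cf))
    )
  } else {
    # fall back to a bounded quasi-Newton search on (log10 Kd, Pf, Pb);
    # port-nls can stall on noisy, weakly saturating curves
    obj <- function(par) {
      sum((P - fp_direct_model(R, L, 10^par[1], par[2], par[3]))^2)
    }
    opts <- lapply(starts_K, function(K0) {
      stats::optim(
        c(log10(K0), p_free0, p_bound0), obj,
        method = "L-BFGS-B",
        lower = c(-9, -Inf, -Inf), upper = c(9, Inf, Inf),
        control = list(maxit = 500)
      )
    })
    opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
    cf <- c(Kd = 10^opt$par[1], Pf = opt$par[2], Pb = opt$par[3])
    se <- stats::setNames(rep(NA_real_, 3), names(cf))
  }
  # saturation check: top measured point should reach most of the fitted
  # amplitude, otherwise Kd is poorly constrained from above
  pred_top <- fp_direct_model(max(R), L, cf[["Kd"]], cf[["Pf"]], cf[["Pb"]])
  frac_sat <- (pred_top - cf[["Pf"]]) / (cf[["Pb"]] - cf[["Pf"]])
  structure(
    list(
      Kd = unname(cf[["Kd"]]), P_free = unname(cf[["Pf"]]),
      P_bound = unname(cf[["Pb"]]), mode = "direct",
      se = c(
        Kd = unname(se[["Kd"]]), P_free = unname(se[["Pf"]]),
        P_bound = unname(se[["Pb"]])
      ),
      flag = if (is.finite(frac_sat) && frac_sat < 0.5) "non-saturating" else "ok"
    ),
    class = "fp_fit"
  )
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf(
    "FP fit (%s): Kd = %.4g uM, P_free = %.4g, P_bound = %.4g [%s]\n",
    x$mode, x$Kd, x$P_free, x$P_bound, x$flag
  ))
  invisible(x)
}

#' Solve the three-species competition equilibrium
#'
#' One receptor, a labeled probe and an unlabeled competitor, each binding
#' the receptor with single-site mass action. The free receptor
#' concentration r solves
#' `r + r * L / (KdL + r) + r * C / (KdC + r) = R_tot`,
#' which is monotone in r and is bracketed in `[0, R_tot]`; it is found by
#' a scalar root search at 1e-12 relative tolerance. Exact ligand
#' depletion is accounted for (no IC50 approximation).
#'
#' @param receptor_tot,probe_tot,competitor_tot total concentrations
#'   (same unit as the Kds; >= 0).
#' @param Kd_probe,Kd_competitor dissociation constants (> 0).
#' @return list with `bound_probe_fraction`, `bound_competitor_fraction`
#'   and `free_receptor`.
#' @export
solve_competitive_equilibrium <- function(receptor_tot, probe_tot,
                                          competitor_tot,
                                          Kd_probe, Kd_competitor) {
  stopifnot(
    receptor_tot >= 0, probe_tot >= 0, competitor_tot >= 0,
    Kd_probe > 0, Kd_competitor > 0
  )
  if (receptor_tot == 0) {
    return(list(
      bound_probe_fraction = 0, bound_competitor_fraction = 0,
      free_receptor = 0
    ))
  }
  bal <- function(r) {
    r + r * probe_tot / (Kd_probe + r) +
      r * competitor_tot / (Kd_competitor + r) - receptor_tot
  }
  r <- stats::uniroot(
    bal, c(0, receptor_tot),
    tol = 1e-12 * max(receptor_tot, 1e-12)
  )$root
  list(
    bound_probe_fraction = if (probe_tot > 0) r / (Kd_probe + r) else 0,
    bound_competitor_fraction = if (competitor_tot > 0) {
      r / (Kd_competitor + r)
    } else {
      0
    },
    free_receptor = r
  )
}

#' Fit a competitive FP titration
#'
#' Single-parameter least squares for the competitor dissociation
#' constant. The probe Kd and the polarization plateaus are held fixed at
#' the values obtained from the direct fit; the model polarization at each
#' competitor concentration comes from the exact three-species equilibrium
#' ([solve_competitive_equilibrium()]), so ligand depletion is handled
#' without IC50 shortcuts. The search is on log10(Kd) over a wide bracket.
#'
#' @param exp an [fp_experiment()] with `mode = "competitive"`.
#' @param direct_fit the `"fp_fit"` from [fit_fp_direct()] supplying
#'   `Kd` (probe), `P_free` and `P_bound`.
#' @return list of class `"fp_fit"` for the competitor; flag
#'   `"lower-bound-only"` when the titration shows no displacement.
#' @export
fit_fp_competitive <- function(exp, direct_fit) {
  stopifnot(
    inherits(exp, "fp_experiment"), exp$mode == "competitive",
    inherits(direct_fit, "fp_fit")
  )
  C <- exp$titrant_conc
  P <- exp$polarization
  R <- exp$receptor_conc
  L <- exp$probe_conc
  Kd_probe <- direct_fit$Kd
  Pf <- direct_fit$P_free
  Pb <- direct_fit$P_bound
  model_P <- function(Kc) {
    vapply(C, function(ci) {
      eq <- solve_competitive_equilibrium(R, L, ci, Kd_probe, Kc)
      Pf + (Pb - Pf) * eq$bound_probe_fraction
    }, numeric(1))
  }
  # displacement check: polarization must drop over the titration
  drop <- P[which.min(C)] - P[which.max(C)]
  noise <- if (!is.null(exp$polarization_sd)) {
    max(mean(exp$polarization_sd), 1e-6)
  } else {
    1e-6
  }
  flag <- if (drop < 3 * noise) "lower-bound-only" else "ok"
  obj <- function(lk) sum((P - model_P(10^lk))^2)
  opt <- stats::optimize(obj, interval = c(-6, 5), tol = 1e-10)
  # polish around the optimum for full precision
  opt2 <- stats::optimize(
    obj, interval = opt$minimum + c(-0.05, 0.05), tol = .Machine$double.eps^0.5
  )
  if (opt2$objective < opt$objective) opt <- opt2
  Kc <- 10^opt$minimum
  structure(
    list(
      Kd = Kc, P_free = Pf, P_bound = Pb, mode = "competitive",
      Kd_probe = Kd_probe, se = c(Kd = NA_real_), flag = flag
    ),
    class = "fp_fit"
  )
}
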