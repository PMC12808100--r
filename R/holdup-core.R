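# Equilibrium algebra of the holdup assay.
#
# A bait-saturated resin depletes binding preys from a cell extract. At
# equilibrium the fraction of a prey bound to the immobilized bait (the
# degree of binding, theta) relates the residual free prey intensity to the
# apparent dissociation constant through the single-site hyperbolic law
#   theta = 1 - I_free/I_tot = C_bait / (C_bait + K_app).

#' Degree of binding from intensities
#'
#' The depletion of a prey in the bait-exposed supernatant relative to the
#' control: `theta = 1 - I_free / I_tot`. Values are at most 1 (complete
#' depletion); negative values indicate enrichment rather than binding and
#' are reported, not treated as errors.
#'
#' @param I_free intensity measured after exposure to the bait resin (>= 0).
#' @param I_tot total intensity measured against the control resin (> 0).
#' @return numeric vector of degrees of binding in (-Inf, 1].
#' @examples
#' degree_of_binding(0.78, 1.00) # 22% depletion
#' @export
degree_of_binding <- function(I_free, I_tot) {
  if (!is.numeric(I_free) || !is.numeric(I_tot)) {
    stop("intensities must be numeric")
  }
  if (any(!is.finite(I_tot)) || any(I_tot <= 0)) {
    stop("I_tot must be positive and finite")
  }
  if (any(I_free < 0, na.rm = TRUE)) {
    stop("I_free must be non-negative")
  }
  1 - I_free / I_tot
}

#' Apparent dissociation constant from a degree of binding
#'
#' Inverts the hyperbolic binding law at a known bait concentration. With
#' the prey concentration supplied the full form
#' `K_app = (C_bait - C_prey * theta) * (1 - theta) / theta` is used;
#' without it, the approximation `K_app = C_bait * (1 - theta) / theta`
#' (valid when the prey is far below the bait, the usual situation for
#' endogenous preys against a resin-immobilized bait).
#'
#' @param theta degree of binding, < 1 (see `clamp`). Non-positive values
#'   are legal and yield `K_app = Inf` with a `"non-binder"` flag.
#' @param C_bait bait concentration (same unit as the returned `K_app`).
#' @param C_prey prey concentration, or `NULL` (default) for the
#'   approximate form.
#' @param clamp if `TRUE`, theta >= 1 (over-depletion from measurement
#'   noise) is clamped to `1 - 1e-6`; if `FALSE` (default) such input is an
#'   error.
#' @return a data.frame of class `"affinity_estimate"` with columns
#'   `theta`, `K_app`, `method` (`"approx"` or `"full"`) and `flag`.
#' @examples
#' kapp_from_theta(0.22, 26) # ~92 uM
#' kapp_from_theta(0.5, 10)  # K_app equals C_bait at half-depletion
#' @export
kapp_from_theta <- function(theta, C_bait, C_prey = NULL, clamp = FALSE) {
  stopifnot(is.numeric(theta), is.numeric(C_bait), all(C_bait > 0))
  if (any(theta >= 1, na.rm = TRUE)) {
    if (clamp) {
      theta[!is.na(theta) & theta >= 1] <- 1 - 1e-6
    } else {
      stop("theta >= 1 (over-depletion); set clamp = TRUE to clamp")
    }
  }
  method <- if (is.null(C_prey)) "approx" else "full"
  n <- max(length(theta), length(C_bait))
  theta <- rep_len(theta, n)
  C_bait <- rep_len(C_bait, n)
  K_app <- if (method == "approx") {
    C_bait * (1 - theta) / theta
  } else {
    stopifnot(all(C_prey >= 0))
    C_prey <- rep_len(C_prey, n)
    (C_bait - C_prey * theta) * (1 - theta) / theta
  }
  flag <- rep("ok", n)
  nb <- !is.na(theta) & theta <= 0
  K_app[nb] <- Inf
  flag[nb] <- "non-binder"
  flag[is.na(theta)] <- NA_character_
  out <- data.frame(
    theta = theta, K_app = K_app, method = method, flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("affinity_estimate", "data.frame")
  out
}

#' Degree of binding predicted from an affinity
#'
#' The forward hyperbolic law `theta = C_bait / (C_bait + K_app)`; the
#' algebraic inverse of [kapp_from_theta()] (approximate form) on (0, 1).
#'
#' @param K_app apparent dissociation constant (>= 0; 0 means an
#'   infinitely tight binder, Inf a non-binder).
#' @param C_bait bait concentration in the same unit (>= 0).
#' @return degree of binding in \[0, 1\].
#' @export
theta_from_kapp <- function(K_app, C_bait) {
  stopifnot(is.numeric(K_app), is.numeric(C_bait))
  if (any(K_app < 0, na.rm = TRUE) || any(C_bait < 0, na.rm = TRUE)) {
    stop("K_app and C_bait must be non-negative")
  }
  n <- max(length(K_app), length(C_bait))
  K_app <- rep_len(K_app, n)
  C_bait <- rep_len(C_bait, n)
  if (any(K_app == 0 & C_bait == 0, na.rm = TRUE)) {
    stop("K_app and C_bait cannot both be zero")
  }
  ifelse(is.infinite(K_app), 0, C_bait / (C_bait + K_app))
}

#' Affinity of the link inside an indirectly captured complex
#'
#' When a bait captures prey A directly and prey B only through its
#' complex with A, the two measured depletions differ (the directly bound
#' prey is always depleted at least as much). Assuming the A-B interaction
#' is independent of the A-bait interaction, the apparent dissociation
#' constant of the A-B link is
#' `K = (C_A * theta_A - C_B * theta_B) * (theta_A - theta_B) /
#'  (theta_A * theta_B)`
#' where `C_A`, `C_B` are the total extract concentrations of the two
#' preys. Units follow the input concentrations (typically nM for
#' endogenous complexes in a diluted extract).
#'
#' @param C_direct,C_indirect total concentrations of the directly and
#'   indirectly captured preys (same unit).
#' @param theta_direct,theta_indirect their measured degrees of binding
#'   against the same bait; both must be > 0.
#' @return a one-row data.frame of class `"affinity_estimate"` with
#'   columns `K_app` and `flag`; `flag` is `"inconsistent"` (estimate
#'   unreliable) when `theta_indirect > theta_direct`.
#' @examples
#' tethered_link_kapp(1, 1, 0.5, 0.25) # 0.5 (input units)
#' @export
tethered_link_kapp <- function(C_direct, C_indirect,
                               theta_direct, theta_indirect) {
  stopifnot(
    is.numeric(C_direct), is.numeric(C_indirect),
    C_direct >= 0, C_indirect >= 0
  )
  if (theta_direct <= 0 || theta_indirect <= 0) {
    stop("both degrees of binding must be positive")
  }
  if (theta_direct > 1 || theta_indirect > 1) {
    stop("degrees of binding cannot exceed 1")
  }
  K <- (C_direct * theta_direct - C_indirect * theta_indirect) *
    (theta_direct - theta_indirect) / (theta_direct * theta_indirect)
  flag <- if (theta_indirect > theta_direct) "inconsistent" else "ok"
  out <- data.frame(
    K_app = K, theta_direct = theta_direct,
    theta_indirect = theta_indirect, flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("affinity_estimate", "data.frame")
  out
}
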