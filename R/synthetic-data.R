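# Seeded generators for every input the pipeline consumes, with ground
# truth attached, so all stages are testable without any external data.
#
# One root seed spawns per-component child streams (see child_seed()) so
# that adding a generator call does not perturb the draws of the others.

#' Specify an nHU-MS simulation
#'
#' The defaults emulate a single-point nHU-MS screen: 6 control and 6 bait
#' replicates (2 biological x 3 technical), a 26 uM bait, binder
#' affinities log-uniform between 0.5 and 50 uM, log2 replicate noise of
#' 0.15, 5% missing-at-random, and protein intensities log-normal over
#' roughly 5-9 decades (arbitrary DIA protein-group units).
#'
#' @param seed integer root seed.
#' @param n_proteins,n_binders protein-group and true-binder counts.
#' @param C_bait bait concentration (uM).
#' @param kapp_range log-uniform range for binder affinities (uM).
#' @param partial_fraction_options candidate values of the
#'   binding-capable fraction f; each binder draws one uniformly.
#' @param n_replicates replicates per condition.
#' @param replicate_noise_sd multiplicative replicate noise, sd in log2
#'   units.
#' @param missing_rate missing-at-random fraction.
#' @param detection_limit_missing extra missing probability applied to
#'   cells in the bottom intensity decile (detection-limit missingness).
#' @param intensity_log_mean,intensity_log_sd log-normal parameters of the
#'   protein abundance distribution (natural log). The defaults (mean 7
#'   decades, sd 0.65 decades) make a 1000-protein dataset span roughly
#'   5-9 in log10, the dynamic range of DIA protein-group intensities.
#' @return list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_proteins = 1000L,
                            n_binders = 20L,
                            C_bait = 26,
                            kapp_range = c(0.5, 50),
                            partial_fraction_options = 1,
                            n_replicates = 6L,
                            replicate_noise_sd = 0.15,
                            missing_rate = 0.05,
                            detection_limit_missing = 0.2,
                            intensity_log_mean = 7 * log(10),
                            intensity_log_sd = 0.65 * log(10)) {
  stopifnot(
    n_binders <= n_proteins, C_bait > 0,
    missing_rate >= 0, missing_rate <= 1,
    detection_limit_missing >= 0, detection_limit_missing <= 1,
    all(partial_fraction_options > 0), all(partial_fraction_options <= 1),
    kapp_range[1] > 0, kapp_range[2] >= kapp_range[1]
  )
  structure(
    list(
      seed = as.integer(seed), n_proteins = as.integer(n_proteins),
      n_binders = as.integer(n_binders), C_bait = C_bait,
      kapp_range = kapp_range,
      partial_fraction_options = partial_fraction_options,
      n_replicates = as.integer(n_replicates),
      replicate_noise_sd = replicate_noise_sd,
      missing_rate = missing_rate,
      detection_limit_missing = detection_limit_missing,
      intensity_log_mean = intensity_log_mean,
      intensity_log_sd = intensity_log_sd
    ),
    class = "simulation_spec"
  )
}

#' Simulate a single-point nHU-MS experiment
#'
#' Control intensities are log-normal per protein; bait-condition
#' intensities are the control level multiplied by `(1 - theta_true)`
#' where `theta_true = f * C_bait / (C_bait + K_app)` for the designated
#' binders (exactly the hyperbolic law, before noise). Multiplicative
#' replicate noise is applied on the log2 scale, then values go missing
#' at random, with extra detection-limit missingness in the bottom decile.
#'
#' @param spec a [simulation_spec()].
#' @return list with `table` (an [intensity_table()]) and `truth`
#'   (data.frame: `prey_id`, `is_binder`, `K_app`, `f`, `theta`).
#' @export
simulate_nhu_ms <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(child_seed(spec$seed, 1L), {
    np <- spec$n_proteins
    nr <- spec$n_replicates
    ids <- sprintf("PROT%04d", seq_len(np))
    base <- exp(stats::rnorm(np, spec$intensity_log_mean,
      spec$intensity_log_sd))
    is_binder <- rep(FALSE, np)
    if (spec$n_binders > 0) is_binder[seq_len(spec$n_binders)] <- TRUE
    K_app <- rep(Inf, np)
    f <- rep(NA_real_, np)
    nb <- spec$n_binders
    if (nb > 0) {
      K_app[is_binder] <- exp(stats::runif(
        nb, log(spec$kapp_range[1]), log(spec$kapp_range[2])
      ))
      f[is_binder] <- sample(spec$partial_fraction_options, nb, replace = TRUE)
    }
    theta <- ifelse(
      is_binder,
      f * spec$C_bait / (spec$C_bait + K_app),
      0
    )
    ctrl <- matrix(base, np, nr)
    bait <- matrix(base * (1 - theta), np, nr)
    vals <- cbind(ctrl, bait)
    vals <- vals * 2^matrix(
      stats::rnorm(np * 2 * nr, 0, spec$replicate_noise_sd), np, 2 * nr
    )
    # missingness: at random, plus detection-limit extra in the bottom decile
    miss <- matrix(
      stats::runif(np * 2 * nr) < spec$missing_rate, np, 2 * nr
    )
    if (spec$detection_limit_missing > 0) {
      lim <- stats::quantile(vals, 0.10)
      low <- vals <= lim
      miss <- miss | (low & matrix(
        stats::runif(np * 2 * nr) < spec$detection_limit_missing, np, 2 * nr
      ))
    }
    vals[miss] <- NA
    rownames(vals) <- ids
    colnames(vals) <- c(
      paste0("control_", seq_len(nr)), paste0("bait_", seq_len(nr))
    )
    tbl <- intensity_table(
      vals,
      condition = rep(c("control", "bait"), each = nr),
      replicate = rep(seq_len(nr), 2)
    )
    truth <- data.frame(
      prey_id = ids, is_binder = is_binder, K_app = K_app, f = f,
      theta = theta, stringsAsFactors = FALSE
    )
    list(table = tbl, truth = truth)
  })
}

#' Simulate a titration holdup series
#'
#' Degrees of binding drawn as Gaussians around
#' `f * C / (K_app + C)`, truncated to \[0, 1\]; replicate mean and sd are
#' reported per concentration.
#'
#' @param K_app,f generating parameters (`K_app` > 0, `0 < f <= 1`).
#' @param C_baits bait concentrations (uM).
#' @param noise_sd Gaussian noise sd on theta (0 gives exact curve
#'   points).
#' @param n_reps replicates per concentration.
#' @param seed integer seed.
#' @return a [titration_series()].
#' @export
simulate_titration <- function(K_app, f = 1, C_baits, noise_sd = 0.03,
                               n_reps = 3L, seed = 1L) {
  stopifnot(K_app > 0, f > 0, f <= 1, noise_sd >= 0)
  with_seed(child_seed(seed, 2L), {
    mu <- .titration_model(C_baits, K_app, f)
    if (noise_sd == 0) {
      return(titration_series(C_baits, mu,
        theta_sd = rep(0, length(C_baits)), n_replicates = n_reps))
    }
    reps <- vapply(
      mu,
      function(m) {
        x <- stats::rnorm(n_reps, m, noise_sd)
        pmin(pmax(x, 0), 1)
      },
      numeric(n_reps)
    )
    titration_series(
      C_baits,
      theta_mean = colMeans(reps),
      theta_sd = apply(reps, 2, stats::sd),
      n_replicates = n_reps
    )
  })
}

#' Simulate a fluorescence polarization titration
#'
#' Polarization readings generated from the exact equilibrium solutions
#' (quadratic model for direct mode, three-species competition for
#' competitive mode) plus Gaussian noise in mP.
#'
#' @param mode `"direct"` or `"competitive"`.
#' @param Kd_probe probe-receptor dissociation constant (uM).
#' @param Kd_competitor competitor dissociation constant (uM, competitive
#'   mode).
#' @param probe_conc probe concentration (uM).
#' @param receptor_conc fixed receptor concentration (uM, competitive
#'   mode).
#' @param titrant_concs concentrations of the titrated species (uM).
#' @param P_free,P_bound polarization plateaus (mP).
#' @param noise_mP Gaussian noise sd (mP).
#' @param seed integer seed.
#' @return an [fp_experiment()].
#' @export
simulate_fp <- function(mode = c("direct", "competitive"),
                        Kd_probe, Kd_competitor = NULL,
                        probe_conc = 0.05, receptor_conc = NULL,
                        titrant_concs,
                        P_free = 60, P_bound = 200,
                        noise_mP = 0, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(Kd_probe > 0, noise_mP >= 0)
  with_seed(child_seed(seed, 3L), {
    P <- if (mode == "direct") {
      fp_direct_model(titrant_concs, probe_conc, Kd_probe, P_free, P_bound)
    } else {
      stopifnot(!is.null(Kd_competitor), !is.null(receptor_conc))
      vapply(titrant_concs, function(ci) {
        eq <- solve_competitive_equilibrium(
          receptor_conc, probe_conc, ci, Kd_probe, Kd_competitor
        )
        P_free + (P_bound - P_free) * eq$bound_probe_fraction
      }, numeric(1))
    }
    if (noise_mP > 0) P <- P + stats::rnorm(length(P), 0, noise_mP)
    fp_experiment(
      mode = mode, titrant_conc = titrant_concs, polarization = P,
      probe_conc = probe_conc, receptor_conc = receptor_conc,
      polarization_sd = rep(noise_mP, length(P))
    )
  })
}

# random amino-acid stretch (uniform over the 20 canonical residues)
.random_peptide <- function(n) {
  paste(sample(setdiff(.aa_alphabet, "X"), n, replace = TRUE), collapse = "")
}

#' Simulate a motif-discovery dataset
#'
#' Builds random protein sequences composed of ordered domain blocks and
#' disordered linkers, plants instances of one consensus motif type inside
#' disordered linkers with elevated per-residue conservation, and plants
#' decoy motif types with background conservation. Returns everything the
#' motif module consumes plus the ground truth. The default scale mirrors
#' a small interactome-level discovery run: ~19 planted instances across
#' 14 partner proteins and 14 decoy types.
#'
#' @param n_partners proteins carrying the planted motif type.
#' @param n_decoy_types decoy motif types.
#' @param n_planted total planted instances of the true type (spread over
#'   the partners, at least one each).
#' @param planted_consensus consensus of the planted type (default
#'   `"NPF"`).
#' @param conservation_effect shift of the planted instances' per-residue
#'   conservation above the background mean (0 = null: planted type is
#'   indistinguishable).
#' @param background_mean,background_sd background conservation
#'   distribution (truncated to \[0, 1\]).
#' @param seed integer seed.
#' @return list with `sequences` (named character vector), `tracks`
#'   (per-protein list with `conservation`, `iupred`), `domains`
#'   (data.frame protein_id/start/end), `instances` (data.frame of all
#'   planted instances: protein_id, start, end, motif_type, is_planted).
#' @export
simulate_motif_dataset <- function(n_partners = 14L,
                                   n_decoy_types = 14L,
                                   n_planted = 19L,
                                   planted_consensus = "NPF",
                                   conservation_effect = 0.3,
                                   background_mean = 0.4,
                                   background_sd = 0.1,
                                   seed = 1L) {
  stopifnot(n_partners >= 1, n_planted >= n_partners)
  with_seed(child_seed(seed, 4L), {
    core_len <- nchar(planted_consensus)
    # decoy consensus strings: random tripeptides distinct from the
    # planted type
    decoys <- character(0)
    while (length(decoys) < n_decoy_types) {
      cand <- .random_peptide(3)
      if (cand != planted_consensus && !(cand %in% decoys)) {
        decoys <- c(decoys, cand)
      }
    }
    n_prot <- n_partners + n_decoy_types
    ids <- sprintf("SYN%03d", seq_len(n_prot))
    # assign planted instances to partner proteins, one minimum each
    extra <- n_planted - n_partners
    if (extra > 3L * n_partners) {
      stop("at most 4 instances can be planted per partner protein")
    }
    counts <- rep(1L, n_partners)
    if (extra > 0) {
      # at most 3 extra slots per partner (4 plantable positions each)
      add <- sample(rep(seq_len(n_partners), 3L))[seq_len(extra)]
      for (a in add) counts[a] <- counts[a] + 1L
    }
    sequences <- character(n_prot)
    names(sequences) <- ids
    tracks <- vector("list", n_prot)
    names(tracks) <- ids
    domains <- NULL
    instances <- NULL
    rtrunc01 <- function(n, mean, sd) pmin(pmax(stats::rnorm(n, mean, sd), 0), 1)
    for (i in seq_len(n_prot)) {
      # layout: domain(60) - linker(40) - domain(60) - linker(40)
      dom1 <- .random_peptide(60)
      link1 <- .random_peptide(40)
      dom2 <- .random_peptide(60)
      link2 <- .random_peptide(40)
      planted_here <- if (i <= n_partners) counts[i] else 1L
      type_here <- if (i <= n_partners) {
        planted_consensus
      } else {
        decoys[i - n_partners]
      }
      # plant instances at spaced offsets inside the linkers
      linker_starts <- c(61L, 161L) # 1-based starts of the two linkers
      pos <- integer(0)
      slots <- c(
        linker_starts[1] + c(5L, 25L),
        linker_starts[2] + c(5L, 25L)
      )
      pos <- sort(sample(slots, planted_here))
      seqchars <- strsplit(paste0(dom1, link1, dom2, link2), "")[[1]]
      for (p in pos) {
        seqchars[p:(p + core_len - 1L)] <-
          strsplit(type_here, "")[[1]]
      }
      sq <- paste(seqchars, collapse = "")
      n <- nchar(sq)
      cons <- rtrunc01(n, background_mean, background_sd)
      elevated <- i <= n_partners
      for (p in pos) {
        idx <- p:(p + core_len - 1L)
        if (elevated) {
          cons[idx] <- rtrunc01(
            core_len, background_mean + conservation_effect, background_sd
          )
        }
      }
      iup <- rep(0.2, n)
      iup[61:100] <- 0.8
      iup[161:200] <- 0.8
      sequences[i] <- sq
      tracks[[i]] <- list(conservation = cons, iupred = iup)
      domains <- rbind(domains, data.frame(
        protein_id = ids[i], start = c(1L, 101L), end = c(60L, 160L),
        stringsAsFactors = FALSE
      ))
      instances <- rbind(instances, data.frame(
        protein_id = ids[i], start = pos, end = pos + core_len - 1L,
        motif_type = type_here, is_planted = elevated,
        stringsAsFactors = FALSE
      ))
    }
    list(
      sequences = sequences, tracks = tracks, domains = domains,
      instances = instances, planted_consensus = planted_consensus,
      decoy_types = decoys
    )
  })
}
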