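# Disorder-aware consensus motif scanning, proteome-background enrichment
# and conservation-based re-ranking of candidate motif types.
#
# Short linear motifs (SLiMs) are few-residue binding elements that live in
# intrinsically disordered regions. Because consensus patterns like NPF are
# extremely common by chance, candidate motif types from a discovery tool
# are re-ranked by the evolutionary conservation of their instances, which
# enriches for functional elements.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Per-residue disorder mask
#'
#' A residue is classified as disordered iff it is outside every annotated
#' globular-domain interval AND one of the disorder evidence rules holds:
#' an experimentally verified disorder flag, or an AlphaFold2 relative
#' solvent accessibility above 0.582, or - only when no AF2-rsa track is
#' available for the protein - an IUPred score above 0.4. Maximal
#' disordered runs shorter than `min_run` residues are then cleared.
#'
#' @param sequence amino-acid sequence string (determines the mask length).
#' @param tracks named list of per-residue numeric vectors, each of the
#'   sequence length; recognized names: `disorder_experimental` (0/1),
#'   `af2_rsa`, `iupred`. Any subset may be present.
#' @param domains two-column matrix/data.frame of 1-based inclusive
#'   `(start, end)` domain intervals, or `NULL`.
#' @param af2_rsa_threshold,iupred_threshold predictor cutoffs (defaults
#'   0.582 and 0.4).
#' @param min_run minimal disordered run length retained (default 5).
#' @param combine `"af2_then_iupred"` (default: IUPred consulted only when
#'   the AF2 track is absent) or `"or"` (either predictor suffices).
#' @return logical vector, one element per residue.
#' @export
disorder_mask <- function(sequence, tracks = list(), domains = NULL,
                          af2_rsa_threshold = 0.582,
                          iupred_threshold = 0.4,
                          min_run = 5L,
                          combine = c("af2_then_iupred", "or")) {
  combine <- match.arg(combine)
  n <- nchar(sequence)
  stopifnot(n > 0)
  for (nm in names(tracks)) {
    if (length(tracks[[nm]]) != n) {
      stop("track '", nm, "' length ", length(tracks[[nm]]),
        " does not match sequence length ", n)
    }
  }
  evid <- rep(FALSE, n)
  if (!is.null(tracks$disorder_experimental)) {
    evid <- evid | (tracks$disorder_experimental > 0)
  }
  has_af2 <- !is.null(tracks$af2_rsa)
  if (has_af2) {
    evid <- evid | (tracks$af2_rsa > af2_rsa_threshold)
  }
  if (!is.null(tracks$iupred) && (combine == "or" || !has_af2)) {
    evid <- evid | (tracks$iupred > iupred_threshold)
  }
  mask <- evid
  if (!is.null(domains) && NROW(domains) > 0) {
    domains <- as.matrix(domains[, 1:2, drop = FALSE])
    if (any(domains[, 1] < 1) || any(domains[, 2] > n) ||
      any(domains[, 1] > domains[, 2])) {
      stop("domain intervals out of sequence bounds")
    }
    for (i in seq_len(nrow(domains))) {
      mask[domains[i, 1]:domains[i, 2]] <- FALSE
    }
  }
  # drop short runs
  r <- rle(mask)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

# Compile a fixed-position consensus ("x" = any residue) into a regex.
.consensus_regex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  ok <- chars %in% c(.aa_alphabet, "X") | chars == "x"
  bad <- strsplit(consensus, "")[[1]][!ok]
  if (length(bad) > 0) {
    stop("invalid pattern character(s): ", paste(unique(bad), collapse = ", "))
  }
  # lower-case x is the wildcard; upper-case X is the unknown residue and
  # matches only a literal X
  orig <- strsplit(consensus, "")[[1]]
  paste(ifelse(orig == "x", ".", toupper(orig)), collapse = "")
}

#' Scan a sequence for a consensus motif
#'
#' Finds every (possibly overlapping) occurrence of a fixed-position
#' consensus pattern (`"x"` is a single-residue wildcard) and reports it
#' with flanking sequence context. When a disorder mask is supplied, only
#' matches whose core lies entirely inside the mask are reported.
#'
#' @param sequence amino-acid sequence string.
#' @param consensus pattern, e.g. `"NPF"` or `"NPxY"`.
#' @param mask logical per-residue mask from [disorder_mask()], or `NULL`.
#' @param flank residues of context reported on each side (default 5,
#'   truncated at the termini).
#' @param protein_id identifier recorded in the output.
#' @return data.frame of class `"motif_instances"` with columns
#'   `protein_id`, `start`, `end` (1-based inclusive), `matched_sequence`
#'   (the core), `context` (core plus flanks), `motif_type`,
#'   `in_disorder`.
#' @examples
#' scan_consensus("GPAAARRNPFARLDNRPR", "NPF") # one hit at 8-10
#' @export
scan_consensus <- function(sequence, consensus, mask = NULL, flank = 5L,
                           protein_id = "seq") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stopifnot(n > 0)
  if (!is.null(mask) && length(mask) != n) {
    stop("mask length does not match sequence length")
  }
  rx <- .consensus_regex(consensus)
  len <- nchar(consensus)
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  starts <- as.integer(m)
  starts <- starts[starts > 0]
  empty <- data.frame(
    protein_id = character(), start = integer(), end = integer(),
    matched_sequence = character(), context = character(),
    motif_type = character(), in_disorder = logical(),
    stringsAsFactors = FALSE
  )
  class(empty) <- c("motif_instances", "data.frame")
  if (length(starts) == 0) return(empty)
  ends <- starts + len - 1L
  keep <- ends <= n
  starts <- starts[keep]
  ends <- ends[keep]
  if (!is.null(mask)) {
    in_mask <- vapply(
      seq_along(starts),
      function(i) all(mask[starts[i]:ends[i]]),
      logical(1)
    )
    starts <- starts[in_mask]
    ends <- ends[in_mask]
  }
  if (length(starts) == 0) return(empty)
  ctx_start <- pmax(starts - flank, 1L)
  ctx_end <- pmin(ends + flank, n)
  out <- data.frame(
    protein_id = protein_id,
    start = starts,
    end = ends,
    matched_sequence = substring(sequence, starts, ends),
    context = substring(sequence, ctx_start, ctx_end),
    motif_type = consensus,
    in_disorder = !is.null(mask),
    stringsAsFactors = FALSE
  )
  class(out) <- c("motif_instances", "data.frame")
  out
}

#' Motif enrichment against a proteome background
#'
#' How many motif-containing proteins would be expected among `n_partners`
#' randomly drawn proteins, given the proteome-wide prevalence of the
#' motif; the fold enrichment of the observed count over that expectation;
#' and an upper-tail hypergeometric probability of observing at least that
#' many. Counting is per protein (>= 1 instance), not per instance.
#'
#' @param observed_with_motif motif-containing proteins among the partners.
#' @param n_partners number of interaction partners considered.
#' @param proteome_with_motif motif-containing proteins in the proteome.
#' @param proteome_size proteome size.
#' @return list with `expected`, `fold` and `p`.
#' @examples
#' motif_enrichment(17, 70, 446, 20000) # > 10-fold enrichment
#' @export
motif_enrichment <- function(observed_with_motif, n_partners,
                             proteome_with_motif, proteome_size) {
  stopifnot(
    observed_with_motif >= 0, n_partners >= 0,
    proteome_with_motif >= 0,
    observed_with_motif <= n_partners,
    proteome_with_motif <= proteome_size
  )
  if (proteome_size == 0) stop("proteome_size must be positive")
  expected <- n_partners * proteome_with_motif / proteome_size
  fold <- if (expected > 0) observed_with_motif / expected else NA_real_
  p <- stats::phyper(
    observed_with_motif - 1, proteome_with_motif,
    proteome_size - proteome_with_motif, n_partners,
    lower.tail = FALSE
  )
  list(expected = expected, fold = fold, p = p)
}

#' Mean conservation of a motif instance
#'
#' Arithmetic mean of the per-residue conservation values over the core
#' motif positions (flanks do not contribute).
#'
#' @param start,end 1-based inclusive core coordinates.
#' @param conservation per-residue conservation track covering the
#'   instance; `NA` inside the core is an error.
#' @return mean conservation score.
#' @export
score_instance_conservation <- function(start, end, conservation) {
  stopifnot(start >= 1, end >= start)
  if (end > length(conservation)) {
    stop("conservation track does not cover positions ", start, "-", end)
  }
  vals <- conservation[start:end]
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("missing conservation values inside the motif core")
  }
  mean(vals)
}

#' Rank motif types by mean instance conservation
#'
#' Candidate motif types (e.g. the consensus strings proposed by a de novo
#' discovery tool) are re-ordered by the mean of their instances'
#' conservation scores, descending; ties are broken lexicographically on
#' the type label for determinism.
#'
#' @param instances data.frame with columns `motif_type` and
#'   `conservation` (one row per scored instance).
#' @return data.frame of class `"motif_type_ranking"` with columns
#'   `motif_type`, `instance_count`, `mean_conservation`, `rank`.
#' @export
rank_motif_types <- function(instances) {
  if (NROW(instances) == 0) {
    out <- data.frame(
      motif_type = character(), instance_count = integer(),
      mean_conservation = numeric(), rank = integer(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("motif_type_ranking", "data.frame")
    return(out)
  }
  stopifnot(
    all(c("motif_type", "conservation") %in% names(instances)),
    !anyNA(instances$conservation)
  )
  agg <- stats::aggregate(
    conservation ~ motif_type, data = instances,
    FUN = mean
  )
  cnt <- table(instances$motif_type)
  agg$instance_count <- as.integer(cnt[agg$motif_type])
  ord <- order(-agg$conservation, agg$motif_type)
  agg <- agg[ord, , drop = FALSE]
  out <- data.frame(
    motif_type = agg$motif_type,
    instance_count = agg$instance_count,
    mean_conservation = agg$conservation,
    rank = seq_len(nrow(agg)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("motif_type_ranking", "data.frame")
  out
}
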