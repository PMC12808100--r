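# Readers and writers for the plain-text formats the package consumes and
# produces. TSV (tab-delimited, UTF-8, header row, decimal point) is the
# canonical tabular dialect. All residue coordinates in files are 1-based
# inclusive.

#' Read a wide intensity matrix with its sample sheet
#'
#' The intensity file is a wide TSV: first column protein identifier,
#' remaining columns one sample each (the layout of DIA protein-group
#' matrices). The sample sheet is a TSV with columns `sample`, `condition`
#' (`control`/`bait`) and optionally `replicate`. Zeros are treated as
#' missing by default (DIA exports encode non-detection inconsistently).
#'
#' @param path intensity TSV path.
#' @param sample_sheet_path sample sheet TSV path.
#' @param zero_as_missing treat 0 as missing (default TRUE).
#' @return an [intensity_table()].
#' @export
read_intensity_table <- function(path, sample_sheet_path,
                                 zero_as_missing = TRUE) {
  raw <- utils::read.delim(path, check.names = FALSE,
    stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("intensity file needs an id column plus samples")
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate protein ids: ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (zero_as_missing) vals[vals == 0] <- NA
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(sheet))) {
    stop("sample sheet needs 'sample' and 'condition' columns")
  }
  unmapped <- setdiff(colnames(vals), sheet$sample)
  if (length(unmapped) > 0) {
    stop("sample column(s) absent from the sample sheet: ",
      paste(unmapped, collapse = ", "))
  }
  sheet <- sheet[match(colnames(vals), sheet$sample), , drop = FALSE]
  intensity_table(
    vals,
    condition = sheet$condition,
    replicate = if ("replicate" %in% names(sheet)) sheet$replicate else NULL
  )
}

#' Write an intensity table and its sample sheet
#'
#' @param table an [intensity_table()].
#' @param path intensity TSV path.
#' @param sample_sheet_path sample sheet TSV path.
#' @param missing_as how missing cells are encoded: `"empty"` or `"zero"`.
#' @return invisibly, the paths.
#' @export
write_intensity_table <- function(table, path, sample_sheet_path,
                                  missing_as = c("empty", "zero")) {
  missing_as <- match.arg(missing_as)
  stopifnot(inherits(table, "intensity_table"))
  v <- table$values
  df <- data.frame(protein_id = rownames(v), v, check.names = FALSE,
    stringsAsFactors = FALSE)
  na_str <- if (missing_as == "empty") "" else "0"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = na_str)
  utils::write.table(table$samples, sample_sheet_path, sep = "\t",
    quote = FALSE, row.names = FALSE)
  invisible(c(path, sample_sheet_path))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path (uncompressed).
#' @return named character vector of uppercase amino-acid sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path)
  sq <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(sq) <- vapply(
    strsplit(names(set), "\\s+"), `[`, character(1), 1
  )
  sq
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read per-residue score tracks
#'
#' Long TSV with columns `protein_id`, `kind`, `position` (1-based) and
#' `value`. Returns a nested list `tracks[[protein_id]][[kind]]` of
#' numeric vectors. When `sequences` is given, every track is checked to
#' have exactly the sequence length.
#'
#' @param path track TSV path.
#' @param sequences optional named character vector for length validation.
#' @return nested list of per-residue numeric vectors.
#' @export
read_tracks <- function(path, sequences = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "kind", "position", "value")
  if (!all(need %in% names(df))) {
    stop("track file needs columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (key in unique(df$protein_id)) {
    sub <- df[df$protein_id == key, , drop = FALSE]
    out[[key]] <- lapply(split(sub, sub$kind), function(s) {
      s <- s[order(s$position), , drop = FALSE]
      if (!identical(s$position, seq_len(nrow(s)))) {
        stop("track positions for ", key, " are not contiguous from 1")
      }
      s$value
    })
    if (!is.null(sequences)) {
      if (!key %in% names(sequences)) {
        stop("track protein ", key, " absent from sequences")
      }
      n <- nchar(sequences[[key]])
      for (kind in names(out[[key]])) {
        if (length(out[[key]][[kind]]) != n) {
          stop("track '", kind, "' for ", key, " has length ",
            length(out[[key]][[kind]]), ", sequence has ", n)
        }
      }
    }
  }
  out
}

#' Write per-residue score tracks
#'
#' Inverse of [read_tracks()].
#'
#' @param tracks nested list `tracks[[protein_id]][[kind]]`.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_tracks <- function(tracks, path) {
  rows <- list()
  for (key in names(tracks)) {
    for (kind in names(tracks[[key]])) {
      v <- tracks[[key]][[kind]]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = key, kind = kind, position = seq_along(v), value = v,
        stringsAsFactors = FALSE
      )
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Read domain-annotation intervals
#'
#' TSV with columns `protein_id`, `start`, `end`; coordinates are 1-based
#' inclusive (declared in the header comment emitted by
#' [write_domains()]).
#'
#' @param path TSV path.
#' @return data.frame `protein_id`, `start`, `end`.
#' @export
read_domains <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
    stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(df))) {
    stop("domain file needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start < 1) || any(df$end < df$start)) {
    stop("malformed domain intervals (1-based inclusive expected)")
  }
  df[need]
}

#' Write domain-annotation intervals
#'
#' @param domains data.frame with `protein_id`, `start`, `end`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_domains <- function(domains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  utils::write.table(domains, con, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Read a candidate motif table
#'
#' TSV with at least `protein_id`, `start`, `end`, `motif_type`
#' (1-based inclusive), e.g. instances exported from a de novo discovery
#' tool.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
    stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "motif_type")
  if (!all(need %in% names(df))) {
    stop("motif table needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write a long titration/FP table
#'
#' Long TSV with columns `series_id`, `x_value`, `x_unit`, `y_value`,
#' `y_sd`, `n`.
#'
#' @param df data.frame in that layout.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_series_table <- function(df, path) {
  need <- c("series_id", "x_value", "x_unit", "y_value", "y_sd", "n")
  stopifnot(all(need %in% names(df)))
  utils::write.table(df[need], path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Read a long titration/FP table
#'
#' @param path TSV path.
#' @return data.frame with columns `series_id`, `x_value`, `x_unit`,
#'   `y_value`, `y_sd`, `n`.
#' @export
read_series_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("series_id", "x_value", "x_unit", "y_value")
  if (!all(need %in% names(df))) {
    stop("series table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"y_sd" %in% names(df)) df$y_sd <- NA_real_
  if (!"n" %in% names(df)) df$n <- 1L
  df
}

#' Write a holdup result table with its JSON sidecar
#'
#' The TSV carries the per-protein results; the JSON sidecar records the
#' fitted threshold-curve parameters, the bait concentration, the seed and
#' the package version, which together suffice to reproduce the run.
#'
#' @param result a `"holdup_result"` from [run_nhu_pipeline()].
#' @param path output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return invisibly, the sidecar path.
#' @export
write_holdup_result <- function(result, path) {
  stopifnot(inherits(result, "holdup_result"))
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  curve <- attr(result, "threshold")
  meta <- list(
    package = "nhuquant",
    version = as.character(utils::packageVersion("nhuquant")),
    C_bait = attr(result, "C_bait"),
    seed = attr(result, "seed"),
    threshold = list(
      y0 = curve$y0, c = curve$c, x0 = curve$x0, sigma = curve$sigma,
      flag = curve$flag
    )
  )
  sidecar <- paste0(sub("\\.tsv$", "", path), ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
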