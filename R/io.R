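## TSV dialects: TIC tables (ND as empty field), peptide tables,
## truth labels, per-comparison results.

#' Write a TIC table as TSV
#'
#' Columns: `protein_id`, then one column per sample (`<state>_rep<k>`);
#' ND encoded as an empty field. `read_tic_table(write_tic_table(x))`
#' round-trips exactly.
#'
#' @param table a [tic_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tic_table <- function(table, path) {
  stopifnot(inherits(table, "tic_table"))
  df <- data.frame(protein_id = rownames(table$tic),
                   table$tic,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a TIC table from TSV
#'
#' Expects the dialect of [write_tic_table()]. Empty fields are ND; zero
#' intensities are normalized to ND with a warning (a TIC is ND or
#' positive, never zero). Ragged rows, non-numeric intensities and
#' duplicate protein ids are parse errors reported with line numbers.
#'
#' @param path file path.
#' @param states,replicates optional explicit per-column roles; by default
#'   parsed from the `<state>_rep<k>` sample ids.
#' @return A [tic_table()].
#' @export
read_tic_table <- function(path, states = NULL, replicates = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("TIC table file has no data rows: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "protein_id") {
    stop("first column must be 'protein_id' (line 1)", call. = FALSE)
  }
  # trailing ND cells drop the trailing tabs in some writers; pad instead
  # of rejecting, but reject rows with too many fields
  nf <- lengths(fields[-1])
  ragged <- which(nf > length(header))
  if (length(ragged)) {
    stop("ragged row(s) at line(s) ",
         paste(ragged + 1L, collapse = ", "), call. = FALSE)
  }
  n_samp <- length(header) - 1L
  protein_id <- character(length(lines) - 1L)
  tic <- matrix(NA_real_, length(lines) - 1L, n_samp)
  for (i in seq_along(protein_id)) {
    row <- fields[[i + 1L]]
    length(row) <- length(header)
    protein_id[i] <- row[1]
    cells <- row[-1]
    empty <- is.na(cells) | !nzchar(cells)
    vals <- suppressWarnings(as.numeric(cells))
    if (any(!empty & is.na(vals))) {
      stop("non-numeric intensity at line ", i + 1L, ": ",
           paste(sQuote(cells[!empty & is.na(vals)]), collapse = ", "),
           call. = FALSE)
    }
    tic[i, ] <- ifelse(empty, NA_real_, vals)
  }
  dup <- duplicated(protein_id)
  if (any(dup)) {
    stop("duplicate protein id(s) at line(s) ",
         paste(which(dup) + 1L, collapse = ", "), call. = FALSE)
  }
  if (any(tic == 0, na.rm = TRUE)) {
    warning(sum(tic == 0, na.rm = TRUE),
            " zero intensity value(s) ingested as ND")
    tic[!is.na(tic) & tic == 0] <- NA_real_
  }
  if (any(tic < 0, na.rm = TRUE)) {
    stop("negative intensity value(s) in ", path, call. = FALSE)
  }
  dimnames(tic) <- list(protein_id, header[-1])
  if (is.null(states)) {
    parsed <- parse_sample_ids(header[-1])
    states <- parsed$state
    replicates <- parsed$replicate
  }
  tic_table(tic, states = states, replicates = replicates)
}

#' Read a peptide-level intensity table from TSV
#'
#' Columns: `peptide_id`, `protein_id`, `sample_id`, `intensity`.
#' @param path file path.
#' @return data.frame suitable for [rollup_tic()].
#' @export
read_peptide_table <- function(path) {
  pep <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("peptide_id", "protein_id", "sample_id", "intensity")
  missing_cols <- setdiff(req, names(pep))
  if (length(missing_cols)) {
    stop("peptide table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(pep$intensity)) {
    stop("non-numeric 'intensity' column in ", path, call. = FALSE)
  }
  pep
}

#' Write per-comparison results as TSV
#'
#' The machine-readable analogue of a tiered differential-expression
#' table: columns `protein_id`, `Z0`, `Z1`, `R0`, `R1`, `znet`, `sn`,
#' `tier`, `direction`, `significant`, `fdr_reliable`, `nd_flag`.
#' Proteins excluded by the detection rule appear with `nd_flag = TRUE`
#' and empty statistics. A header comment records the sign convention.
#'
#' @param fit a [znet()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "znet_fit"))
  tab <- fit$table[c("protein_id", "Z0", "Z1", "R0", "R1", "znet", "sn",
                     "tier", "direction", "significant", "fdr_reliable")]
  tab$nd_flag <- FALSE
  if (length(fit$nd_proteins)) {
    nd <- tab[rep(NA_integer_, length(fit$nd_proteins)), ]
    nd$protein_id <- fit$nd_proteins
    nd$nd_flag <- TRUE
    tab <- rbind(tab, nd)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# comparison %s vs %s: positive Znet = higher in %s (first state minus second)",
    fit$comparison[1], fit$comparison[2], fit$comparison[1]), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write an FDR curve as TSV plus JSON metadata
#'
#' @param curve an [monte_carlo_fdr()] result.
#' @param path output TSV path (`cutoff`, `fdr`); a sidecar
#'   `<path>.json` records reps, seed and sn scale.
#' @return `path`, invisibly.
#' @export
write_fdr_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fdr_curve"))
  utils::write.table(curve[c("cutoff", "fdr")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(reps = attr(curve, "reps"), seed = attr(curve, "seed"),
         scale = attr(curve, "scale")),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
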