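#' Protein-by-sample TIC table
#'
#' A `tic_table` holds total ion count (TIC) values for a set of proteins
#' across samples, together with the (state, replicate) role of each sample.
#' TIC is the sum of collision-induced-dissociation fragment intensities over
#' a protein's identified peptides in one sample; a protein with no recorded
#' TIC in a sample is not detected (ND), stored as `NA`. A TIC is ND or
#' strictly positive, never zero.
#'
#' @param tic numeric matrix, proteins in rows (rownames are protein ids),
#'   samples in columns (colnames are sample ids). `NA` encodes ND.
#' @param states character vector, one state label per column of `tic`.
#' @param replicates integer vector, one replicate index per column.
#' @return An object of class `tic_table`: a list with elements `tic`
#'   (the matrix) and `samples` (data.frame with columns `sample_id`,
#'   `state`, `replicate`).
#' @examples
#' m <- matrix(2^rnorm(8, 20), 2, 4,
#'             dimnames = list(c("P1", "P2"),
#'                             c("A_rep1", "A_rep2", "B_rep1", "B_rep2")))
#' tic_table(m, states = c("A", "A", "B", "B"), replicates = c(1, 2, 1, 2))
#' @export
tic_table <- function(tic, states, replicates) {
  if (!is.matrix(tic) || !is.numeric(tic)) {
    stop("'tic' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(tic)) || is.null(colnames(tic))) {
    stop("'tic' must have protein ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(tic))) {
    stop("duplicate protein ids in TIC table", call. = FALSE)
  }
  if (length(states) != ncol(tic) || length(replicates) != ncol(tic)) {
    stop("'states' and 'replicates' must have one entry per sample column",
         call. = FALSE)
  }
  if (any(tic <= 0, na.rm = TRUE)) {
    stop("TIC values must be positive or ND (NA); zero/negative found",
         call. = FALSE)
  }
  samples <- data.frame(
    sample_id = colnames(tic),
    state = as.character(states),
    replicate = as.integer(replicates),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(samples[c("state", "replicate")])) {
    stop("each (state, replicate) pair may map to only one sample",
         call. = FALSE)
  }
  structure(list(tic = tic, samples = samples), class = "tic_table")
}

#' @export
print.tic_table <- function(x, ...) {
  st <- split(x$samples$sample_id, x$samples$state)
  cat(sprintf("TIC table: %d proteins x %d samples\n",
              nrow(x$tic), ncol(x$tic)))
  for (s in names(st)) {
    cat(sprintf("  state %-12s %s\n", s, paste(st[[s]], collapse = ", ")))
  }
  nd <- sum(is.na(x$tic))
  cat(sprintf("  ND entries: %d (%.1f%%)\n", nd, 100 * nd / length(x$tic)))
  invisible(x)
}

#' @export
dim.tic_table <- function(x) dim(x$tic)

# Columns of the TIC matrix for one state, ordered by replicate index.
# Errors unless the state has exactly two replicates (the supported design).
state_columns <- function(table, state) {
  idx <- which(table$samples$state == state)
  if (length(idx) == 0L) {
    stop(sprintf("state '%s' not present in TIC table", state),
         call. = FALSE)
  }
  if (length(idx) != 2L) {
    stop(sprintf(
      "unsupported design: state '%s' has %d replicates (exactly 2 required)",
      state, length(idx)), call. = FALSE)
  }
  idx[order(table$samples$replicate[idx])]
}

check_comparison <- function(table, comparison) {
  if (!is.character(comparison) || length(comparison) != 2L ||
      comparison[1] == comparison[2]) {
    stop("'comparison' must name two distinct states", call. = FALSE)
  }
  invisible(comparison)
}
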