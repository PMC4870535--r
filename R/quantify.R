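#' Roll peptide intensities up to protein TIC values
#'
#' The total ion count (TIC) of a protein in a sample is the sum of the
#' summed fragment intensities of its member peptides in that sample.
#' Proteins with no peptide observation in a sample are not detected (ND)
#' there. Duplicate (peptide, sample) rows are aggregated by summation with
#' a warning; negative intensities are an error, zero intensities are
#' dropped with a warning (a TIC is ND or positive, never zero).
#'
#' @param peptides data.frame with columns `peptide_id`, `protein_id`,
#'   `sample_id`, `intensity`.
#' @param states,replicates optional per-sample roles, one entry per
#'   distinct `sample_id` (in sorted order). If omitted, sample ids must
#'   follow the `<state>_rep<k>` convention, from which roles are parsed.
#' @return A [tic_table()].
#' @examples
#' pep <- data.frame(peptide_id = c("q1", "q2", "q1", "q2"),
#'                   protein_id = "P1",
#'                   sample_id = rep(c("A_rep1", "A_rep2"), each = 2),
#'                   intensity = c(100, 50, 90, 60))
#' rollup_tic(pep)$tic
#' @export
rollup_tic <- function(peptides, states = NULL, replicates = NULL) {
  req <- c("peptide_id", "protein_id", "sample_id", "intensity")
  if (!is.data.frame(peptides) || !all(req %in% names(peptides))) {
    stop("'peptides' must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(peptides) == 0L) {
    stop("empty peptide table", call. = FALSE)
  }
  if (any(!is.finite(peptides$intensity)) || any(peptides$intensity < 0)) {
    stop("peptide intensities must be finite and nonnegative",
         call. = FALSE)
  }
  if (any(peptides$intensity == 0)) {
    warning("dropping ", sum(peptides$intensity == 0),
            " zero-intensity peptide row(s); TIC is ND or positive")
    peptides <- peptides[peptides$intensity > 0, , drop = FALSE]
    if (nrow(peptides) == 0L) stop("no positive peptide rows remain",
                                   call. = FALSE)
  }
  dup <- duplicated(peptides[c("peptide_id", "sample_id")])
  if (any(dup)) {
    warning("aggregating ", sum(dup),
            " duplicate (peptide_id, sample_id) row(s) by summation")
  }
  proteins <- sort(unique(peptides$protein_id))
  samples <- sort(unique(peptides$sample_id))
  tic <- with(peptides, tapply(
    intensity,
    list(factor(protein_id, proteins), factor(sample_id, samples)),
    sum
  ))
  if (is.null(states)) {
    parsed <- parse_sample_ids(samples)
    states <- parsed$state
    replicates <- parsed$replicate
  }
  tic_table(tic, states = states, replicates = replicates)
}

parse_sample_ids <- function(sample_ids) {
  m <- regmatches(sample_ids, regexec("^(.+)_rep([0-9]+)$", sample_ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("cannot parse sample id(s) ",
         paste(sQuote(sample_ids[bad]), collapse = ", "),
         "; expected '<state>_rep<k>' or explicit states/replicates",
         call. = FALSE)
  }
  data.frame(
    state = vapply(m, `[`, "", 2L),
    replicate = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Apply the both-replicates detection rule
#'
#' Retains exactly the proteins observed (non-ND) in all four samples of a
#' two-state comparison: both replicates of both states. Excluded protein
#' ids are attached as attribute `"nd_proteins"` so downstream reports can
#' flag them as ND. The operation is idempotent.
#'
#' @param table a [tic_table()].
#' @param comparison character(2), the two state labels; defaults to all
#'   states of the table (which must then be exactly two).
#' @return A [tic_table()] restricted to the comparison's four samples and
#'   fully observed proteins, with attribute `nd_proteins`.
#' @examples
#' sim <- simulate_tic_experiment(
#'   sim_config(n_proteins = 30, dropout_prob = 0.2, seed = 2))
#' filtered <- filter_detected(sim$table)
#' length(attr(filtered, "nd_proteins"))
#' @export
filter_detected <- function(table, comparison = NULL) {
  stopifnot(inherits(table, "tic_table"))
  if (is.null(comparison)) {
    comparison <- unique(table$samples$state)
    if (length(comparison) != 2L) {
      stop("'comparison' must be given when the table has more than two ",
           "states", call. = FALSE)
    }
  }
  check_comparison(table, comparison)
  cols <- c(state_columns(table, comparison[1]),
            state_columns(table, comparison[2]))
  sub <- table$tic[, cols, drop = FALSE]
  keep <- rowSums(is.na(sub)) == 0L
  out <- tic_table(sub[keep, , drop = FALSE],
                   states = table$samples$state[cols],
                   replicates = table$samples$replicate[cols])
  attr(out, "nd_proteins") <- rownames(table$tic)[!keep]
  out
}

#' Replicate correlation quality control
#'
#' Pearson correlation of log2 TIC between the two biological replicates of
#' one state, over proteins detected in both. Under the generative model
#' with between-protein baseline spread `s_b` and replicate noise `s_r`
#' (both log2-scale), the expected value is `s_b^2 / (s_b^2 + s_r^2)`.
#'
#' @param table a [tic_table()].
#' @param state state label.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @examples
#' sim <- simulate_tic_experiment(sim_config(n_proteins = 200, seed = 5))
#' replicate_correlation(sim$table, "state1")
#' @export
replicate_correlation <- function(table, state) {
  stopifnot(inherits(table, "tic_table"))
  cols <- state_columns(table, state)
  x <- table$tic[, cols[1]]
  y <- table$tic[, cols[2]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    stop(sprintf(
      "insufficient data: %d protein(s) co-detected in both replicates of '%s' (>= 3 required)",
      sum(ok), state), call. = FALSE)
  }
  stats::cor(log2(x[ok]), log2(y[ok]))
}
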