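#' Cross-state and intra-replicate log2-ratio populations
#'
#' For a two-state by two-replicate comparison, computes per protein the two
#' cross-state log2 differences, pairing replicates by index,
#' \deqn{Z_0 = \log_2 TIC_{A,1} - \log_2 TIC_{B,1}, \quad
#'       Z_1 = \log_2 TIC_{A,2} - \log_2 TIC_{B,2},}
#' and the two intra-replicate log2 differences, one per state,
#' \deqn{R_0 = \log_2 TIC_{A,1} - \log_2 TIC_{A,2}, \quad
#'       R_1 = \log_2 TIC_{B,1} - \log_2 TIC_{B,2},}
#' where A is the first-named state: positive Z means higher expression in
#' the first-named state. The cross-state populations carry the biological
#' signal; the intra-replicate populations are the noise reference.
#'
#' @param table a [tic_table()] that already passed [filter_detected()] for
#'   this comparison (ND entries are an error here).
#' @param comparison character(2), the two state labels (first minus
#'   second); defaults to the table's states.
#' @return An object of class `ratio_populations`: list with `protein_id`,
#'   numeric vectors `Z0`, `Z1`, `R0`, `R1`, the `comparison`, and `label`
#'   (`"A_vs_B"`).
#' @examples
#' sim <- simulate_tic_experiment(sim_config(n_proteins = 20, seed = 1))
#' pops <- ratio_populations(sim$table)
#' head(pops$Z0)
#' @export
ratio_populations <- function(table, comparison = NULL) {
  stopifnot(inherits(table, "tic_table"))
  if (is.null(comparison)) {
    comparison <- unique(table$samples$state)
    if (length(comparison) != 2L) {
      stop("'comparison' must be given when the table has more than two ",
           "states", call. = FALSE)
    }
  }
  check_comparison(table, comparison)
  a <- state_columns(table, comparison[1])
  b <- state_columns(table, comparison[2])
  m <- table$tic[, c(a, b), drop = FALSE]
  if (anyNA(m)) {
    stop("TIC table contains ND entries for this comparison; ",
         "apply filter_detected() first", call. = FALSE)
  }
  l2 <- log2(m)
  structure(list(
    protein_id = rownames(m),
    Z0 = unname(l2[, 1] - l2[, 3]),
    Z1 = unname(l2[, 2] - l2[, 4]),
    R0 = unname(l2[, 1] - l2[, 2]),
    R1 = unname(l2[, 3] - l2[, 4]),
    comparison = comparison,
    label = paste(comparison, collapse = "_vs_"),
    log2_tic = unname(l2)
  ), class = "ratio_populations")
}

#' @export
print.ratio_populations <- function(x, ...) {
  cat(sprintf("Ratio populations: %s (n = %d proteins)\n",
              x$label, length(x$protein_id)))
  cat(sprintf("  sd(Z0) = %.3f  sd(Z1) = %.3f  sd(R0) = %.3f  sd(R1) = %.3f\n",
              stats::sd(x$Z0), stats::sd(x$Z1),
              stats::sd(x$R0), stats::sd(x$R1)))
  invisible(x)
}

#' Normalize a ratio population to mean 0, standard deviation 1
#'
#' Centering and scaling by the sample (n-1) standard deviation; rank order
#' is preserved and affine-transformed inputs map to identical output.
#'
#' @param values numeric vector, length >= 2, with nonzero spread.
#' @param name population name used in the degenerate-population error.
#' @return Numeric vector with mean 0 and sd 1 (to numerical tolerance).
#' @examples
#' normalize_population(c(10, 20))
#' @export
normalize_population <- function(values, name = "population") {
  if (!is.numeric(values) || length(values) < 2L) {
    stop(sprintf("population '%s' needs >= 2 values", name), call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop(sprintf("population '%s' contains non-finite values", name),
         call. = FALSE)
  }
  s <- sd_checked(values, name)
  (values - mean(values)) / s
}

# Normalize the three populations: Z0 and Z1 each on their own, R0 and R1
# pooled (they are two draws of the same noise reference).
normalize_ratio_populations <- function(pops) {
  stopifnot(inherits(pops, "ratio_populations"))
  n <- length(pops$Z0)
  r <- normalize_population(c(pops$R0, pops$R1), "R (pooled)")
  list(
    z0 = normalize_population(pops$Z0, "Z0"),
    z1 = normalize_population(pops$Z1, "Z1"),
    r0 = r[seq_len(n)],
    r1 = r[n + seq_len(n)]
  )
}

#' Merge normalized cross-state scores into Znet
#'
#' Per protein, Znet is the mean of the two normalized cross-state values,
#' renormalized so the Znet population again has mean 0 and standard
#' deviation 1. On a pure-null population Znet is standard normal, so the
#' fixed cutoffs 1.0 / 1.65 / 1.96 delimit the outermost 33% / 10% / 5%.
#'
#' @param pops a [ratio_populations()] object; normalization of the three
#'   populations (Z0, Z1, pooled R) is performed internally.
#' @return A list with `znet` (named numeric), the normalized populations
#'   `z0`, `z1`, `r0`, `r1`, and `pre_znet` (the per-protein mean before
#'   renormalization).
#' @examples
#' sim <- simulate_tic_experiment(sim_config(n_proteins = 50, seed = 4))
#' z <- merge_znet(ratio_populations(sim$table))
#' sd(z$znet)
#' @export
merge_znet <- function(pops) {
  norm <- normalize_ratio_populations(pops)
  pre <- (norm$z0 + norm$z1) / 2
  znet <- normalize_population(pre, "Znet")
  names(znet) <- pops$protein_id
  c(list(znet = znet, pre_znet = pre), norm)
}

#' Assign tiered significance levels to Znet scores
#'
#' Tiers by strict comparison of |Znet| against the three population
#' cutoffs: `> 1.96` outermost 5% (`"outer5"`), `> 1.65` outermost 10%
#' (`"outer10"`), `> 1.0` outermost 33% (`"outer33"`), otherwise `"inner"`.
#' A protein is called significant when it reaches the outer 10% tier.
#' Direction is the sign of Znet: positive means higher expression in the
#' first-named state.
#'
#' @param znet numeric vector of Znet scores.
#' @param tiers increasing numeric(3) of tier cutoffs.
#' @return data.frame with columns `znet`, `tier` (factor), `direction`
#'   (`"up"`, `"down"`, `"none"`), `significant` (logical, outer 10% or
#'   beyond).
#' @examples
#' classify_tiers(c(2.96, -1.84, 0.35))
#' @export
classify_tiers <- function(znet, tiers = c(1.0, 1.65, 1.96)) {
  stopifnot(is.numeric(tiers), length(tiers) == 3L, !is.unsorted(tiers))
  a <- abs(znet)
  tier <- ifelse(a > tiers[3], "outer5",
          ifelse(a > tiers[2], "outer10",
          ifelse(a > tiers[1], "outer33", "inner")))
  data.frame(
    znet = unname(znet),
    tier = factor(tier, levels = c("inner", "outer33", "outer10", "outer5")),
    direction = ifelse(znet > 0, "up", ifelse(znet < 0, "down", "none")),
    significant = a > tiers[2],
    row.names = names(znet),
    stringsAsFactors = FALSE
  )
}
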