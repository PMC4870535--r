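#' Fit the Znet differential-expression model to a TIC table
#'
#' The central fitting function. For one two-state by two-replicate
#' comparison it (i) applies the both-replicates detection rule, (ii)
#' computes the cross-state (Z0, Z1) and intra-replicate (R0, R1)
#' log2-ratio populations, (iii) normalizes the three populations (Z0, Z1,
#' pooled R) to mean 0 / sd 1, (iv) merges the normalized cross-state
#' values into a single Znet score per protein (mean of the two, then
#' renormalized to unit sd), (v) assigns significance tiers at
#' |Znet| > 1.0 / 1.65 / 1.96 (outermost 33% / 10% / 5% of a null
#' population) with direction from the sign, and (vi) computes the system
#' and per-protein signal-to-noise statistics, flagging proteins with
#' sn above the FDR-calibrated cutoff as reliable.
#'
#' Positive Znet means higher expression in the first-named state.
#'
#' @param table a [tic_table()] (proteins not observed in all four samples
#'   of the comparison are set aside and reported as ND).
#' @param comparison character(2): the two states, first minus second;
#'   defaults to the table's two states.
#' @param tiers increasing numeric(3) tier cutoffs.
#' @param sn_cutoff per-protein signal-to-noise cutoff for the
#'   FDR-reliable flag.
#' @param sn_scale `"normalized"` or `"raw"`, see [protein_sn()].
#' @return An object of class `znet_fit` with components
#'   \describe{
#'     \item{table}{per-protein data.frame: `protein_id`, raw `Z0`, `Z1`,
#'       `R0`, `R1`, normalized `z0`, `z1`, `r0`, `r1`, `znet`, `sn`,
#'       `tier`, `direction`, `significant`, `fdr_reliable`.}
#'     \item{system_sn}{dataset-level signal-to-noise ratio.}
#'     \item{replicate_cor}{named Pearson log2 replicate correlations, one
#'       per state (NA when fewer than 3 co-detected proteins).}
#'     \item{nd_proteins}{ids excluded by the detection rule.}
#'     \item{pops, comparison, label, tiers, sn_cutoff, sn_scale, n_input,
#'       n_retained}{supporting pieces.}
#'   }
#' @examples
#' sim <- simulate_tic_experiment(sim_config(preset = "paperlike", seed = 1))
#' fit <- znet(sim$table)
#' fit
#' head(coef(fit))
#' @seealso [monte_carlo_fdr()] to calibrate `sn_cutoff`,
#'   [cog_crosstab()] and [overlap_counts()] to summarize fits.
#' @export
znet <- function(table, comparison = NULL, tiers = c(1.0, 1.65, 1.96),
                 sn_cutoff = 2.8, sn_scale = c("normalized", "raw")) {
  stopifnot(inherits(table, "tic_table"))
  sn_scale <- match.arg(sn_scale)
  filtered <- filter_detected(table, comparison)
  comparison <- unique(filtered$samples$state)
  pops <- ratio_populations(filtered, comparison)
  merged <- merge_znet(pops)
  cls <- classify_tiers(merged$znet, tiers)
  sn <- protein_sn(pops, scale = sn_scale)

  rep_cor <- vapply(comparison, function(s) {
    tryCatch(replicate_correlation(filtered, s),
             error = function(e) NA_real_)
  }, numeric(1))

  tab <- data.frame(
    protein_id = pops$protein_id,
    Z0 = pops$Z0, Z1 = pops$Z1, R0 = pops$R0, R1 = pops$R1,
    z0 = merged$z0, z1 = merged$z1, r0 = merged$r0, r1 = merged$r1,
    znet = unname(merged$znet),
    sn = unname(sn),
    tier = cls$tier,
    direction = cls$direction,
    significant = cls$significant,
    fdr_reliable = unname(sn) > sn_cutoff,
    stringsAsFactors = FALSE
  )
  structure(list(
    call = match.call(),
    comparison = comparison,
    label = pops$label,
    n_input = nrow(table$tic),
    n_retained = nrow(tab),
    nd_proteins = attr(filtered, "nd_proteins"),
    table = tab,
    pops = pops,
    system_sn = attr(sn, "system_sn"),
    replicate_cor = rep_cor,
    tiers = tiers,
    sn_cutoff = sn_cutoff,
    sn_scale = sn_scale
  ), class = "znet_fit")
}

#' @export
print.znet_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Znet differential expression fit: %s vs %s\n",
              x$comparison[1], x$comparison[2]))
  cat(sprintf("  (positive Znet = higher in %s)\n", x$comparison[1]))
  cat(sprintf("  proteins: %d input, %d detected in all four samples, %d ND\n",
              x$n_input, x$n_retained, length(x$nd_proteins)))
  cat(sprintf("  system S/N: %.*f\n", digits, x$system_sn))
  cat(sprintf("  significant (|Znet| > %.2f): %d up, %d down\n",
              x$tiers[2],
              sum(x$table$significant & x$table$direction == "up"),
              sum(x$table$significant & x$table$direction == "down")))
  cat(sprintf("  FDR-reliable (S/N > %.2f): %d\n",
              x$sn_cutoff, sum(x$table$fdr_reliable)))
  invisible(x)
}

#' @export
summary.znet_fit <- function(object, ...) {
  tab <- object$table
  out <- list(
    label = object$label,
    comparison = object$comparison,
    n_input = object$n_input,
    n_retained = object$n_retained,
    n_nd = length(object$nd_proteins),
    system_sn = object$system_sn,
    replicate_cor = object$replicate_cor,
    tier_counts = table(tab$tier),
    direction_counts = table(tab$direction[tab$significant]),
    n_reliable = sum(tab$fdr_reliable),
    sn_cutoff = object$sn_cutoff,
    tiers = object$tiers
  )
  class(out) <- "summary.znet_fit"
  out
}

#' @export
print.summary.znet_fit <- function(x, ...) {
  cat(sprintf("Comparison %s (first state minus second)\n", x$label))
  cat(sprintf("  detected in both replicates of both states: %d / %d (%d ND)\n",
              x$n_retained, x$n_input, x$n_nd))
  cat(sprintf("  replicate log2 correlations: %s\n",
              paste(sprintf("%s %.3f", names(x$replicate_cor),
                            x$replicate_cor), collapse = ", ")))
  cat(sprintf("  system S/N: %.3f\n", x$system_sn))
  cat("  tier counts:\n")
  print(x$tier_counts)
  cat(sprintf("  significant up/down at |Znet| > %.2f: %s\n", x$tiers[2],
              paste(names(x$direction_counts), x$direction_counts,
                    collapse = ", ")))
  cat(sprintf("  FDR-reliable at S/N > %.2f: %d\n", x$sn_cutoff,
              x$n_reliable))
  invisible(x)
}

#' @export
coef.znet_fit <- function(object, ...) {
  stats::setNames(object$table$znet, object$table$protein_id)
}

#' Normalized intra-replicate values of a Znet fit
#'
#' The noise component of the model: the unit-sd normalized within-state
#' replicate differences, one column per state.
#' @param object a [znet()] fit.
#' @param ... unused.
#' @return Numeric matrix (proteins x 2).
#' @export
residuals.znet_fit <- function(object, ...) {
  m <- cbind(r0 = object$table$r0, r1 = object$table$r1)
  rownames(m) <- object$table$protein_id
  m
}

#' Permutation-null replicates of a Znet fit
#'
#' Draws datasets from the fit's Monte-Carlo null: each protein's four
#' log2 TIC values are reassigned to state/replicate roles by a uniform
#' state-mixing permutation, destroying cross-state structure while
#' preserving intra-replicate noise. Used internally by
#' [monte_carlo_fdr()]; exposed for diagnostics.
#'
#' @param object a [znet()] fit.
#' @param nsim number of null replicates.
#' @param seed integer seed, required for reproducibility.
#' @param ... unused.
#' @return A list of `nsim` [ratio_populations()] objects.
#' @export
simulate.znet_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) {
    stop("field 'seed' is required", call. = FALSE)
  }
  with_seed(seed, replicate(nsim, permute_populations(object$pops),
                            simplify = FALSE))
}

#' Diagnostic plots for a Znet fit
#'
#' Two panels: the Znet score distribution with tier cutoffs, and
#' per-protein S/N against Znet with the FDR-calibrated cutoff.
#' @param x a [znet()] fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.znet_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::hist(x$table$znet, breaks = 50, main = x$label,
                 xlab = "Znet", ...)
  graphics::abline(v = c(-1, 1) %o% x$tiers, lty = 3)
  sn <- pmin(x$table$sn, 50)
  graphics::plot(x$table$znet, sn, pch = 16, cex = 0.4,
                 xlab = "Znet", ylab = "per-protein S/N (capped at 50)",
                 main = sprintf("system S/N = %.2f", x$system_sn))
  graphics::abline(h = x$sn_cutoff, lty = 3)
  invisible(x)
}
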