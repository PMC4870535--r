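#' System signal-to-noise ratio
#'
#' Dataset-level quality measure: the mean of the standard deviations of
#' the two cross-state populations divided by the mean of the standard
#' deviations of the two intra-replicate populations,
#' \deqn{S/N_{sys} = \frac{(sd(Z_0)+sd(Z_1))/2}{(sd(R_0)+sd(R_1))/2}.}
#' A well-powered two-state experiment shows cross-state spread several
#' times the replicate noise; a ratio of 5 or more indicates strong global
#' differential signal.
#'
#' @param pops a [ratio_populations()] object with >= 2 proteins.
#' @return Positive scalar.
#' @examples
#' sim <- simulate_tic_experiment(sim_config(preset = "paperlike", seed = 1))
#' system_sn(ratio_populations(filter_detected(sim$table)))
#' @export
system_sn <- function(pops) {
  stopifnot(inherits(pops, "ratio_populations"))
  if (length(pops$Z0) < 2L) {
    stop("system S/N needs >= 2 proteins", call. = FALSE)
  }
  num <- mean(c(stats::sd(pops$Z0), stats::sd(pops$Z1)))
  den <- mean(c(sd_checked(pops$R0, "R0"), sd_checked(pops$R1, "R1")))
  num / den
}

#' Per-protein signal-to-noise statistic
#'
#' Ratio of the protein's cross-state vector magnitude to its
#' intra-replicate vector magnitude. With `scale = "normalized"` (default)
#' the magnitudes are taken on the unit-sd normalized populations,
#' \deqn{sn_i = \sqrt{z_{0i}^2 + z_{1i}^2} / \sqrt{r_{0i}^2 + r_{1i}^2},}
#' so the scaling by the overall system signal-to-noise is realized through
#' the population normalization. With `scale = "raw"` the raw magnitudes
#' are used and the ratio is divided by [system_sn()]; the two coincide
#' when sd(Z0) = sd(Z1) and sd(R0) = sd(R1). A protein whose
#' intra-replicate magnitude is exactly zero is maximally
#' replicate-consistent and gets `sn = Inf`, flagged in the
#' `"infinite_sn"` attribute.
#'
#' When the four population values of a protein are independent standard
#' normals, `sn^2` follows the F(2,2) distribution, so
#' `P(sn > c) = 1 / (1 + c^2)`; the cutoff 2.8 then bounds the null
#' exceedance at ~11%. On tables from the two-state four-sample design the
#' Z and R populations share the replicate-noise contrast Z0 - Z1 = R0 - R1,
#' which makes the observed null tail lighter than this bound (the cutoff
#' is conservative there).
#'
#' @param pops a [ratio_populations()] object.
#' @param scale `"normalized"` (default) or `"raw"`.
#' @return Named numeric vector of nonnegative (possibly infinite) sn
#'   values, with attributes `system_sn` and `infinite_sn` (protein ids
#'   with zero intra-replicate magnitude).
#' @examples
#' sim <- simulate_tic_experiment(sim_config(n_proteins = 100, seed = 9))
#' sn <- protein_sn(ratio_populations(sim$table))
#' summary(sn)
#' @export
protein_sn <- function(pops, scale = c("normalized", "raw")) {
  stopifnot(inherits(pops, "ratio_populations"))
  scale <- match.arg(scale)
  sys <- system_sn(pops)
  if (scale == "normalized") {
    norm <- normalize_ratio_populations(pops)
    num <- sqrt(norm$z0^2 + norm$z1^2)
    den <- sqrt(norm$r0^2 + norm$r1^2)
    sn <- num / den
  } else {
    num <- sqrt(pops$Z0^2 + pops$Z1^2)
    den <- sqrt(pops$R0^2 + pops$R1^2)
    sn <- (num / den) / sys
  }
  # exactly zero replicate disagreement: after centering the pooled R
  # population the denominator would be a pure population-mean artifact,
  # so flag such proteins as infinite rather than huge-but-arbitrary
  zero_noise <- pops$R0 == 0 & pops$R1 == 0
  sn[zero_noise] <- Inf
  sn[(num == 0 & den == 0) |
       (zero_noise & pops$Z0 == 0 & pops$Z1 == 0)] <- 0  # silent protein
  names(sn) <- pops$protein_id
  attr(sn, "system_sn") <- sys
  attr(sn, "infinite_sn") <- pops$protein_id[is.infinite(sn)]
  attr(sn, "scale") <- scale
  sn
}

#' Flag FDR-reliable proteins by signal-to-noise cutoff
#'
#' Marks proteins with `sn > cutoff` (strict) as FDR-reliable. Proteins
#' with infinite sn (zero intra-replicate disagreement) pass the filter
#' with a warning rather than being silently excluded. The flag is carried
#' independently of the |Znet| tier: tiered tables use the |Znet| > 1.65
#' rule while differential-protein counts use the sn rule.
#'
#' @param fit a [znet()] fit.
#' @param cutoff positive cutoff, default 2.8 (calibrated to ~10% FDR in
#'   a strong-separation experiment).
#' @return The fit with `table$fdr_reliable` updated and `sn_cutoff` set.
#' @export
apply_sn_filter <- function(fit, cutoff = 2.8) {
  stopifnot(inherits(fit, "znet_fit"))
  check_number(cutoff, "cutoff", lower = 0)
  inf_pass <- is.infinite(fit$table$sn)
  if (any(inf_pass)) {
    warning(sum(inf_pass), " protein(s) with infinite S/N ",
            "(zero intra-replicate magnitude) pass the filter")
  }
  fit$table$fdr_reliable <- fit$table$sn > cutoff
  fit$sn_cutoff <- cutoff
  fit
}

# One permutation-null replicate: for each protein, reassign the four log2
# values to roles (A1, A2, B1, B2) by a uniform draw over the 4 role maps
# whose state partition differs from the original within-state pairing, so
# that the cross-state structure is destroyed while each protein's own
# values (hence its intra-replicate noise level) are preserved.
PERM_ROLE_MAPS <- rbind(
  c(1L, 3L, 2L, 4L),
  c(1L, 3L, 4L, 2L),
  c(1L, 4L, 2L, 3L),
  c(1L, 4L, 3L, 2L)
)

# Score a (possibly permuted) set of ratio populations against fixed
# normalization constants taken from the observed data. A Monte-Carlo null
# protein is embedded in the observed dataset, so its normalized values --
# and hence its sn -- are computed with the observed population means/sds
# (for scale = "raw", with the observed system S/N).
sn_reference <- function(pops, scale) {
  list(
    scale = scale,
    m_z0 = mean(pops$Z0), s_z0 = sd_checked(pops$Z0, "Z0"),
    m_z1 = mean(pops$Z1), s_z1 = sd_checked(pops$Z1, "Z1"),
    m_r = mean(c(pops$R0, pops$R1)),
    s_r = sd_checked(c(pops$R0, pops$R1), "R (pooled)"),
    system_sn = system_sn(pops)
  )
}

protein_sn_ref <- function(pops, ref) {
  if (ref$scale == "normalized") {
    z0 <- (pops$Z0 - ref$m_z0) / ref$s_z0
    z1 <- (pops$Z1 - ref$m_z1) / ref$s_z1
    r0 <- (pops$R0 - ref$m_r) / ref$s_r
    r1 <- (pops$R1 - ref$m_r) / ref$s_r
    num <- sqrt(z0^2 + z1^2)
    den <- sqrt(r0^2 + r1^2)
    sn <- num / den
  } else {
    num <- sqrt(pops$Z0^2 + pops$Z1^2)
    den <- sqrt(pops$R0^2 + pops$R1^2)
    sn <- (num / den) / ref$system_sn
  }
  sn[num == 0 & den == 0] <- 0
  sn
}

permute_populations <- function(pops) {
  l2 <- pops$log2_tic
  n <- nrow(l2)
  v <- sample.int(4L, n, replace = TRUE)
  roles <- PERM_ROLE_MAPS[v, , drop = FALSE]
  idx <- function(k) l2[cbind(seq_len(n), roles[, k])]
  a1 <- idx(1L); a2 <- idx(2L); b1 <- idx(3L); b2 <- idx(4L)
  out <- pops
  out$Z0 <- a1 - b1
  out$Z1 <- a2 - b2
  out$R0 <- a1 - a2
  out$R1 <- b1 - b2
  out$log2_tic <- cbind(a1, a2, b1, b2)
  out
}

#' Monte-Carlo FDR calibration of the signal-to-noise cutoff
#'
#' Estimates, for each cutoff c on a grid, the false discovery rate of the
#' rule `sn > c` as \eqn{FDR(c) = E[N_{null}(c)] / N_{obs}(c)}:
#' `N_obs(c)` is the observed number of proteins exceeding c and
#' `N_null(c)` is the exceedance count in a Monte-Carlo null dataset in
#' which each protein's state labels are permuted (state-mixing role
#' reassignment of its four log2 values), destroying the cross-state
#' structure while preserving the intra-replicate noise; the expectation is
#' the average over `reps` permutation replicates. Permuted values are
#' scored against the observed populations' normalization constants (a
#' Monte-Carlo null protein is embedded in the observed dataset), so the
#' shrinkage induced by the observed cross-state/intra-replicate variance
#' ratio applies to null replicates exactly as to real proteins. Estimates are clipped to \[0, 1\] and made nonincreasing in c
#' by a running minimum; cutoffs with no observed discoveries get `NA`.
#'
#' @param fit a [znet()] fit (or a [ratio_populations()] object).
#' @param cutoffs ascending grid of sn cutoffs.
#' @param reps number of Monte-Carlo replicates (>= 100).
#' @param seed integer seed, required.
#' @return An object of class `fdr_curve`: data.frame with columns
#'   `cutoff`, `n_obs`, `mean_null`, `fdr`, and attributes `reps`, `seed`,
#'   `scale`.
#' @examples
#' sim <- simulate_tic_experiment(sim_config(preset = "paperlike",
#'                                           n_proteins = 300, seed = 2))
#' fit <- znet(sim$table)
#' curve <- monte_carlo_fdr(fit, reps = 100, seed = 11)
#' fdr_at(curve, 2.8)
#' @export
monte_carlo_fdr <- function(fit, cutoffs = round(seq(0, 10, by = 0.1), 10),
                            reps = 500, seed) {
  pops <- if (inherits(fit, "znet_fit")) fit$pops else fit
  stopifnot(inherits(pops, "ratio_populations"))
  scale <- if (inherits(fit, "znet_fit")) fit$sn_scale else "normalized"
  if (missing(seed)) {
    stop("field 'seed' is required for the Monte-Carlo null", call. = FALSE)
  }
  check_number(reps, "reps", lower = 100, integer = TRUE)
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("'cutoffs' must be strictly ascending", call. = FALSE)
  }
  exceed <- function(sn) {
    s <- sort(sn[is.finite(sn)])
    n_inf <- sum(is.infinite(sn))  # +Inf exceeds every finite cutoff
    (length(s) - findInterval(cutoffs, s)) + n_inf
  }
  n_obs <- exceed(protein_sn(pops, scale = scale))
  ref <- sn_reference(pops, scale)
  null_tot <- numeric(length(cutoffs))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      null_sn <- protein_sn_ref(permute_populations(pops), ref)
      null_tot <- null_tot + exceed(null_sn)
    }
  })
  mean_null <- null_tot / reps
  fdr <- ifelse(n_obs > 0, pmin(1, mean_null / n_obs), NA_real_)
  # enforce monotone nonincreasing FDR in the cutoff
  run <- Inf
  for (i in seq_along(fdr)) {
    if (!is.na(fdr[i])) {
      run <- min(run, fdr[i])
      fdr[i] <- run
    }
  }
  structure(
    data.frame(cutoff = cutoffs, n_obs = n_obs,
               mean_null = mean_null, fdr = fdr),
    reps = reps, seed = as.integer(seed), scale = scale,
    class = c("fdr_curve", "data.frame")
  )
}

#' Look up the estimated FDR at a cutoff
#'
#' @param curve an [monte_carlo_fdr()] result.
#' @param cutoff sn cutoff; the estimate at the largest grid point not
#'   exceeding `cutoff` is returned.
#' @return FDR estimate in \[0, 1\], or `NA` if undefined there.
#' @export
fdr_at <- function(curve, cutoff = 2.8) {
  stopifnot(inherits(curve, "fdr_curve"))
  i <- findInterval(cutoff, curve$cutoff)
  if (i < 1L) {
    stop("cutoff below the calibration grid", call. = FALSE)
  }
  curve$fdr[i]
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo FDR curve: %d cutoffs in [%g, %g], %d permutation reps (seed %d)\n",
    nrow(x), min(x$cutoff), max(x$cutoff), attr(x, "reps"), attr(x, "seed")))
  show <- x[x$cutoff %in% c(1, 2, 2.8, 4, 6), , drop = FALSE]
  if (nrow(show)) print.data.frame(show, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.fdr_curve <- function(x, ...) {
  ok <- !is.na(x$fdr)
  graphics::plot(x$cutoff[ok], x$fdr[ok], type = "s",
                 xlab = "S/N cutoff", ylab = "estimated FDR",
                 main = "Monte-Carlo FDR calibration", ...)
  graphics::abline(h = 0.10, lty = 3)
  graphics::abline(v = 2.8, lty = 3)
  invisible(x)
}
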