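# Brute-force reference implementations, deliberately naive (explicit
# loops, no shared code with the package internals), used to cross-check
# the vectorized pipeline on small fixtures.

# Z/R log2-ratio formulas, evaluated protein by protein.
oracle_ratios <- function(tic, a1, a2, b1, b2) {
  n <- nrow(tic)
  out <- data.frame(Z0 = numeric(n), Z1 = numeric(n),
                    R0 = numeric(n), R1 = numeric(n))
  for (i in seq_len(n)) {
    out$Z0[i] <- log2(tic[i, a1]) - log2(tic[i, b1])
    out$Z1[i] <- log2(tic[i, a2]) - log2(tic[i, b2])
    out$R0[i] <- log2(tic[i, a1]) - log2(tic[i, a2])
    out$R1[i] <- log2(tic[i, b1]) - log2(tic[i, b2])
  }
  out
}

# Detection rule: exhaustive per-row scan.
oracle_detected <- function(tic) {
  keep <- logical(nrow(tic))
  for (i in seq_len(nrow(tic))) {
    keep[i] <- TRUE
    for (j in seq_len(ncol(tic))) {
      if (is.na(tic[i, j])) keep[i] <- FALSE
    }
  }
  keep
}

# COG cross-tab: nested-loop tally (one count per assigned letter).
oracle_crosstab <- function(znet, cog_string, threshold) {
  up <- stats::setNames(integer(length(LETTERS)), LETTERS)
  down <- up
  for (i in seq_along(znet)) {
    if (abs(znet[i]) <= threshold) next
    letters_i <- strsplit(cog_string[i], ";", fixed = TRUE)[[1]]
    letters_i <- trimws(letters_i)[nzchar(trimws(letters_i))]
    if (length(letters_i) == 0) letters_i <- "X"
    for (ltr in letters_i) {
      if (znet[i] > 0) up[ltr] <- up[ltr] + 1L else down[ltr] <- down[ltr] + 1L
    }
  }
  list(up = up, down = down)
}

# Venn region counts from membership bitmasks.
oracle_overlap <- function(sets) {
  universe <- unique(c(sets[[1]], sets[[2]], sets[[3]]))
  counts <- integer(7)
  names(counts) <- c("100", "010", "110", "001", "101", "011", "111")
  for (p in universe) {
    key <- paste(as.integer(c(p %in% sets[[1]], p %in% sets[[2]],
                              p %in% sets[[3]])), collapse = "")
    counts[key] <- counts[key] + 1L
  }
  counts
}

# A small random TIC table with optional ND holes.
random_tic_table <- function(n, seed, nd_frac = 0) {
  set.seed(seed)
  m <- matrix(2^rnorm(4 * n, 20, 2), n, 4)
  if (nd_frac > 0) {
    m[sample(length(m), round(nd_frac * length(m)))] <- NA
  }
  dimnames(m) <- list(sprintf("P%03d", seq_len(n)),
                      c("A_rep1", "A_rep2", "B_rep1", "B_rep2"))
  tic_table(m, states = c("A", "A", "B", "B"), replicates = c(1, 2, 1, 2))
}

# Ratio populations built directly from given vectors (bypasses the
# four-sample design; used for closed-form null checks of the statistic).
make_pops <- function(Z0, Z1, R0, R1) {
  structure(list(
    protein_id = sprintf("P%06d", seq_along(Z0)),
    Z0 = Z0, Z1 = Z1, R0 = R0, R1 = R1,
    comparison = c("A", "B"), label = "A_vs_B"
  ), class = "ratio_populations")
}
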