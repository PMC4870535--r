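# Build a znet_fit-shaped object with prescribed scores so annotation
# summaries can be checked against hand-countable fixtures.
stub_fit <- function(protein_id, znet, label = "A_vs_B", sn = NULL) {
  if (is.null(sn)) sn <- abs(znet)
  cls <- classify_tiers(stats::setNames(znet, protein_id))
  structure(list(
    comparison = strsplit(label, "_vs_")[[1]],
    label = label,
    table = data.frame(protein_id = protein_id, znet = znet, sn = sn,
                       tier = cls$tier, direction = cls$direction,
                       significant = cls$significant,
                       fdr_reliable = sn > 2.8,
                       stringsAsFactors = FALSE),
    nd_proteins = character(0),
    tiers = c(1.0, 1.65, 1.96), sn_cutoff = 2.8
  ), class = "znet_fit")
}

test_that("COG cross-tab counts up/down per letter with the sentinel class", {
  fit <- stub_fit(c("p1", "p2", "p3", "p4", "p5"),
                  c(2.0, 1.7, -1.9, 2.5, 0.3))
  ann <- data.frame(protein_id = c("p1", "p2", "p3", "p5"),
                    cog = c("C", "C", "C", "E"),
                    stringsAsFactors = FALSE)
  ct <- cog_crosstab(fit, ann)
  expect_equal(ct$A_vs_B_up[ct$cog == "C"], 2)
  expect_equal(ct$A_vs_B_down[ct$cog == "C"], 1)
  expect_equal(ct$A_vs_B_up[ct$cog == "X"], 1)   # p4: no COG -> sentinel
  expect_equal(ct$A_vs_B_up[ct$cog == "E"], 0)   # p5 below threshold
  expect_equal(ct$A_vs_B_up[ct$cog == "Total"], 3)
  expect_equal(ct$A_vs_B_down[ct$cog == "Total"], 1)
})

test_that("multi-letter proteins are counted once per letter", {
  fit <- stub_fit(c("p1", "p2"), c(2.0, -2.0))
  ann <- data.frame(protein_id = c("p1", "p2"),
                    cog = c("C;E;I", "C"), stringsAsFactors = FALSE)
  ct <- cog_crosstab(fit, ann)
  expect_equal(ct$A_vs_B_up[ct$cog %in% c("C", "E", "I")], c(1, 1, 1))
  expect_equal(ct$A_vs_B_up[ct$cog == "Total"], 3)  # letter total > 1 protein
  expect_equal(ct$A_vs_B_down[ct$cog == "C"], 1)
})

test_that("COG cross-tab matches a brute-force tally on a random fixture", {
  set.seed(60)
  n <- 50
  ids <- sprintf("p%02d", 1:n)
  znet <- rnorm(n, 0, 1.5)
  cogs <- replicate(n, paste(sample(c("C", "E", "I", "P", "O", ""),
                                    sample(0:2, 1)), collapse = ";"))
  fit <- stub_fit(ids, znet)
  ct <- cog_crosstab(fit, data.frame(protein_id = ids, cog = cogs,
                                     stringsAsFactors = FALSE))
  ref <- oracle_crosstab(znet, cogs, 1.65)
  for (ltr in setdiff(ct$cog, "Total")) {
    expect_identical(ct$A_vs_B_up[ct$cog == ltr], unname(ref$up[ltr]))
    expect_identical(ct$A_vs_B_down[ct$cog == ltr], unname(ref$down[ltr]))
  }
  expect_equal(sum(ref$up), ct$A_vs_B_up[ct$cog == "Total"])
})

test_that("cross-tab totals reproduce significant counts under single-letter COGs", {
  set.seed(61)
  ids <- sprintf("p%02d", 1:40)
  znet <- rnorm(40, 0, 1.5)
  fit <- stub_fit(ids, znet)
  ann <- data.frame(protein_id = ids,
                    cog = sample(c("C", "E", "I"), 40, replace = TRUE),
                    stringsAsFactors = FALSE)
  ct <- cog_crosstab(fit, ann)
  expect_equal(ct$A_vs_B_up[ct$cog == "Total"] +
                 ct$A_vs_B_down[ct$cog == "Total"],
               sum(abs(znet) > 1.65))
})

test_that("malformed COG letters are rejected with the offenders listed", {
  fit <- stub_fit("p1", 2.0)
  ann <- data.frame(protein_id = "p1", cog = "C;c7", stringsAsFactors = FALSE)
  expect_error(cog_crosstab(fit, ann), "c7")
})

test_that("overlap regions follow set algebra on known sets", {
  fits <- list(
    one = stub_fit(c("A", "B"), c(2, 2)),
    two = stub_fit(c("B", "C"), c(2, -2)),
    three = stub_fit(c("C"), c(-2))
  )
  ov <- overlap_counts(fits)
  get <- function(r) ov$n[ov$region == r]
  expect_equal(get("100"), 1)  # A only in set 1
  expect_equal(get("110"), 1)  # B in sets 1 and 2
  expect_equal(get("011"), 1)  # C in sets 2 and 3
  expect_equal(c(get("010"), get("001"), get("101"), get("111")),
               c(0, 0, 0, 0))
  expect_equal(sum(ov$n), 3)   # conservation: regions partition the union
  expect_equal(ov$two_down[ov$region == "011"], 1)  # C is down in set 2
})

test_that("three identical significant sets collapse into the triple region", {
  f <- stub_fit(sprintf("p%d", 1:6), rep(c(2, -2), 3))
  ov <- overlap_counts(list(a = f, b = f, c = f))
  expect_equal(ov$n[ov$region == "111"], 6)
  expect_equal(sum(ov$n), 6)
})

test_that("overlap counts equal a brute-force bitmask tally on random sets", {
  set.seed(62)
  ids <- sprintf("p%02d", 1:60)
  fits <- lapply(1:3, function(k) {
    z <- rnorm(60, 0, 1.6)
    stub_fit(ids, z, label = paste0("cmp", k, "_vs_ref"))
  })
  names(fits) <- paste0("c", 1:3)
  ov <- overlap_counts(fits)
  sets <- lapply(fits, function(f) f$table$protein_id[abs(f$table$znet) > 1.65])
  ref <- oracle_overlap(sets)
  for (r in names(ref)) {
    expect_identical(ov$n[ov$region == r], unname(ref[r]))
  }
  expect_equal(sum(ov$n), length(unique(unlist(sets))))
})

test_that("overlap of the sn-reliable sets and input-order invariance", {
  set.seed(63)
  ids <- sprintf("p%02d", 1:30)
  fits <- lapply(1:3, function(k) stub_fit(ids, rnorm(30, 0, 1.5),
                                           sn = rexp(30, 1 / 2)))
  names(fits) <- paste0("c", 1:3)
  ov_sn <- overlap_counts(fits, use = "sn")
  sets <- lapply(fits, function(f) f$table$protein_id[f$table$sn > 2.8])
  expect_equal(sum(ov_sn$n), length(unique(unlist(sets))))
  # permuting input row order changes nothing
  fits_perm <- lapply(fits, function(f) {
    f$table <- f$table[sample(nrow(f$table)), ]
    f
  })
  expect_equal(overlap_counts(fits_perm, use = "sn")$n, ov_sn$n)
  expect_error(overlap_counts(fits[1:2]), "three")
  expect_error(overlap_counts(stats::setNames(fits, c("a", "a", "b"))),
               "duplicated")
})

test_that("HOV rollup groups scores by annotation layer with multi-membership", {
  fit <- stub_fit(c("p1", "p2", "p3"), c(2.0, -2.0, 0.5))
  ann <- data.frame(protein_id = c("p1", "p2", "p3"),
                    cog = c("C", "", "E"),
                    kegg = c("M00001;M00002", "M00001", ""),
                    stringsAsFactors = FALSE)
  kegg <- hov_rollup(fit, ann, "kegg")
  expect_equal(kegg$n[kegg$category == "M00001"], 2)
  expect_equal(kegg$n[kegg$category == "M00002"], 1)  # p1 in both modules
  expect_equal(kegg$mean_znet[kegg$category == "M00001"], 0)
  expect_equal(kegg$mean_znet[kegg$category == "M00002"], 2)
  expect_equal(kegg$n_down[kegg$category == "M00001"], 1)
  cog <- hov_rollup(fit, ann, "cog")
  expect_equal(cog$n[cog$category == "X"], 1)  # p2: unannotated sentinel
  expect_equal(cog$mean_znet[cog$category == "E"], 0.5)
  expect_error(hov_rollup(fit, ann, "metacyc"), "metacyc")
})

test_that("grouped means equal an independent per-category recomputation", {
  set.seed(64)
  ids <- sprintf("p%02d", 1:20)
  znet <- rnorm(20)
  cats <- sample(c("EC1.1", "EC2.7", "EC3.5"), 20, replace = TRUE)
  fit <- stub_fit(ids, znet)
  ec <- hov_rollup(fit, data.frame(protein_id = ids, ec = cats,
                                   stringsAsFactors = FALSE), "ec")
  for (cat in unique(cats)) {
    expect_equal(ec$mean_znet[ec$category == cat],
                 mean(znet[cats == cat]))
    expect_equal(ec$n[ec$category == cat], sum(cats == cat))
  }
})
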