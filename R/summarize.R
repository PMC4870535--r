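## Annotation-level summaries: COG cross-tabs, three-way overlaps and
## higher-order-variable (HOV) rollups.

COG_SENTINEL <- "X"  # "Not in COG"

# Split a ";"-separated multi-valued annotation field into a list.
split_multi <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' Read a protein annotation map
#'
#' Tab-separated file with columns `protein_id`, `cog`, `ec`, `kegg`,
#' `metacyc`; multi-valued cells are `;`-separated, empty cells mean no
#' annotation. COG letters must come from the standard single-letter
#' alphabet (A-Z); proteins without a COG letter are counted under the
#' sentinel class `X` ("Not in COG") by [cog_crosstab()].
#'
#' @param path file path.
#' @return data.frame of class `annotation_map`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  as_annotation(ann)
}

#' Validate an annotation data.frame
#'
#' @param ann data.frame with column `protein_id` and any of `cog`, `ec`,
#'   `kegg`, `metacyc`.
#' @return The validated data.frame, classed `annotation_map`.
#' @export
as_annotation <- function(ann) {
  if (!is.data.frame(ann) || !"protein_id" %in% names(ann)) {
    stop("annotation must be a data.frame with a 'protein_id' column",
         call. = FALSE)
  }
  if (anyDuplicated(ann$protein_id)) {
    stop("duplicate protein ids in annotation map", call. = FALSE)
  }
  for (col in c("cog", "ec", "kegg", "metacyc")) {
    if (!col %in% names(ann)) ann[[col]] <- ""
  }
  letters_used <- unlist(split_multi(ann$cog))
  bad <- setdiff(unique(letters_used), LETTERS)
  if (length(bad)) {
    stop("malformed COG letter(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  class(ann) <- c("annotation_map", "data.frame")
  ann
}

# COG letters for a set of proteins; empty/missing -> sentinel X.
cog_letters_for <- function(protein_id, ann) {
  idx <- match(protein_id, ann$protein_id)
  cogs <- split_multi(ann$cog[idx])
  cogs[is.na(idx)] <- list(character(0))
  lapply(cogs, function(v) if (length(v) == 0) COG_SENTINEL else v)
}

#' COG-class cross-tabulation of up- and down-regulated proteins
#'
#' Counts, per comparison and COG letter, the proteins whose |Znet|
#' exceeds `threshold`, split by direction. A protein with several COG
#' letters is counted once per letter (so column totals can exceed the
#' number of distinct significant proteins); proteins without a COG
#' assignment fall in the sentinel class `X` ("Not in COG").
#'
#' @param fits a single [znet()] fit or a named list of fits (names become
#'   comparison column labels; unnamed lists use each fit's label).
#' @param ann an annotation map ([as_annotation()]).
#' @param threshold |Znet| cutoff, default 1.65 (outermost 10%).
#' @return data.frame of class `cog_crosstab`: one row per COG letter plus
#'   a `Total` row, columns `<comparison>_up` / `<comparison>_down`.
#' @export
cog_crosstab <- function(fits, ann, threshold = 1.65) {
  fits <- as_fit_list(fits)
  ann <- as_annotation(ann)
  letters_all <- sort(unique(c(
    COG_SENTINEL,
    unlist(lapply(fits, function(f) {
      unlist(cog_letters_for(f$table$protein_id, ann))
    }))
  )))
  out <- data.frame(cog = c(letters_all, "Total"),
                    stringsAsFactors = FALSE)
  for (lbl in names(fits)) {
    f <- fits[[lbl]]
    up_counts <- stats::setNames(integer(length(letters_all)), letters_all)
    down_counts <- up_counts
    sel <- abs(f$table$znet) > threshold
    cogs <- cog_letters_for(f$table$protein_id[sel], ann)
    dirs <- f$table$direction[sel]
    for (i in seq_along(cogs)) {
      for (ltr in cogs[[i]]) {
        if (dirs[i] == "up") {
          up_counts[ltr] <- up_counts[ltr] + 1L
        } else if (dirs[i] == "down") {
          down_counts[ltr] <- down_counts[ltr] + 1L
        }
      }
    }
    out[[paste0(lbl, "_up")]] <- c(up_counts, sum(up_counts))
    out[[paste0(lbl, "_down")]] <- c(down_counts, sum(down_counts))
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("cog_crosstab", "data.frame")
  out
}

as_fit_list <- function(fits) {
  if (inherits(fits, "znet_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, TRUE, "znet_fit")))
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, `[[`, "", "label")
  }
  if (anyDuplicated(names(fits))) {
    stop("duplicated comparison labels", call. = FALSE)
  }
  fits
}

#' Three-comparison overlap (Venn) counts of differential proteins
#'
#' Partitions the union of significant proteins from exactly three
#' comparisons into the seven subset regions of a three-set Venn diagram,
#' with a per-comparison up/down direction breakdown inside each region.
#' The significant set of a comparison is `|Znet| > threshold` by default,
#' or `sn > sn_cutoff` with `use = "sn"` (the rule behind
#' differential-protein counts).
#'
#' @param fits named list of exactly three [znet()] fits.
#' @param use `"znet"` (default) or `"sn"`.
#' @param threshold |Znet| cutoff when `use = "znet"`.
#' @param sn_cutoff sn cutoff when `use = "sn"`; defaults to each fit's own.
#' @return data.frame of class `overlap_summary`: one row per region
#'   (membership pattern such as `"110"`, ordered as the given fits),
#'   column `n`, and `<comparison>_up` / `<comparison>_down` columns
#'   counting, among the region's proteins, directions in the comparisons
#'   the region belongs to.
#' @export
overlap_counts <- function(fits, use = c("znet", "sn"), threshold = 1.65,
                           sn_cutoff = NULL) {
  use <- match.arg(use)
  fits <- as_fit_list(fits)
  if (length(fits) != 3L) {
    stop("exactly three comparisons are required", call. = FALSE)
  }
  sets <- lapply(fits, function(f) {
    if (use == "znet") {
      f$table$protein_id[abs(f$table$znet) > threshold]
    } else {
      cut <- if (is.null(sn_cutoff)) f$sn_cutoff else sn_cutoff
      f$table$protein_id[f$table$sn > cut]
    }
  })
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  regions <- apply(expand.grid(rep(list(1:0), 3))[, 3:1], 1,
                   paste, collapse = "")
  regions <- setdiff(regions, "000")
  out <- data.frame(region = regions,
                    n = as.integer(table(factor(pattern, regions))),
                    stringsAsFactors = FALSE)
  for (k in seq_along(fits)) {
    lbl <- names(fits)[k]
    dir_k <- stats::setNames(fits[[k]]$table$direction,
                             fits[[k]]$table$protein_id)
    up <- down <- integer(length(regions))
    for (i in seq_along(regions)) {
      if (substr(regions[i], k, k) == "1") {
        ids <- universe[pattern == regions[i]]
        up[i] <- sum(dir_k[ids] == "up", na.rm = TRUE)
        down[i] <- sum(dir_k[ids] == "down", na.rm = TRUE)
      }
    }
    out[[paste0(lbl, "_up")]] <- up
    out[[paste0(lbl, "_down")]] <- down
  }
  attr(out, "use") <- use
  attr(out, "comparisons") <- names(fits)
  class(out) <- c("overlap_summary", "data.frame")
  out
}

#' Group a fit's scores by a higher-order annotation variable
#'
#' Rolls per-protein results up to one of the four annotation layers
#' (COG letter, EC number, KEGG module, METACYC pathway). A protein
#' belonging to several categories of the chosen layer appears in each.
#'
#' @param fit a [znet()] fit.
#' @param ann an annotation map.
#' @param hov one of `"cog"`, `"ec"`, `"kegg"`, `"metacyc"`.
#' @return data.frame with one row per category: `category`, `n` (member
#'   count among retained proteins), `n_up`, `n_down` (significant at the
#'   fit's outer-10% tier), `mean_znet`.
#' @export
hov_rollup <- function(fit, ann, hov = c("cog", "ec", "kegg", "metacyc")) {
  stopifnot(inherits(fit, "znet_fit"))
  hov <- match.arg(hov)
  ann <- as_annotation(ann)
  idx <- match(fit$table$protein_id, ann$protein_id)
  vals <- split_multi(ann[[hov]][idx])
  vals[is.na(idx)] <- list(character(0))
  if (hov == "cog") {
    vals <- lapply(vals, function(v) if (length(v) == 0) COG_SENTINEL else v)
  }
  reps <- lengths(vals)
  long <- data.frame(
    category = unlist(vals),
    znet = rep(fit$table$znet, reps),
    significant = rep(fit$table$significant, reps),
    direction = rep(fit$table$direction, reps),
    stringsAsFactors = FALSE
  )
  if (nrow(long) == 0L) {
    stop(sprintf("no '%s' annotations for the fitted proteins", hov),
         call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(long, long$category), function(d) {
    data.frame(
      category = d$category[1],
      n = nrow(d),
      n_up = sum(d$significant & d$direction == "up"),
      n_down = sum(d$significant & d$direction == "down"),
      mean_znet = mean(d$znet),
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  agg[order(agg$category), ]
}
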