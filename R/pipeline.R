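#' Run the full differential-expression pipeline from a config
#'
#' Executes, in order: peptide rollup (when the input is peptide-level),
#' the both-replicates detection rule with identified-protein counts,
#' replicate correlations, ratio populations, normalization, Znet scores
#' and tiers, system and per-protein signal-to-noise, Monte-Carlo FDR
#' calibration, and annotation summaries — writing one results TSV per
#' comparison, FDR curves, a COG cross-tab, a three-way overlap summary
#' (when exactly three comparisons are configured), and a JSON run
#' manifest. Given the same inputs, config and seed, two runs produce
#' byte-identical artifacts. On any stage error, partial outputs are
#' removed before the error is propagated with the stage name.
#'
#' @param config a list, or the path to a YAML/JSON file, with fields:
#'   \describe{
#'     \item{input}{list with `tic` (TIC TSV path) or `peptides`
#'       (peptide TSV path).}
#'     \item{comparisons}{list of two-element character vectors (first
#'       state minus second), optionally named with comparison labels.}
#'     \item{annotation}{optional annotation TSV path.}
#'     \item{thresholds}{optional: `tiers` (numeric(3), default
#'       1.0/1.65/1.96) and `sn_cutoff` (default 2.8).}
#'     \item{monte_carlo}{optional: `enabled` (default TRUE), `reps`
#'       (default 500), `cutoffs` (default 0-10 by 0.1), `seed`
#'       (required when enabled).}
#'     \item{out_dir}{output directory, created if needed.}
#'   }
#' @param quiet suppress progress messages.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(writer, obj, file) {
    path <- file.path(cfg$out_dir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- "input"
  tryCatch({
      table <- if (!is.null(cfg$input$peptides)) {
        stage <- "rollup"
        rollup_tic(read_peptide_table(cfg$input$peptides))
      } else {
        read_tic_table(cfg$input$tic)
      }
      stage <- "validate"
      all_states <- unique(unlist(cfg$comparisons))
      missing_states <- setdiff(all_states, table$samples$state)
      if (length(missing_states)) {
        stop("comparison state(s) not in input samples: ",
             paste(sQuote(missing_states), collapse = ", "), call. = FALSE)
      }
      ann <- if (!is.null(cfg$annotation)) read_annotation(cfg$annotation)

      # step (1): identified proteins, observed in both replicates
      stage <- "detection"
      for (s in unique(table$samples$state)) {
        cols <- state_columns(table, s)
        n_both <- sum(rowSums(is.na(table$tic[, cols, drop = FALSE])) == 0)
        say("state %s: %d proteins observed in both replicates", s, n_both)
      }

      stage <- "comparisons"
      fits <- list()
      counts <- list()
      for (k in seq_along(cfg$comparisons)) {
        cmp <- cfg$comparisons[[k]]
        lbl <- names(cfg$comparisons)[k]
        fit <- znet(table, comparison = cmp, tiers = cfg$tiers,
                    sn_cutoff = cfg$sn_cutoff)
        say("comparison %s: %d retained, %d ND, system S/N %.2f, r = %s",
            lbl, fit$n_retained, length(fit$nd_proteins), fit$system_sn,
            paste(sprintf("%.3f", fit$replicate_cor), collapse = "/"))
        emit(write_results, fit, paste0("comparison_", lbl, ".tsv"))
        if (cfg$mc$enabled) {
          curve <- monte_carlo_fdr(fit, cutoffs = cfg$mc$cutoffs,
                                   reps = cfg$mc$reps,
                                   seed = cfg$mc$seed + k)
          emit(write_fdr_curve, curve, paste0("fdr_", lbl, ".tsv"))
          say("comparison %s: Monte-Carlo FDR at S/N > %.1f: %s",
              lbl, cfg$sn_cutoff,
              format(fdr_at(curve, cfg$sn_cutoff), digits = 3))
        }
        fits[[lbl]] <- fit
        counts[[lbl]] <- list(
          retained = fit$n_retained, nd = length(fit$nd_proteins),
          significant = sum(fit$table$significant),
          fdr_reliable = sum(fit$table$fdr_reliable)
        )
      }

      stage <- "summaries"
      if (!is.null(ann)) {
        emit(write_tsv_plain, cog_crosstab(fits, ann, cfg$tiers[2]),
             "cog_crosstab.tsv")
      }
      if (length(fits) == 3L) {
        emit(write_tsv_plain, overlap_counts(fits, threshold = cfg$tiers[2]),
             "overlap_summary.tsv")
      }

      stage <- "manifest"
      # the manifest records analysis parameters; the output location is
      # not one of them (and would break byte-identity across directories)
      cfg_echo <- cfg[setdiff(names(cfg), "out_dir")]
      cfg_json <- jsonlite::toJSON(cfg_echo, auto_unbox = TRUE, digits = NA)
      tmp <- tempfile()
      writeLines(cfg_json, tmp)
      manifest <- list(
        package = "znetdiff",
        version = as.character(utils::packageVersion("znetdiff")),
        seed = if (cfg$mc$enabled) cfg$mc$seed else NULL,
        config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
        config_md5 = unname(tools::md5sum(tmp)),
        counts = counts,
        files = basename(written)
      )
      unlink(tmp)
      manifest_path <- file.path(cfg$out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      written <- c(written, manifest_path)
      invisible(stats::setNames(as.list(written), basename(written)))
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

validate_run_config <- function(config) {
  if (!is.list(config)) {
    stop("config must be a list or a YAML/JSON path", call. = FALSE)
  }
  if (is.null(config$input) ||
      (is.null(config$input$tic) && is.null(config$input$peptides))) {
    stop("field 'input' must provide 'tic' or 'peptides' path",
         call. = FALSE)
  }
  for (f in c("tic", "peptides")) {
    p <- config$input[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("field 'input.%s': file not found: %s", f, p),
           call. = FALSE)
    }
  }
  if (is.null(config$out_dir)) {
    stop("field 'out_dir' is required", call. = FALSE)
  }
  if (is.null(config$comparisons) || !length(config$comparisons)) {
    stop("field 'comparisons' must list at least one state pair",
         call. = FALSE)
  }
  comparisons <- lapply(config$comparisons, function(cmp) {
    cmp <- as.character(unlist(cmp))
    if (length(cmp) != 2L || cmp[1] == cmp[2]) {
      stop("field 'comparisons': each entry must be two distinct states",
           call. = FALSE)
    }
    cmp
  })
  if (is.null(names(comparisons)) || any(!nzchar(names(comparisons)))) {
    names(comparisons) <- vapply(comparisons, paste, "", collapse = "_vs_")
  }
  if (anyDuplicated(names(comparisons))) {
    stop("field 'comparisons': duplicated comparison labels",
         call. = FALSE)
  }
  th <- config$thresholds
  tiers <- if (is.null(th$tiers)) c(1.0, 1.65, 1.96) else as.numeric(th$tiers)
  if (length(tiers) != 3L || is.unsorted(tiers)) {
    stop("field 'thresholds.tiers' must be three increasing cutoffs",
         call. = FALSE)
  }
  sn_cutoff <- if (is.null(th$sn_cutoff)) 2.8 else th$sn_cutoff
  check_number(sn_cutoff, "thresholds.sn_cutoff", lower = 0)
  mc <- config$monte_carlo
  enabled <- if (is.null(mc$enabled)) TRUE else isTRUE(mc$enabled)
  if (enabled) {
    if (is.null(mc$seed)) {
      stop("field 'monte_carlo.seed' is required when Monte-Carlo is enabled",
           call. = FALSE)
    }
    check_number(mc$seed, "monte_carlo.seed", integer = TRUE)
  }
  list(
    input = config$input,
    annotation = config$annotation,
    comparisons = comparisons,
    tiers = tiers,
    sn_cutoff = sn_cutoff,
    mc = list(
      enabled = enabled,
      reps = if (is.null(mc$reps)) 500L else as.integer(mc$reps),
      cutoffs = if (is.null(mc$cutoffs)) round(seq(0, 10, by = 0.1), 10)
                else as.numeric(mc$cutoffs),
      seed = if (enabled) as.integer(mc$seed) else NULL
    ),
    out_dir = config$out_dir
  )
}
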