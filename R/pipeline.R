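# End-to-end orchestration: simulate or load -> log2 -> variance phenotype
# (non-normalized branch) -> group tests / ANCOVA / correlations / median
# split -> quantile normalization -> present filter -> differential
# expression -> directional lists -> overlap -> enrichment -> cross-
# validation, with a machine-readable results document and a Markdown report.

#' Pipeline run configuration
#'
#' Exactly one of a simulation configuration or a set of input paths must be
#' supplied.
#'
#' @param simulation a [sim_config()] describing a cohort to simulate, or
#'   `NULL` when reading files.
#' @param expression,presence,metadata paths to the tab-delimited input
#'   tables (required when `simulation` is `NULL`).
#' @param genesets optional path to a GMT file for the enrichment stage.
#' @param scale scale of the expression file (`"linear"` or `"log2"`).
#' @param log2_floor floor for [log2_transform()] of linear input.
#' @param p_threshold,fc_threshold,min_present DE and background thresholds.
#' @param enrich_method `"fisher"` or `"ease"`.
#' @param stages which stages to run (later stages that depend on skipped
#'   ones are skipped too).
#' @param seed integer seed for split tie-breaking (and carried into the
#'   report); simulation uses the seed inside `simulation`.
#' @param out_dir output directory, created if needed; `NULL` disables file
#'   output.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(simulation = NULL,
                       expression = NULL, presence = NULL, metadata = NULL,
                       genesets = NULL, scale = c("linear", "log2"),
                       log2_floor = 2^-4,
                       p_threshold = 0.05, fc_threshold = 1.1,
                       min_present = 50,
                       enrich_method = c("fisher", "ease"),
                       stages = c("variance", "association", "de", "overlap",
                                  "enrichment", "crossval"),
                       seed = 1L, out_dir = NULL) {
  scale <- match.arg(scale)
  enrich_method <- match.arg(enrich_method)
  stages <- match.arg(stages, several.ok = TRUE)
  if (p_threshold <= 0 || fc_threshold <= 0 || min_present < 0) {
    stop("thresholds must be positive")
  }
  if (is.null(simulation)) {
    for (field in c("expression", "presence", "metadata")) {
      if (is.null(get(field))) {
        stop(sprintf("missing required input: '%s' (no simulation supplied)",
                     field))
      }
    }
  } else {
    stopifnot(inherits(simulation, "sim_config"))
    if (!is.null(expression) || !is.null(presence) || !is.null(metadata)) {
      stop("supply either a simulation or input paths, not both")
    }
  }
  structure(as.list(environment()), class = "run_config")
}

.stage <- function(results, name, expr) {
  results$stages[[name]] <- tryCatch(
    list(ok = TRUE, value = eval.parent(substitute(expr))),
    error = function(e) list(ok = FALSE, error = conditionMessage(e))
  )
  results
}

.stage_value <- function(results, name) {
  st <- results$stages[[name]]
  if (is.null(st) || !st$ok) NULL else st$value
}

#' Run the full analysis pipeline
#'
#' Executes the workflow on simulated or loaded data. The variance phenotype
#' is always computed on the non-quantile-normalized log2 matrix; the
#' differential-expression branch runs on quantile-normalized data with a
#' present-call background — the report states which branch fed each
#' statistic. A failing stage is recorded and independent later stages still
#' run. Identical configuration and seed give identical results.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of class `gexvar_run`: `stages` (per-stage
#'   results or errors), `summary` (flat named list of headline numbers),
#'   and paths of files written (when `out_dir` is set): the phenotype
#'   table, DE table, gene lists, `results.json`, and `report.md`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  results <- list(stages = list(), config = config)

  # --- load or simulate -----------------------------------------------------
  results <- .stage(results, "input", {
    if (!is.null(config$simulation)) {
      cohort <- simulate_cohort(config$simulation)
    } else {
      expr <- read_expression_matrix(config$expression, config$scale)
      if (expr$scale == "linear") expr <- log2_transform(expr, config$log2_floor)
      cohort <- list(
        expression = expr,
        presence = read_presence_matrix(config$presence),
        metadata = read_sample_metadata(config$metadata)
      )
      validate_presence(cohort$presence, cohort$expression)
    }
    cohort
  })
  cohort <- .stage_value(results, "input")
  if (is.null(cohort)) {
    stop("input stage failed: ", results$stages$input$error)
  }
  md <- cohort$metadata
  gsets <- if (!is.null(config$genesets)) read_gene_sets(config$genesets) else NULL

  # --- variance phenotype (non-normalized branch) ---------------------------
  if ("variance" %in% config$stages) {
    results <- .stage(results, "variance", {
      pheno <- overall_variance(cohort$expression)
      pheno$standardized_variance <- standardize(pheno$overall_variance)
      pheno
    })
  }
  pheno <- .stage_value(results, "variance")

  # --- association tests ----------------------------------------------------
  if ("association" %in% config$stages && !is.null(pheno)) {
    std <- stats::setNames(pheno$standardized_variance, pheno$sample_id)
    results <- .stage(results, "association", {
      out <- list()
      is_dx <- !is.na(md$diagnosis)
      if (any(md$diagnosis[is_dx] == "autism") &&
          any(md$diagnosis[is_dx] == "control")) {
        out$normality <- lapply(split(std[is_dx], md$diagnosis[is_dx]),
                                function(v) .try_analysis(shapiro_normality(v)))
        out$group_test <- compare_groups(std[is_dx], md$diagnosis[is_dx],
                                         case = "autism")
        out$ancova <- .try_analysis(
          variance_ancova(std[is_dx], md[is_dx, , drop = FALSE])
        )
        ctrl <- is_dx & md$diagnosis == "control" & !is.na(md$paternal_age)
        out$paternal_age <- .try_analysis(
          correlation_fisher(md$paternal_age[ctrl], std[md$sample_id[ctrl]])
        )
        out$paternal_age_spearman <- .try_analysis(
          spearman_corr(md$paternal_age[ctrl], std[md$sample_id[ctrl]])
        )
        out$median_split <- .try_analysis({
          fs <- median_split(md$paternal_age)
          young <- !is.na(fs) & fs == "younger" & is_dx
          ctrl_split <- !is.na(fs) & is_dx & md$diagnosis == "control"
          list(
            median = attr(fs, "median"),
            autism_vs_young_control = .try_analysis(
              compare_groups(std[md$sample_id[young]], md$diagnosis[young],
                             case = "autism")),
            old_vs_young_control = .try_analysis(
              compare_groups(std[md$sample_id[ctrl_split]],
                             as.character(fs[ctrl_split]), case = "older"))
          )
        })
      }
      if ("condition" %in% names(md) && !all(is.na(md$condition))) {
        out$condition_means <- vapply(
          split(pheno$overall_variance, md$condition), mean, numeric(1))
      }
      out
    })
  }

  # --- DE branch (quantile-normalized) --------------------------------------
  if ("de" %in% config$stages) {
    results <- .stage(results, "de", {
      qn <- quantile_normalize(cohort$expression)
      background <- if (!is.null(cohort$presence)) {
        present_filter(cohort$presence, config$min_present)
      } else {
        probe_ids(qn)
      }
      if (!length(background)) stop("present filter removed every probe")
      is_dx <- !is.na(md$diagnosis)
      tab <- de_table(.subset_samples(qn, md$sample_id[is_dx]),
                      md$diagnosis[is_dx], case = "autism",
                      background = background,
                      p_threshold = config$p_threshold,
                      fc_threshold = config$fc_threshold)
      list(qn = qn, background = background, table = tab,
           down = significant_sets(tab, "down"),
           up = significant_sets(tab, "up"))
    })
  }
  de <- .stage_value(results, "de")

  # --- overlap of autism-linked and paternal-age-linked lists ---------------
  if ("overlap" %in% config$stages && !is.null(de)) {
    results <- .stage(results, "overlap", {
      fs <- median_split(md$paternal_age)
      young_ctrl <- !is.na(fs) & fs == "younger" & md$diagnosis %in% "control"
      old_ctrl <- !is.na(fs) & fs == "older" & md$diagnosis %in% "control"
      aut <- md$diagnosis %in% "autism"
      if (sum(young_ctrl) < 2 || sum(old_ctrl) < 2) {
        stop("too few control samples per paternal-age stratum")
      }
      lab <- function(sel_case, sel_ref, case, ref) {
        keep <- sel_case | sel_ref
        list(ids = md$sample_id[keep],
             labels = ifelse(sel_case[keep], case, ref))
      }
      l1 <- lab(aut, young_ctrl, "autism", "young_control")
      tab1 <- de_table(.subset_samples(de$qn, l1$ids), l1$labels,
                       case = "autism", background = de$background,
                       p_threshold = config$p_threshold,
                       fc_threshold = config$fc_threshold)
      l2 <- lab(old_ctrl, young_ctrl, "old_control", "young_control")
      tab2 <- de_table(.subset_samples(de$qn, l2$ids), l2$labels,
                       case = "old_control", background = de$background,
                       p_threshold = config$p_threshold,
                       fc_threshold = config$fc_threshold)
      down1 <- significant_sets(tab1, "down")
      down2 <- significant_sets(tab2, "down")
      up1 <- significant_sets(tab1, "up")
      up2 <- significant_sets(tab2, "up")
      list(
        autism_vs_young = list(down = down1, up = up1),
        old_vs_young = list(down = down2, up = up2),
        down_overlap = .try_analysis(
          overlap_chi_square(down1, down2, de$background)),
        up_overlap = .try_analysis(
          overlap_chi_square(up1, up2, de$background)),
        shared_down = intersect(down1, down2)
      )
    })
  }
  ov <- .stage_value(results, "overlap")

  # --- enrichment -----------------------------------------------------------
  if ("enrichment" %in% config$stages && !is.null(de) && !is.null(gsets)) {
    results <- .stage(results, "enrichment", {
      lst <- if (!is.null(ov) && length(ov$shared_down)) ov$shared_down else de$down
      if (!length(lst)) stop("no down-regulated probes to test")
      enrich_sets(lst, de$background, gsets, method = config$enrich_method,
                  adjust = "BH")
    })
  }

  # --- cross-validation -----------------------------------------------------
  if ("crossval" %in% config$stages) {
    results <- .stage(results, "crossval", {
      has_pa <- !is.na(md$paternal_age)
      case_ids <- md$sample_id[md$diagnosis %in% "autism" & has_pa]
      ctrl_ids <- md$sample_id[md$diagnosis %in% "control" & has_pa]
      crossval_run(cohort, case_ids, ctrl_ids,
                   analyses = c("variance", "de", "overlap"),
                   background = if (!is.null(de)) de$background else NULL,
                   p_threshold = config$p_threshold,
                   fc_threshold = config$fc_threshold,
                   seed = config$seed)
    })
  }

  results$summary <- .pipeline_summary(results)
  if (!is.null(config$out_dir)) {
    results$files <- .write_outputs(results, cohort, config)
  }
  class(results) <- "gexvar_run"
  invisible(results)
}

.pipeline_summary <- function(results) {
  s <- list()
  assoc <- .stage_value(results, "association")
  if (!is.null(assoc$group_test)) {
    s$diagnosis_estimate_sd <- assoc$group_test$estimate
    s$diagnosis_p <- assoc$group_test$p_value
  }
  if (!is.null(assoc$paternal_age) && !isTRUE(assoc$paternal_age$skipped)) {
    s$paternal_age_r <- assoc$paternal_age$r
    s$paternal_age_p <- assoc$paternal_age$p_two_tailed
  }
  de <- .stage_value(results, "de")
  if (!is.null(de)) {
    s$n_background <- length(de$background)
    s$n_down <- length(de$down)
    s$n_up <- length(de$up)
  }
  ov <- .stage_value(results, "overlap")
  if (!is.null(ov) && !isTRUE(ov$down_overlap$skipped)) {
    s$down_overlap_chisq <- ov$down_overlap$statistic
    s$down_overlap_p <- ov$down_overlap$p_value
  }
  cv <- .stage_value(results, "crossval")
  if (!is.null(cv) && !is.null(cv$concordance)) {
    s$crossval_signs_agree <- attr(cv$concordance, "signs_agree")
  }
  s
}

.write_outputs <- function(results, cohort, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  pheno <- .stage_value(results, "variance")
  if (!is.null(pheno)) {
    f <- file.path(config$out_dir, "variance_phenotype.tsv")
    utils::write.table(pheno, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["phenotype"] <- f
  }
  de <- .stage_value(results, "de")
  if (!is.null(de)) {
    f <- file.path(config$out_dir, "de_table.tsv")
    utils::write.table(de$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["de_table"] <- f
    for (dd in c("down", "up")) {
      f <- file.path(config$out_dir, paste0(dd, "_regulated.txt"))
      writeLines(de[[dd]], f)
      files[paste0(dd, "_list")] <- f
    }
  }
  enr <- .stage_value(results, "enrichment")
  if (!is.null(enr)) {
    f <- file.path(config$out_dir, "enrichment.tsv")
    utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["enrichment"] <- f
  }
  f <- file.path(config$out_dir, "results.json")
  jsonlite::write_json(
    c(results$summary,
      list(stage_status = lapply(results$stages, function(st)
        if (st$ok) "ok" else paste("failed:", st$error)))),
    f, auto_unbox = TRUE, digits = NA, null = "null"
  )
  files["results"] <- f
  f <- file.path(config$out_dir, "report.md")
  writeLines(.render_report(results, config), f)
  files["report"] <- f
  files
}

.render_report <- function(results, config) {
  s <- results$summary
  fmt <- function(x) if (is.null(x)) "not computed" else sprintf("%.4g", x)
  lines <- c(
    "# Expression-distribution variance analysis report", "",
    sprintf("seed: %d", as.integer(config$seed)), "",
    "## Stage status", "",
    vapply(names(results$stages), function(nm) {
      st <- results$stages[[nm]]
      sprintf("- %s: %s", nm, if (st$ok) "ok" else paste("FAILED -", st$error))
    }, character(1)), "",
    "## Variance phenotype (computed on NON-quantile-normalized log2 data)", "",
    sprintf("- diagnosis effect (autism - control, SD units): %s (p = %s)",
            fmt(s$diagnosis_estimate_sd), fmt(s$diagnosis_p)),
    sprintf("- paternal-age correlation in controls: r = %s (p = %s)",
            fmt(s$paternal_age_r), fmt(s$paternal_age_p)), "",
    "## Differential expression (computed on QUANTILE-NORMALIZED data)", "",
    sprintf("- background probes (present filter, >= %d samples): %s",
            config$min_present, fmt(s$n_background)),
    sprintf("- down-regulated: %s; up-regulated: %s (p < %g, fold change >= %g)",
            fmt(s$n_down), fmt(s$n_up), config$p_threshold, config$fc_threshold),
    sprintf("- down-list overlap (autism vs paternal-age): chi^2 = %s (p = %s)",
            fmt(s$down_overlap_chisq), fmt(s$down_overlap_p)), "",
    "## Cross-validation", "",
    sprintf("- replicate variance-effect signs agree: %s",
            if (is.null(s$crossval_signs_agree)) "not computed"
            else s$crossval_signs_agree)
  )
  lines
}

#' @export
print.gexvar_run <- function(x, ...) {
  cat("<gexvar_run>\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (st$ok) "ok" else paste("FAILED -", st$error)))
  }
  invisible(x)
}
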