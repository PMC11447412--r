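## End-to-end orchestration: fit the calibration curve, estimate residual
## activities per condition, infer the stress-inactivated fraction from the
## all-WT animal, predict both hypotheses, select the supported one, and
## run the variant screen. Reports are written as JSON (sorted keys, with a
## config hash and seed for audit) and TSV.

#' Analysis configuration
#'
#' Validates and normalizes the configuration for [run_dimer_analysis()]
#' and [run_variant_screen()]. May be loaded from a YAML file with
#' [read_config()]. Tables may be given as file paths (TSV) or directly as
#' data frames.
#'
#' @param calibration calibration table or TSV path (columns `gene`,
#'   `genotype_label`, `keap1_level_pct`, `mrna_rel`, `replicate_id`).
#' @param observations observation table or TSV path (columns `gene`,
#'   `condition_label`, `mrna_rel`, `replicate_id`).
#' @param variants variant table or TSV path (columns `gene`,
#'   `protein_change`, `panel`, `allele_frequency`).
#' @param gene target gene analysed (rows for other genes are dropped).
#' @param wt_condition label of the stressed all-wild-type condition, from
#'   which the inactivated fraction is inferred.
#' @param test_condition label of the condition whose activity is compared
#'   with the hypothesis predictions.
#' @param wt_allele_fraction WT monomer fraction of the test genotype.
#' @param mode heterodimer arithmetic (`"paper_linear"` or `"binomial"`).
#' @param n_boot,seed bootstrap size and RNG seed.
#' @param outdir optional output directory for JSON/TSV reports.
#' @return an object of class `run_config`.
#' @export
run_config <- function(calibration = NULL, observations = NULL,
                       variants = NULL, gene = "Nqo1",
                       wt_condition = "wt_stressed",
                       test_condition = "het_stressed",
                       wt_allele_fraction = 0.5,
                       mode = c("paper_linear", "binomial"),
                       n_boot = 2000, seed = 1, outdir = NULL) {
  mode <- match.arg(mode)
  check_table_arg <- function(x, what) {
    if (is.null(x) || is.data.frame(x)) return(x)
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) {
        stop(sprintf("configuration error: %s file '%s' does not exist",
                     what, x), call. = FALSE)
      }
      return(x)
    }
    stop(sprintf("`%s` must be a data frame or a TSV path", what),
         call. = FALSE)
  }
  structure(
    list(calibration = check_table_arg(calibration, "calibration"),
         observations = check_table_arg(observations, "observations"),
         variants = check_table_arg(variants, "variants"),
         gene = gene,
         wt_condition = wt_condition,
         test_condition = test_condition,
         wt_allele_fraction = check_fraction(wt_allele_fraction,
                                             "wt_allele_fraction"),
         mode = mode,
         n_boot = as.integer(n_boot),
         seed = as.integer(seed),
         outdir = outdir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path path to a YAML configuration file whose keys mirror the
#'   arguments of `run_config()`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: config file '%s' does not exist",
                 path), call. = FALSE)
  }
  do.call(run_config, yaml::read_yaml(path))
}

#' Read and write the package's TSV dialects
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()]
#' fixing the tab separator, no quoting and no row names.
#'
#' @param path file path.
#' @return `read_tsv_table()` returns a data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @param x data frame to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
load_table <- function(x, what) {
  if (is.null(x)) {
    stop(sprintf("configuration error: no %s table configured", what),
         call. = FALSE)
  }
  if (is.character(x)) {
    if (!file.exists(x)) {
      stop(sprintf("configuration error: %s file '%s' does not exist",
                   what, x), call. = FALSE)
    }
    return(read_tsv_table(x))
  }
  as.data.frame(x)
}

#' @noRd
report_provenance <- function(config) {
  ## the hash covers the analytic inputs; the output location is excluded
  hashed <- unclass(config)
  hashed$outdir <- NULL
  list(package = "keapsense",
       version = as.character(utils::packageVersion("keapsense")),
       config_hash = config_hash(hashed),
       seed = config$seed)
}

#' Run the dimer-inactivation analysis end to end
#'
#' Fits the calibration curve, estimates residual KEAP1 activity (with
#' bootstrap CI) for every condition in the observation table, infers the
#' WT-homodimer inactivated fraction from the all-WT stressed condition,
#' predicts total activity under both hypotheses for the configured test
#' genotype, and selects the hypothesis consistent with the test-condition
#' estimate. When `outdir` is set, writes `dimer_analysis.json` and
#' `dimer_analysis.tsv`.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return an object of class `dimer_analysis_report`.
#' @export
run_dimer_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  calib <- load_table(config$calibration, "calibration")
  obs <- load_table(config$observations, "observations")
  if ("gene" %in% names(calib)) calib <- calib[calib$gene == config$gene, ]
  if ("gene" %in% names(obs)) obs <- obs[obs$gene == config$gene, ]
  if (nrow(obs) == 0) {
    stop("data error: no observations for gene ", config$gene, call. = FALSE)
  }
  conditions <- unique(obs$condition_label)
  if (!config$wt_condition %in% conditions) {
    stop(sprintf(
      "configuration error: all-WT stressed condition '%s' absent from the observation table; the inactivated fraction cannot be inferred",
      config$wt_condition), call. = FALSE)
  }
  if (!config$test_condition %in% conditions) {
    stop(sprintf("configuration error: test condition '%s' absent from the observation table",
                 config$test_condition), call. = FALSE)
  }
  curve <- fit_calibration(calib, gene = config$gene)
  estimates <- lapply(seq_along(conditions), function(i) {
    rows <- obs[obs$condition_label == conditions[[i]], ]
    estimate_activity_ci(calib, rows$mrna_rel,
                         n_boot = config$n_boot,
                         seed = config$seed + i,
                         gene = config$gene,
                         condition_label = conditions[[i]])
  })
  names(estimates) <- conditions
  f_inact <- infer_homodimer_inactivation(
    estimates[[config$wt_condition]]$activity_point)
  population <- dimer_composition(config$wt_allele_fraction)
  verdict <- evaluate_hypotheses(population, f_inact,
                                 estimates[[config$test_condition]],
                                 mode = config$mode)
  report <- structure(
    list(config = config,
         curve = curve,
         estimates = estimates,
         f_inact = f_inact,
         population = population,
         verdict = verdict,
         provenance = report_provenance(config)),
    class = "dimer_analysis_report"
  )
  if (!is.null(config$outdir)) write_dimer_report(report, config$outdir)
  report
}

#' @export
print.dimer_analysis_report <- function(x, ...) {
  cat("== KEAP1 dimer-inactivation analysis ==\n")
  print(x$curve)
  for (est in x$estimates) print(est)
  cat(sprintf("Inferred WT-homodimer inactivated fraction: %.1f%%\n",
              100 * x$f_inact))
  print(x$verdict)
  invisible(x)
}

#' @noRd
dimer_report_rows <- function(report) {
  v <- report$verdict
  mk <- function(hyp, pred) {
    data.frame(gene = report$config$gene,
               condition = report$config$test_condition,
               hypothesis = hyp,
               mode = report$config$mode,
               predicted_activity_pct = 100 * pred$total_activity,
               contrib_mut_homo_pct = 100 * pred$contrib_mut_homo,
               contrib_wt_homo_pct = 100 * pred$contrib_wt_homo,
               contrib_het_pct = 100 * pred$contrib_het,
               observed_activity_pct = 100 * v$estimate$activity_point,
               ci_low_pct = 100 * v$estimate$ci_low,
               ci_high_pct = 100 * v$estimate$ci_high,
               within_ci = unname(v$within_ci[[hyp]]),
               selected = v$selected,
               stringsAsFactors = FALSE)
  }
  rbind(mk("monomer", v$breakdown_monomer), mk("dimer", v$breakdown_dimer))
}

#' @noRd
write_dimer_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  v <- report$verdict
  payload <- list(
    provenance = report$provenance,
    settings = list(gene = report$config$gene,
                    mode = report$config$mode,
                    wt_allele_fraction = report$config$wt_allele_fraction,
                    n_boot = report$config$n_boot,
                    seed = report$config$seed),
    population = report$population[c("f_wt_homo", "f_het", "f_mut_homo")],
    f_inact = report$f_inact,
    estimates = lapply(report$estimates, function(e)
      e[c("condition_label", "activity_point", "ci_low", "ci_high",
          "n_boot", "seed", "n_replicates")]),
    predictions = list(
      monomer = v$breakdown_monomer[c("total_activity", "contrib_mut_homo",
                                      "contrib_wt_homo", "contrib_het")],
      dimer = v$breakdown_dimer[c("total_activity", "contrib_mut_homo",
                                  "contrib_wt_homo", "contrib_het")]),
    within_ci = as.list(v$within_ci),
    selected = v$selected)
  payload <- payload[order(names(payload))]
  jsonlite::write_json(payload, file.path(outdir, "dimer_analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_table(dimer_report_rows(report),
                  file.path(outdir, "dimer_analysis.tsv"))
  invisible(outdir)
}

#' Run the sensor-variant screen
#'
#' Parses the protein changes in the variant table, classifies each against
#' the sensor map, evaluates the single-variant fail-safe consequence, and
#' tabulates category counts. Malformed rows are collected and reported;
#' the run fails only when no row parses. When `outdir` is set, writes
#' `variant_screen.json` and `variant_screen.tsv`.
#'
#' @param config a [run_config()] (or path to a YAML config) with a
#'   `variants` table.
#' @param map a [keap1_sensor_map()].
#' @return an object of class `variant_screen_report` with `results` (one
#'   row per distinct variant), `counts`, `malformed` and `provenance`.
#' @export
run_variant_screen <- function(config, map = keap1_sensor_map()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  tab <- load_table(config$variants, "variants")
  if (!"protein_change" %in% names(tab)) {
    stop("data error: variant table needs a `protein_change` column",
         call. = FALSE)
  }
  changes <- unique(as.character(tab$protein_change))
  parsed <- list()
  malformed <- character()
  for (ch in changes) {
    v <- tryCatch(parse_protein_variant(ch), error = function(e) {
      malformed <<- c(malformed, sprintf("%s: %s", ch, conditionMessage(e)))
      NULL
    })
    if (!is.null(v)) parsed[[ch]] <- v
  }
  if (length(parsed) == 0) {
    stop("data error: no parseable variants in the table", call. = FALSE)
  }
  rows <- lapply(names(parsed), function(ch) {
    v <- parsed[[ch]]
    cl <- classify_variant(v, map)
    lost <- intersect(v$position, map$oxidative_cys)
    if (!cl$destroys_thiol) lost <- integer()
    fs <- suppressWarnings(failsafe_oxidative(lost, map))
    data.frame(protein_change = ch,
               position = v$position,
               ref_aa = v$ref_aa,
               alt_aa = v$alt_aa,
               category = cl$category,
               destroys_thiol = cl$destroys_thiol,
               destroys_basicity = cl$destroys_basicity,
               failsafe_functional = fs$functional,
               intact_parts = paste(fs$intact_parts, collapse = ","),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  counts <- count_by_category(unname(parsed), map)
  report <- structure(
    list(config = config,
         results = results,
         counts = counts,
         malformed = malformed,
         provenance = report_provenance(config)),
    class = "variant_screen_report"
  )
  if (!is.null(config$outdir)) write_screen_report(report, config$outdir)
  report
}

#' @export
print.variant_screen_report <- function(x, ...) {
  cat("== KEAP1 sensor-variant screen ==\n")
  print(x$results[c("protein_change", "category", "failsafe_functional")],
        row.names = FALSE)
  print(x$counts)
  if (length(x$malformed)) {
    cat("Malformed rows skipped:\n")
    for (mm in x$malformed) cat(" -", mm, "\n")
  }
  invisible(x)
}

#' @noRd
write_screen_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    counts = c(as.list(report$counts$counts),
               oxidative_affecting = report$counts$oxidative_affecting),
    malformed = as.list(report$malformed),
    provenance = report$provenance,
    variants = report$results)
  payload <- payload[order(names(payload))]
  jsonlite::write_json(payload, file.path(outdir, "variant_screen.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_table(report$results, file.path(outdir, "variant_screen.tsv"))
  invisible(outdir)
}
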