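#' Read replicated trial records from CSV
#'
#' Expects a header with columns `year`, `environment`, `block`,
#' `genotype`, `value` in any order and any case. Duplicate
#' (year, environment, block, genotype) keys and non-numeric values are
#' errors naming the offenders.
#'
#' @param path CSV file path.
#' @return `data.frame` of validated records.
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  names(raw) <- tolower(names(raw))
  need <- c("year", "environment", "block", "genotype", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("trial CSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, need]
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.finite(val))
  if (length(bad)) {
    stop("non-numeric or non-finite value(s) at data line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  raw$value <- val
  key <- paste(raw$year, raw$environment, raw$block, raw$genotype,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    k <- strsplit(key[which(dup)[1L]], "\r", fixed = TRUE)[[1L]]
    stop(sprintf(
      "duplicate record key (year=%s, environment=%s, block=%s, genotype=%s)",
      k[1], k[2], k[3], k[4]))
  }
  raw
}

#' Write trial records to CSV
#'
#' @param records `data.frame` with columns year, environment, block,
#'   genotype, value.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  write.csv(records[, c("year", "environment", "block", "genotype",
                        "value")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker panel from genotype and map CSVs
#'
#' The panel CSV holds one line per row: first column `line`, remaining
#' columns one marker each (header row of marker IDs), entries -1/+1. The
#' map CSV has columns `marker`, `chromosome`, `position` (cM).
#'
#' @param panel_path,map_path CSV paths.
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(panel_path, map_path) {
  g <- read.csv(panel_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(g)[1L] != "line") stop("panel CSV must start with a 'line' column")
  m <- as.matrix(g[, -1L, drop = FALSE])
  rownames(m) <- g$line
  storage.mode(m) <- "double"
  map <- read.csv(map_path, stringsAsFactors = FALSE)
  marker_panel(m, map)
}

#' Write a marker panel to genotype and map CSVs
#'
#' @param panel A [marker_panel()].
#' @inheritParams read_marker_panel
#' @return Invisibly, `c(panel_path, map_path)`.
#' @export
write_marker_panel <- function(panel, panel_path, map_path) {
  g <- data.frame(line = panel$lines, panel$genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(g, panel_path, row.names = FALSE, quote = FALSE)
  write.csv(panel$map, map_path, row.names = FALSE, quote = FALSE)
  invisible(c(panel_path, map_path))
}

#' Pipeline run configuration
#'
#' @param families Response families for the G x E partition.
#' @param alpha_level Significance level for the stability slope test.
#' @param enet_alphas Elastic-net mixing values for the marker scan.
#' @param n_folds Cross-validation folds for penalty selection.
#' @param seed Seed for every stochastic step (fitters, folds).
#' @param verbose Emit `key=value` progress lines.
#' @return List of class `run_config`.
#' @export
run_config <- function(families = RESPONSE_FAMILIES[-3L],
                       alpha_level = 0.05, enet_alphas = c(0.5, 1),
                       n_folds = 10L, seed = 1L, verbose = FALSE) {
  families <- vapply(families, match.arg, "", choices = RESPONSE_FAMILIES)
  structure(list(families = unname(families), alpha_level = alpha_level,
                 enet_alphas = enet_alphas, n_folds = n_folds,
                 seed = seed, verbose = verbose),
            class = "run_config")
}

log_line <- function(verbose, ...) {
  if (verbose) message(paste(sprintf("%s=%s", names(c(...)), c(...)),
                             collapse = " "))
}

#' Run the full G x E analysis pipeline
#'
#' Per year stratum: two-way ANOVA partition, per-family G x E partition
#' (the percentage table), and Finlay-Wilkinson/Eberhart-Russell stability
#' classification. When a marker panel is supplied, additionally fits
#' per-line linear responses, derives the poor/average/good phenotypes and
#' runs the elastic-net genome scan at each configured mixing value.
#' All outputs are written as CSV plus a single JSON report; content is
#' byte-identical across runs with the same inputs and seed.
#'
#' @param config A [run_config()].
#' @param trials Trial records: a `data.frame` or a CSV path for
#'   [read_trials()].
#' @param panel Optional [marker_panel()], or a length-2 character vector
#'   `c(panel_csv, map_csv)`.
#' @param out_dir Output directory (created if absent).
#' @return The report bundle (named list), invisibly.
#' @export
run_pipeline <- function(config, trials, panel = NULL,
                         out_dir = tempfile("nlgxe_")) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.character(panel)) {
    panel <- read_marker_panel(panel[1L], panel[2L])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line(config$verbose, stage = "start", seed = config$seed)

  years <- if ("year" %in% names(trials)) {
    sort(unique(as.character(trials$year)))
  } else NA_character_

  anovas <- list(); stability <- list()
  for (yr in years) {
    sub <- if (is.na(yr)) trials else
      trials[trials$year == yr, , drop = FALSE]
    an <- anova_partition(sub)
    anovas[[as.character(yr)]] <- an[c(
      "ss_total", "ss_G", "ss_E", "ss_GxE", "ss_error",
      "df_G", "df_E", "df_GxE", "df_error",
      "n_genotypes", "n_environments", "n_reps")]
    tab <- suppressWarnings(compute_environment_index(sub))
    lin <- fit_all_genotypes(tab, "LINEAR", seed = config$seed)
    st <- suppressWarnings(classify_stability(
      lin, tab, alpha_level = config$alpha_level,
      error_ms = if (an$df_error > 0) an$ss_error / an$df_error else NULL,
      error_df = if (an$df_error > 0) an$df_error else NULL))
    st$year <- as.character(yr)
    stability[[as.character(yr)]] <- st
  }
  pct <- percent_table(trials, families = config$families,
                       seed = config$seed)
  pct$pct_explained <- round(pct$pct_explained, 2)
  stab <- do.call(rbind, stability)
  rownames(stab) <- NULL

  # Table-1-style wide layout: one row per year, one column per family
  wide <- stats::reshape(
    pct[, c("year", "family", "pct_explained")],
    idvar = "year", timevar = "family", direction = "wide")
  names(wide) <- sub("^pct_explained\\.", "", names(wide))
  write.csv(wide, file.path(out_dir, "percent_table.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(stab, file.path(out_dir, "stability.csv"),
            row.names = FALSE, quote = FALSE)

  report <- list(
    seed = config$seed,
    settings = list(families = config$families,
                    alpha_level = config$alpha_level,
                    enet_alphas = config$enet_alphas,
                    n_folds = config$n_folds),
    anova = anovas,
    percent_table = pct,
    stability = stab)

  if (!is.null(panel)) {
    # marker scan on the (single-year) line x environment data
    tab <- suppressWarnings(compute_environment_index(trials))
    lin <- fit_all_genotypes(tab, "LINEAR", seed = config$seed)
    if (nrow(lin$skipped)) {
      stop("lines without a linear fit: ",
           paste(lin$skipped$genotype, collapse = ", "))
    }
    ph <- representative_phenotypes(tab, lin)
    scan_out <- list()
    for (a in config$enet_alphas) {
      scans <- genome_scan(panel, ph,
                           enet_config(alpha = a,
                                       n_folds = config$n_folds,
                                       seed = config$seed))
      tabl <- scan_table(panel, scans)
      fn <- sprintf("scan_alpha%s.csv", format(a))
      write.csv(tabl, file.path(out_dir, fn), row.names = FALSE,
                quote = FALSE)
      scan_out[[format(a)]] <- list(
        alpha = a,
        n_nonzero = vapply(scans, `[[`, 0L, "n_nonzero"),
        lambda_selected = vapply(scans, `[[`, 0, "lambda_selected"),
        mean_abs_effect = vapply(scans, function(s) mean(abs(s$effects)),
                                 0))
      log_line(config$verbose, stage = "scan", alpha = a)
    }
    report$scan <- scan_out
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log_line(config$verbose, stage = "done", out_dir = out_dir)
  invisible(report)
}
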