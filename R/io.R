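# canonical interchange schema shared by every pipeline stage
.CANONICAL_COLUMNS <- c("id", "net_charge", "total_dipole",
                        "transversal_dipole", "mpa_mean", "mpa_sd",
                        "alogp", "accumulation")

#' Validate a compound table against the canonical schema
#'
#' Checks that the required columns are present, numeric fields are
#' numeric and finite, accumulation is non-negative, MPA fields are
#' positive/non-negative and ids are unique. Violations are collected
#' and reported together with their row numbers.
#'
#' @param table A data frame.
#' @param require_accumulation Whether the `accumulation` column is
#'   mandatory (it is for the pipeline; a pure descriptor table may
#'   omit it).
#' @return The validated table as a tibble with `id` coerced to
#'   character.
#' @export
validate_compound_table <- function(table, require_accumulation = TRUE) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    abort("compound table must be a non-empty data frame")
  }
  required <- .CANONICAL_COLUMNS
  if (!require_accumulation) required <- setdiff(required, "accumulation")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  table <- tibble::as_tibble(table)
  table$id <- as.character(table$id)
  problems <- character(0)
  dup <- table$id[duplicated(table$id)]
  if (length(dup) > 0L) {
    problems <- c(problems, paste0("duplicate id(s): ",
                                   paste(unique(dup), collapse = ", ")))
  }
  num_cols <- setdiff(required, "id")
  for (col in num_cols) {
    v <- table[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      problems <- c(problems, paste0(
        "column ", col, " is not numeric (rows ",
        paste(head(bad, 5L), collapse = ", "), ")"
      ))
      next
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      problems <- c(problems, paste0(
        "column ", col, " has missing/non-finite values (rows ",
        paste(head(bad, 5L), collapse = ", "), ")"
      ))
    }
  }
  check_range <- function(col, ok, what) {
    if (col %in% names(table) && is.numeric(table[[col]])) {
      bad <- which(!ok(table[[col]]) & is.finite(table[[col]]))
      if (length(bad) > 0L) {
        problems <<- c(problems, paste0(
          "column ", col, " must be ", what, " (rows ",
          paste(head(bad, 5L), collapse = ", "), ")"
        ))
      }
    }
  }
  if (require_accumulation) {
    check_range("accumulation", function(v) v >= 0, ">= 0")
  }
  check_range("mpa_mean", function(v) v > 0, "> 0")
  check_range("mpa_sd", function(v) v >= 0, ">= 0")
  if (length(problems) > 0L) {
    abort(paste0("compound table schema violations:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  table
}

#' Read and write compound tables
#'
#' The canonical CSV schema (`id`, `net_charge`, `total_dipole`,
#' `transversal_dipole`, `mpa_mean`, `mpa_sd`, `alogp`,
#' `accumulation`) is the single interchange format between pipeline
#' stages. Reading validates the schema and reports violations with row
#' numbers; writing emits the canonical columns first in a stable
#' order, with locale-independent formatting, so identical inputs give
#' byte-identical files.
#'
#' @param path CSV file path.
#' @param require_accumulation Passed to [validate_compound_table()].
#' @return `read_compound_table()` returns a validated tibble;
#'   `write_compound_table()` returns `path` invisibly.
#' @export
read_compound_table <- function(path, require_accumulation = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  table <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_compound_table(table, require_accumulation = require_accumulation)
}

#' @rdname read_compound_table
#' @param table A compound table.
#' @export
write_compound_table <- function(table, path) {
  cols <- c(intersect(.CANONICAL_COLUMNS, names(table)),
            setdiff(names(table), .CANONICAL_COLUMNS))
  readr::write_csv(table[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' A run configuration carries the pore model, the scoring
#' coefficients, the filter cutoffs and the descriptor settings:
#'
#' ```yaml
#' pore:
#'   name: OmpF
#'   v_pore_mV: -30
#'   e_pore_mV_per_A: 30
#'   area_mean_A2: 55
#'   area_sd_A2: 5
#' coefficients: {alpha: 0.6, beta: -0.02, gamma: 0.004, delta: 1.0}
#' filters: {accumulation_cutoff: 45, alogp_cutoff: 2.9}
#' descriptors: {n_directions: 256, resolution: 0.1}
#' ```
#'
#' A missing `coefficients` block yields a config that
#' [run_pipeline()] rejects with a calibration-required error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A config list with elements `pore` ([pore_model()]),
#'   `coefficients` ([scoring_coefficients()] or `NULL`),
#'   `accumulation_cutoff`, `alogp_cutoff`, `epsilon` and
#'   `descriptors`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$pore)) abort("config must have a pore block")
  p <- raw$pore
  pore <- pore_model(
    name = p$name %||% "OmpF",
    v_pore = p$v_pore_mV %||% p$v_pore,
    e_pore = p$e_pore_mV_per_A %||% p$e_pore,
    area_mean = p$area_mean_A2 %||% p$area_mean,
    area_sd = p$area_sd_A2 %||% p$area_sd,
    glycine_score = p$glycine_score %||% NA_real_
  )
  coefficients <- if (!is.null(raw$coefficients)) {
    cc <- raw$coefficients
    scoring_coefficients(cc$alpha, cc$beta, cc$gamma, cc$delta)
  }
  filters <- raw$filters %||% list()
  desc <- raw$descriptors %||% list()
  cutoffs <- c(filters$accumulation_cutoff %||% 45,
               filters$alogp_cutoff %||% 2.9)
  if (any(cutoffs <= 0)) abort("filter cutoffs must be positive")
  res <- desc$resolution %||% 0.1
  if (res <= 0) abort("descriptor resolution must be > 0")
  list(
    pore = pore,
    coefficients = coefficients,
    accumulation_cutoff = cutoffs[1L],
    alogp_cutoff = cutoffs[2L],
    epsilon = raw$epsilon %||% 0.1,
    descriptors = list(
      n_directions = desc$n_directions %||% 256,
      resolution = res,
      seed = desc$seed %||% 1L
    )
  )
}

#' Illustrative pore model, coefficients and run configuration
#'
#' Example parameters for an OmpF-like cation-selective general porin
#' (negative internal potential, strong transversal field, a
#' constriction of about 55 Angstrom^2 with thermal fluctuations) and
#' scoring weights on the same scale. These are illustrative
#' configuration values for demonstration and simulation, not trained
#' constants: the published scoring function's coefficients and pore
#' parameters are not public, so real applications should supply their
#' own configuration or fit coefficients to reference permeability data
#' with [fit_coefficients()].
#'
#' @return [example_pore_model()] a [pore_model()];
#'   [example_coefficients()] a [scoring_coefficients()];
#'   [example_run_config()] a full config list as returned by
#'   [read_run_config()].
#' @export
example_pore_model <- function() {
  pore_model(name = "OmpF", v_pore = -30, e_pore = 30,
             area_mean = 55, area_sd = 5)
}

#' @rdname example_pore_model
#' @export
example_coefficients <- function() {
  scoring_coefficients(alpha = 0.6, beta = -0.02, gamma = 0.004,
                       delta = 1.0)
}

#' @rdname example_pore_model
#' @export
example_run_config <- function() {
  list(
    pore = example_pore_model(),
    coefficients = example_coefficients(),
    accumulation_cutoff = 45,
    alogp_cutoff = 2.9,
    epsilon = 0.1,
    descriptors = list(n_directions = 256, resolution = 0.1, seed = 1L)
  )
}

#' Write a pipeline report to disk
#'
#' Writes three files into `out_dir`: `compounds.csv` (the scored,
#' categorised per-compound table in a stable column order),
#' `report.json` (filter audit, permeability x accumulation
#' cross-tabulation, regression summary) and `run_metadata.json`
#' (configuration echo, a configuration hash and package version) so a
#' run can be reproduced. Reruns on identical inputs produce
#' byte-identical CSV and report files.
#'
#' @param report A `porin_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "porin_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  csv_path <- file.path(out_dir, "compounds.csv")
  tab <- report$per_compound
  tab$category <- as.character(tab$category)
  tab$accumulation_category <- as.character(tab$accumulation_category)
  write_compound_table(tab, csv_path)

  reg <- report$regression
  ct <- report$crosstab
  report_json <- list(
    audit = as.list(report$audit),
    warning_empty_survivors = report$audit$kept == 0L,
    crosstab = list(
      permeability = rownames(ct),
      accumulation = colnames(ct),
      counts = matrix(as.integer(ct), nrow = nrow(ct))
    ),
    regression = if (is.null(reg)) NULL else list(
      n = reg$n, r = reg$r, p_value = reg$p_value,
      slope = reg$slope, intercept = reg$intercept
    )
  )
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_json, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  cfg <- report$config
  meta <- list(
    package = "porinperm",
    version = as.character(utils::packageVersion("porinperm")),
    config = list(
      pore = unclass(cfg$pore),
      coefficients = unclass(cfg$coefficients),
      accumulation_cutoff = cfg$accumulation_cutoff,
      alogp_cutoff = cfg$alogp_cutoff,
      epsilon = cfg$epsilon
    ),
    config_hash = rlang::hash(cfg)
  )
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(compounds = csv_path, report = json_path,
              metadata = meta_path))
}
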