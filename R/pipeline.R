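# Config-driven orchestration. Everything is stratified by sex: the risk
# definition, the marker reference ranges and the glycome distribution all
# differ between men and women, so no pooled analysis is offered.

#' Read a flat key=value run configuration
#'
#' One `key = value` (or `key: value`) pair per line; `#` comments and
#' blank lines ignored. Comma-separated values become vectors. Keys (all
#' optional unless noted): `mode` ("simulate" or "ingest"), `seed`
#' (mandatory in simulate mode), `sexes` ("M,F"), `input_csv` (ingest
#' mode), `out_dir`, `n_nonrisk`, `n_risk` (per-stratum override),
#' `univariate_columns`, `max_size`, `cv_folds`, `cv_repeats`,
#' `log_level`.
#'
#' @param path Config file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  abort_if(!file.exists(path), "config file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  abort_if(any(bad), "malformed config line: %s", lines[bad][1])
  cfg <- stats::setNames(
    lapply(kv, function(m) {
      v <- trimws(strsplit(m[3], ",")[[1]])
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) num else v
    }),
    vapply(kv, `[[`, "", 2)
  )
  run_config(cfg)
}

#' Normalize and validate a run configuration
#'
#' @param cfg Named list of raw config values.
#' @return Validated `run_config`.
#' @export
run_config <- function(cfg) {
  mode <- match.arg(cfg$mode %||% "simulate", c("simulate", "ingest"))
  if (mode == "simulate") {
    abort_if(is.null(cfg$seed), "seed is mandatory in simulate mode")
  } else {
    abort_if(is.null(cfg$input_csv) || !file.exists(cfg$input_csv),
             "ingest mode needs an existing input_csv")
  }
  sexes <- as.character(cfg$sexes %||% c("M", "F"))
  abort_if(!all(sexes %in% c("M", "F")), "sexes must be among M, F")
  out <- list(
    mode = mode,
    seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else NULL,
    sexes = sexes,
    input_csv = cfg$input_csv,
    out_dir = as.character(cfg$out_dir %||% "glycorisk-run"),
    n_nonrisk = if (!is.null(cfg$n_nonrisk)) as.integer(cfg$n_nonrisk) else NULL,
    n_risk = if (!is.null(cfg$n_risk)) as.integer(cfg$n_risk) else NULL,
    univariate_columns = as.character(cfg$univariate_columns %||% gp_labels()),
    max_size = as.integer(cfg$max_size %||% 8),
    cv_folds = as.integer(cfg$cv_folds %||% 5),
    cv_repeats = as.integer(cfg$cv_repeats %||% 2),
    log_level = as.character(cfg$log_level %||% "info")
  )
  class(out) <- "run_config"
  out
}

# Hash of the analytic configuration. Output location and verbosity do
# not affect results and are excluded, so runs into different directories
# with the same analytic settings carry the same hash.
config_hash <- function(config) {
  config <- unclass(config)
  config <- config[setdiff(names(config), c("out_dir", "log_level"))]
  flat <- paste(names(config), vapply(config, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(flat, tf)
  unname(tools::md5sum(tf))
}

log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[glycorisk] %s", sprintf(...)))
}

#' Validate an ingested cohort CSV
#'
#' Checks the schema (required columns), the closure of the 46 peak
#' columns (integration rounding up to 0.5 absolute is re-closed
#' silently; larger deviations are recorded as violations, then
#' re-closed), and value ranges (ages 18-91, non-negative markers and
#' peaks). All violations are returned, not just the first.
#'
#' @param path Cohort CSV path.
#' @return List: `cohort` (re-closed data.frame) and `violations`
#'   (data.frame `row`, `column`, `problem`; zero rows when clean).
#' @export
validate_cohort_csv <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  cohort <- read_cohort_csv(path)
  required <- c("subject_id", "sex", "risk", "age", "smoker",
                "alcohol_gweek", gp_labels(), "GGT", "MCV", "CDT")
  missing_cols <- setdiff(required, names(cohort))
  viol <- list()
  note <- function(row, column, problem) {
    viol[[length(viol) + 1]] <<- data.frame(row = row, column = column,
                                            problem = problem,
                                            stringsAsFactors = FALSE)
  }
  for (mc in missing_cols) note(NA_integer_, mc, "missing column")
  if (length(missing_cols) == 0) {
    if (!all(cohort$sex %in% c("M", "F"))) {
      for (i in which(!cohort$sex %in% c("M", "F")))
        note(i, "sex", "unknown sex code")
    }
    if (!all(cohort$risk %in% RISK_LEVELS)) {
      for (i in which(!cohort$risk %in% RISK_LEVELS))
        note(i, "risk", "unknown risk label")
    }
    for (i in which(cohort$age < 18 | cohort$age > 91))
      note(i, "age", "age outside 18-91")
    for (cl in c("GGT", "MCV", "CDT", "alcohol_gweek")) {
      for (i in which(!is.na(cohort[[cl]]) & cohort[[cl]] < 0))
        note(i, cl, "negative value")
    }
    gp <- as.matrix(cohort[, gp_labels()])
    for (i in which(gp < 0, arr.ind = TRUE)[, 1])
      note(i, "GP", "negative peak area")
    sums <- rowSums(gp)
    off <- abs(sums - 100)
    for (i in which(off > 0.5))
      note(i, "GP", sprintf("peak columns sum to %.3f, re-closed", sums[i]))
    reclose <- off > 1e-9 & sums > 0
    if (any(reclose)) {
      gp[reclose, ] <- t(apply(gp[reclose, , drop = FALSE], 1, close_to_percent))
      cohort[, gp_labels()] <- gp
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(row = integer(0), column = character(0), problem = character(0))
  list(cohort = cohort, violations = violations)
}

#' Run the full analysis pipeline
#'
#' Simulate-or-ingest a cohort, then per sex: the univariate peak screen
#' with Holm adjustment, the derived-trait comparison, balance selection
#' (adjusted for age and smoking), and the diagnostic evaluation of the
#' standard markers alone and combined with the selected balance. Writes
#' all artifacts under `config$out_dir` together with a run manifest
#' (config echo, config hash, seed, package version, wall time) and
#' returns them invisibly. Idempotent given seed and config.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @return Invisible list of per-sex results plus the manifest.
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "run_config"), "config must be a run_config")
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  if (config$mode == "simulate") {
    cohorts <- lapply(seq_along(config$sexes), function(i) {
      sx <- config$sexes[i]
      n <- NULL
      if (!is.null(config$n_nonrisk)) {
        n <- c("non-risk" = config$n_nonrisk, "risk" = config$n_risk %||% config$n_nonrisk)
      }
      generate_cohort(default_cohort_spec(sx, n_per_stratum = n,
                                          seed = config$seed + i - 1L))
    })
    cohort <- do.call(rbind, cohorts)
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
  } else {
    v <- validate_cohort_csv(config$input_csv)
    abort_if(any(is.na(v$violations$row)),
             "cohort CSV schema invalid: %s",
             paste(unique(v$violations$column[is.na(v$violations$row)]),
                   collapse = ", "))
    cohort <- v$cohort
    if (nrow(v$violations)) {
      utils::write.csv(v$violations,
                       file.path(config$out_dir, "ingest_violations.csv"),
                       row.names = FALSE)
    }
  }

  results <- list()
  for (sx in config$sexes) {
    sub <- cohort[cohort$sex == sx, ]
    if (!all(RISK_LEVELS %in% sub$risk)) {
      log_msg(config, "skipping sex %s: need both risk strata", sx)
      next
    }
    tag <- if (sx == "M") "men" else "women"
    log_msg(config, "analysing %s (n = %d)", tag, nrow(sub))

    uni <- univariate_screen(sub, config$univariate_columns)
    utils::write.csv(uni, file.path(config$out_dir,
                                    sprintf("univariate_%s.csv", tag)),
                     row.names = FALSE)
    traits <- trait_group_compare(sub)
    utils::write.csv(traits, file.path(config$out_dir,
                                       sprintf("traits_%s.csv", tag)),
                     row.names = FALSE)

    y <- as.integer(sub$risk == "risk")
    covar <- data.frame(age = sub$age, smoker = as.integer(sub$smoker))
    sel <- forward_select(sub[, gp_labels()], y, covariates = covar,
                          max_size = config$max_size,
                          cv_folds = config$cv_folds,
                          cv_repeats = config$cv_repeats,
                          seed = config$seed %||% 1L)
    jsonlite::write_json(
      list(config_hash = hash, numerator = sel$numerator,
           denominator = sel$denominator, chosen_size = sel$chosen_size,
           cv_table = sel$cv_table, seed = sel$seed),
      file.path(config$out_dir, sprintf("selection_%s.json", tag)),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(subject_id = sub$subject_id,
                                balance = sel$scores),
                     file.path(config$out_dir, sprintf("balance_scores_%s.csv", tag)),
                     row.names = FALSE)

    flags <- apply_marker_thresholds(sub$sex, sub$GGT, sub$MCV, sub$CDT)
    diag_rows <- lapply(c(GGT = "ggt_pos", MCV = "mcv_pos", CDT = "cdt_pos"),
                        function(cl) {
      tab <- tabulate_marker(flags[[cl]], sub$risk)
      dm <- diagnostic_metrics(tab)
      marker <- sub[[toupper(base::sub("_pos", "", cl))]]
      keep <- !is.na(marker)
      cmp <- compare_marker_vs_balance(marker[keep], sel$scores[keep], y[keep],
                                       covar[keep, ])
      data.frame(sens = dm$sensitivity, spec = dm$specificity,
                 lr_plus = dm$lr_plus, lr_lo = dm$lr_ci[1], lr_hi = dm$lr_ci[2],
                 auc_marker = cmp$marker$auc,
                 auc_marker_lo = cmp$marker$ci95[1],
                 auc_marker_hi = cmp$marker$ci95[2],
                 auc_balance = cmp$balance$auc,
                 auc_combined = cmp$combined$auc,
                 n = sum(keep))
    })
    diag <- cbind(marker = names(diag_rows), do.call(rbind, diag_rows),
                  config_hash = hash)
    utils::write.csv(diag, file.path(config$out_dir,
                                     sprintf("diagnostics_%s.csv", tag)),
                     row.names = FALSE)
    results[[tag]] <- list(univariate = uni, traits = traits,
                           selection = sel, diagnostics = diag)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("glycorisk")),
    r_version = R.version.string,
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    config_hash = hash,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
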