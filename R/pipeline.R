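# Orchestration: read and validate the subject CSV, assemble the per-subject
# analysis frame, run classification + HWE + association battery, and write a
# deterministic report bundle. Every number in the bundle is produced by one
# operation in one module; the orchestrator only routes data.

SUBJECT_COLUMNS <- c("id", "sex", "uninformed", paste0("c", 0:20),
                     "maoa_a1", "maoa_a2", "oxtr_a1", "oxtr_a2",
                     "rs3_a1_bp", "rs3_a2_bp")

#' Read and validate a subject CSV
#'
#' Expected header: `id, sex, uninformed, c0..c20, maoa_a1, maoa_a2 (empty
#' for males), oxtr_a1, oxtr_a2, rs3_a1_bp, rs3_a2_bp`. Rows violating the
#' behavioral invariants (sex not female/male, uninformed or schedule
#' entries outside 0..20 or non-integer, a male with two MAOA alleles) are
#' rejected with line-numbered diagnostics issued as warnings; missing
#' genotype fields are tolerated (that variant is later coded `excluded`
#' while the behavioral data are kept).
#'
#' @param path Path to the CSV file.
#' @return Validated subject data frame; rejected row diagnostics in
#'   attribute `"rejected"`.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty subject file: ", path)
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("malformed header, missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[SUBJECT_COLUMNS]
  sched_cols <- paste0("c", 0:20)
  problems <- character(0)
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header is line 1
    row_problems <- character(0)
    if (!raw$sex[i] %in% c("female", "male")) {
      row_problems <- c(row_problems, sprintf("sex '%s' invalid", raw$sex[i]))
    }
    entries <- suppressWarnings(as.numeric(raw[i, sched_cols]))
    if (anyNA(entries) || any(entries != floor(entries)) ||
        any(entries < 0 | entries > 20)) {
      row_problems <- c(row_problems, "schedule entries must be integers in [0, 20]")
    }
    u <- suppressWarnings(as.numeric(raw$uninformed[i]))
    if (is.na(u) || u != floor(u) || u < 0 || u > 20) {
      row_problems <- c(row_problems, "uninformed contribution must be an integer in [0, 20]")
    }
    if (identical(raw$sex[i], "male") && !is.na(raw$maoa_a2[i])) {
      row_problems <- c(row_problems,
                        "male rows must not carry a second MAOA allele (X-linked)")
    }
    if (length(row_problems)) {
      keep[i] <- FALSE
      problems <- c(problems, sprintf("line %d (id %s): %s", line, raw$id[i],
                                      paste(row_problems, collapse = "; ")))
    }
  }
  if (length(problems)) {
    warning("rejected ", sum(!keep), " row(s):\n  ",
            paste(problems, collapse = "\n  "), call. = FALSE)
  }
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no valid subject rows in ", path)
  rownames(out) <- NULL
  attr(out, "rejected") <- problems
  out
}

#' Assemble the per-subject analysis frame
#'
#' Codes genotypes, classifies strategies and computes scenario means for a
#' subject table, producing the frame [run_battery()] consumes.
#'
#' @param subjects Subject table ([read_subjects()] / [generate_cohort()]).
#' @param config A [classifier_config()].
#' @return Data frame with `id`, `sex`, `uninformed`, `label`, `maoa`,
#'   `oxtr`, `avpr1a`, `sm_low`, `sm_mid`, `sm_high`, plus the classifier
#'   calls in attribute `"classification"`.
#' @export
cohort_analysis_frame <- function(subjects, config = classifier_config()) {
  sched <- as.matrix(subjects[paste0("c", 0:20)])
  cls <- classify_cohort(sched, config = config, ids = subjects$id)
  coded <- code_genotypes(subjects)
  sm <- scenario_means(sched)
  out <- data.frame(
    id = subjects$id, sex = subjects$sex,
    uninformed = as.integer(subjects$uninformed),
    label = cls$calls$label,
    maoa = coded$maoa, oxtr = coded$oxtr, avpr1a = coded$avpr1a,
    sm_low = sm$low, sm_mid = sm$mid, sm_high = sm$high,
    stringsAsFactors = FALSE
  )
  attr(out, "classification") <- cls
  out
}

#' Pipeline configuration
#'
#' Exactly one of `input` (a subject CSV path) or `synthetic` (a
#' [cohort_spec()]) must be given.
#'
#' @param input Path to a subject CSV, or `NULL`.
#' @param synthetic A [cohort_spec()], or `NULL`.
#' @param classifier A [classifier_config()].
#' @param battery A [battery_config()].
#' @param seed Integer seed recorded in every output and used for the
#'   battery's stochastic steps.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            classifier = classifier_config(),
                            battery = battery_config(), seed = 1L) {
  if (is.null(input) == is.null(synthetic)) {
    stop("give exactly one of `input` (CSV path) or `synthetic` (cohort_spec)")
  }
  battery$seed <- as.integer(seed)
  structure(
    list(input = input, synthetic = synthetic, classifier = classifier,
         battery = battery, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `input` (CSV path) or `synthetic` (fields of
#' [cohort_spec()]), `classifier` (fields of [classifier_config()]),
#' `battery` (fields of [battery_config()]), `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read YAML configurations")
  }
  cfg <- yaml::read_yaml(path)
  synthetic <- if (!is.null(cfg$synthetic)) do.call(cohort_spec, cfg$synthetic)
  classifier <- do.call(classifier_config, cfg$classifier %||% list())
  battery <- do.call(battery_config, cfg$battery %||% list())
  pipeline_config(input = cfg$input, synthetic = synthetic,
                  classifier = classifier, battery = battery,
                  seed = cfg$seed %||% 1L)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

write_tsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    for (nm in names(df)) {
      if (is.double(df[[nm]])) {
        df[[nm]] <- fmt_num(df[[nm]], digits[[nm]] %||% digits[["default"]] %||% 6)
      }
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Read (or generate) the subject table, code genotypes, classify
#' strategies, test Hardy-Weinberg equilibrium, run the association battery,
#' and write the report bundle: per-subject strategy calls
#' (`strategy_calls.tsv`), the overall and by-sex strategy distribution
#' (`strategy_distribution.tsv`), the sex-difference Fisher test, per-
#' genotype strategy distributions (`genotype_distributions.tsv`),
#' per-strategy and per-genotype average profiles (`average_profiles.tsv`),
#' HWE results (`hwe.json`), the association report (`association.json`,
#' `association_tests.tsv`) and a run manifest (`manifest.json`). Reruns
#' with the same configuration and seed are byte-identical. The exit status
#' of the wrapper script reflects validation only, never test significance.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the analysis frame, classification, HWE
#'   results, the association report and the output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wrote <- character(0)
  on_failure <- function(e) {
    unlink(file.path(out_dir, wrote))
    stop("pipeline failed (partial outputs removed): ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    subjects <- if (!is.null(config$input)) {
      read_subjects(config$input)
    } else {
      generate_cohort(config$synthetic)
    }
    frame <- cohort_analysis_frame(subjects, config$classifier)
    cls <- attr(frame, "classification")

    # per-subject strategy calls
    write_tsv(cls$calls, file.path(out_dir, "strategy_calls.tsv"),
              digits = list(full_rho = 4, full_p = 6))
    wrote <- c(wrote, "strategy_calls.tsv")

    # strategy distribution, overall and by sex, plus the sex-difference test
    dist_overall <- cls$distribution
    by_sex <- lapply(split(frame$label, frame$sex), function(lb) {
      f <- factor(lb, levels = STRATEGY_LEVELS)
      as.numeric(round(100 * table(f) / length(f), 2))
    })
    dist_df <- data.frame(strategy = STRATEGY_LEVELS, overall = dist_overall)
    for (sx in names(by_sex)) dist_df[[sx]] <- by_sex[[sx]]
    write_tsv(dist_df, file.path(out_dir, "strategy_distribution.tsv"),
              digits = list(default = 2))
    wrote <- c(wrote, "strategy_distribution.tsv")

    sex_tab <- table(factor(frame$label, levels = STRATEGY_LEVELS), frame$sex)
    sex_fisher <- if (length(unique(frame$sex)) >= 2L) {
      fisher_exact(sex_tab, seed = config$seed)$p
    } else {
      NA_real_
    }

    # per-genotype strategy distributions (the battery's Fisher tables)
    geno_rows <- list()
    for (sx in unique(frame$sex)) {
      for (v in c("maoa", "oxtr", "avpr1a")) {
        sub <- frame[frame$sex == sx & frame[[v]] != "excluded", ]
        if (nrow(sub) == 0L) next
        for (g in sort(unique(sub[[v]]))) {
          lb <- factor(sub$label[sub[[v]] == g], levels = STRATEGY_LEVELS)
          geno_rows[[length(geno_rows) + 1L]] <- data.frame(
            sex = sx, variant = v, genotype = g, n = length(lb),
            t(as.numeric(round(100 * table(lb) / length(lb), 2))),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    geno_df <- do.call(rbind, geno_rows)
    names(geno_df)[5:8] <- STRATEGY_LEVELS
    write_tsv(geno_df, file.path(out_dir, "genotype_distributions.tsv"),
              digits = list(default = 2))
    wrote <- c(wrote, "genotype_distributions.tsv")

    # average profiles per strategy and per genotype
    sched <- as.matrix(subjects[paste0("c", 0:20)])
    prof <- average_profile(frame$label, sched)
    prof_rows <- data.frame(group = paste0("strategy:", rownames(prof)),
                            prof, check.names = FALSE)
    for (sx in unique(frame$sex)) {
      for (v in c("maoa", "oxtr", "avpr1a")) {
        sel <- frame$sex == sx & frame[[v]] != "excluded"
        for (g in sort(unique(frame[[v]][sel]))) {
          rows <- sel & frame[[v]] == g
          prof_rows <- rbind(prof_rows, data.frame(
            group = sprintf("%s:%s:%s", sx, v, g),
            t(colMeans(sched[rows, , drop = FALSE])), check.names = FALSE
          ))
        }
      }
    }
    write_tsv(prof_rows, file.path(out_dir, "average_profiles.tsv"),
              digits = list(default = 3))
    wrote <- c(wrote, "average_profiles.tsv")

    # Hardy-Weinberg equilibrium
    coded <- cbind(frame[c("sex")], frame[c("maoa", "oxtr", "avpr1a")])
    hwe <- list(
      oxtr = unclass(hwe_test(genotype_count_table(coded, "oxtr"))),
      avpr1a = unclass(hwe_test(genotype_count_table(coded, "avpr1a"))),
      maoa_female = unclass(maoa_female_hwe(subjects))
    )
    jsonlite::write_json(hwe, file.path(out_dir, "hwe.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    wrote <- c(wrote, "hwe.json")

    # association battery
    report <- run_battery(frame, config$battery)
    write_tsv(report$tests, file.path(out_dir, "association_tests.tsv"),
              digits = list(statistic = 4, p = 6,
                            alpha_exact = 6, alpha_printed = 5))
    wrote <- c(wrote, "association_tests.tsv")
    jsonlite::write_json(
      list(sex_difference_fisher_p = sex_fisher,
           tests = report$tests,
           ledger = report$ledger,
           skipped = report$skipped,
           n_flags = report$n_flags),
      file.path(out_dir, "association.json"),
      auto_unbox = TRUE, digits = 6, pretty = TRUE, dataframe = "rows"
    )
    wrote <- c(wrote, "association.json")

    manifest <- list(
      package = "coopgene",
      package_version = as.character(utils::packageVersion("coopgene")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      input = config$input %||% "synthetic",
      synthetic = if (!is.null(config$synthetic)) unclass(config$synthetic),
      classifier = unclass(config$classifier),
      n_subjects = nrow(frame),
      outputs = wrote
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    wrote <- c(wrote, "manifest.json")

    invisible(list(frame = frame, classification = cls, hwe = hwe,
                   report = report, sex_difference_fisher_p = sex_fisher,
                   out_dir = out_dir, outputs = file.path(out_dir, wrote)))
  }, error = on_failure)
}
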