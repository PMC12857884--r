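# Orchestration: a single config object drives the fit / simulate / screen
# workflows, and a thin argv parser exposes them as subcommands.  All
# randomness flows from config$seed; the run manifest echoes the config so a
# run can be reproduced bit-for-bit.

#' Execute a configured workflow
#'
#' Dispatches on `config$subcommand`:
#' \describe{
#'   \item{`fit`}{load a table ([load_table()]), fit [fit_gplm_bar()], write
#'     a coefficient CSV, per-covariate smooth-curve CSVs, and a JSON
#'     manifest under `out_prefix`; optional bootstrap SEs via `boot > 0`.}
#'   \item{`simulate`}{run [run_study()] and write the aggregate table CSV.}
#'   \item{`screen`}{run [screen_snps()] on a dosage table and write the
#'     retained matrix, the per-SNP statistics and the stage counts.}
#' }
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   fields: `subcommand`; for `fit`: `input`, `response`, `highdim`,
#'   `categorical`, `continuous`, `family`, `degree`, `lambda_rule`,
#'   `lambda_value`, `xi`, `boot`, `seed`, `out_prefix`; for `simulate`:
#'   `scenario`, `n`, `p`, `reps`, `methods` (names among `bar_aic`,
#'   `bar_bic`, `bar_hbic`, `oracle`), `seed`, `jobs`, `out`; for `screen`:
#'   `input`, `response_file` or `response` column, `maf`, `pvalue`,
#'   `out_prefix`.
#' @return invisibly, the main result object of the subcommand.
#' @export
gplmbar_run <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$subcommand))
  switch(config$subcommand,
         fit = run_fit(config),
         simulate = run_simulate(config),
         screen = run_screen(config),
         stop(sprintf("unknown subcommand '%s'", config$subcommand),
              call. = FALSE))
}

cfg <- function(config, name, default = NULL) {
  if (is.null(config[[name]])) default else config[[name]]
}

run_fit <- function(config) {
  data <- load_table(config$input, response = config$response,
                     highdim = cfg(config, "highdim", "."),
                     categorical = cfg(config, "categorical", character()),
                     continuous = cfg(config, "continuous", character()),
                     family = cfg(config, "family", "logistic"))
  control <- bar_control(
    xi_n = cfg(config, "xi", 1),
    lambda_rule = cfg(config, "lambda_rule", "bic"),
    lambda_value = cfg(config, "lambda_value"))
  spec <- if (ncol(data$Z)) {
    sieve_basis_spec(data$Z, degree = cfg(config, "degree", 3L))
  }
  fit <- fit_gplm_bar(data, spec, control)
  B <- cfg(config, "boot", 0L)
  boot <- if (B > 0L) {
    bootstrap_se(data, spec, control, B = B, seed = cfg(config, "seed", 1L),
                 fit = fit)
  }
  prefix <- cfg(config, "out_prefix", "gplmbar_fit")
  write_fit_outputs(fit, prefix, data = data, boot = boot)
  invisible(fit)
}

run_simulate <- function(config) {
  method_names <- cfg(config, "methods", c("bar_bic", "oracle"))
  methods <- stats::setNames(lapply(method_names, function(m) {
    switch(m,
           bar_aic = bar_control(lambda_rule = "aic"),
           bar_bic = bar_control(lambda_rule = "bic"),
           bar_hbic = bar_control(lambda_rule = "hbic"),
           oracle = "oracle",
           stop(sprintf("unknown method '%s'", m), call. = FALSE))
  }), method_names)
  res <- run_study(as.character(config$scenario), config$n, config$p,
                   cfg(config, "reps", 1L), methods,
                   base_seed = cfg(config, "seed", 0L),
                   jobs = cfg(config, "jobs", 1L))
  out <- cfg(config, "out", "gplmbar_study.csv")
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write.csv(res$table, out, row.names = FALSE)
  invisible(res)
}

run_screen <- function(config) {
  G <- load_dosage(config$input,
                   sample_id = cfg(config, "sample_id"))
  y <- if (!is.null(config$response) && config$response %in% colnames(G)) {
    yy <- G[, config$response]
    G <- G[, setdiff(colnames(G), config$response), drop = FALSE]
    yy
  } else if (!is.null(config$response_file)) {
    read_delim_auto(config$response_file)[[1L]]
  } else {
    stop("screen needs 'response' (a column of the input) or 'response_file'",
         call. = FALSE)
  }
  res <- screen_snps(y, G, maf = cfg(config, "maf", 0.1),
                     p_threshold = cfg(config, "pvalue", 0.1))
  prefix <- cfg(config, "out_prefix", "gplmbar_screen")
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  write.csv(cbind(data.frame(sample = seq_len(nrow(res$G))), res$G),
            paste0(prefix, "_retained.csv"), row.names = FALSE)
  write.csv(res$screen_table, paste0(prefix, "_snp_stats.csv"),
            row.names = FALSE)
  write.csv(res$maf_report, paste0(prefix, "_maf_report.csv"),
            row.names = FALSE)
  jsonlite::write_json(as.list(res$counts), paste0(prefix, "_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Command-line entry point
#'
#' A small argv parser wiring the `fit`, `simulate` and `screen` subcommands
#' to [gplmbar_run()].  Installed as the executable script
#' `exec/gplm-bar`; flags use `--name value` (or `--name=value`) syntax and
#' override values read from `--config FILE` (JSON).
#'
#' @param args character vector, defaulting to the process arguments.
#' @return exit status (0 on success), invisibly.
#' @export
gplmbar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: gplm-bar <fit|simulate|screen> [--config FILE] [--flag value ...]",
    "  fit:      --input FILE --response COL [--highdim C1,C2|.]",
    "            [--categorical C1,..] [--continuous C1,..] [--family F]",
    "            [--lambda-rule aic|bic|hbic|fixed] [--lambda-value V]",
    "            [--xi V] [--degree D] [--boot B] [--seed S] [--out-prefix P]",
    "  simulate: --scenario {1,2,3,3-weak} --n N --p P --reps R",
    "            [--methods bar_bic,oracle] [--seed S] [--jobs J] [--out F]",
    "  screen:   --input FILE --response COL [--maf V] [--pvalue V]",
    "            [--out-prefix P]", sep = "\n")
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  sub <- args[1L]
  flags <- parse_flags(args[-1L])
  config <- list()
  if (!is.null(flags$config)) {
    config <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    flags$config <- NULL
  }
  config[names(flags)] <- flags
  config$subcommand <- sub
  # typed coercions
  for (nm in c("n", "p", "reps", "boot", "seed", "jobs", "degree")) {
    if (!is.null(config[[nm]])) config[[nm]] <- as.integer(config[[nm]])
  }
  for (nm in c("xi", "lambda_value", "maf", "pvalue")) {
    if (!is.null(config[[nm]])) config[[nm]] <- as.numeric(config[[nm]])
  }
  for (nm in c("methods", "categorical", "continuous")) {
    if (is.character(config[[nm]])) {
      config[[nm]] <- strsplit(paste(config[[nm]], collapse = ","),
                               ",")[[1]]
    }
  }
  if (is.character(config$highdim) && !identical(config$highdim, ".")) {
    config$highdim <- strsplit(paste(config$highdim, collapse = ","),
                               ",")[[1]]
  }
  status <- tryCatch({
    gplmbar_run(config)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a),
                                   call. = FALSE)
    a <- sub("^--", "", a)
    if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1]]
      key <- kv[1]
      val <- paste(kv[-1], collapse = "=")
      i <- i + 1L
    } else {
      key <- a
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        val <- "true"
        i <- i + 1L
      } else {
        val <- args[i + 1L]
        i <- i + 2L
      }
    }
    out[[gsub("-", "_", key)]] <- val
  }
  out
}
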