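# File-based interface: delimited tables in, CSV/JSON artifacts out.

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Load a delimited table into a typed model dataset
#'
#' Reads a CSV/TSV file with a header row and assembles a [gplm_data()] from
#' an explicit column-role map.  Roles are never inferred: every referenced
#' column must exist and roles must not overlap.
#'
#' @param path CSV or TSV file (separator sniffed from the header line).
#' @param response name of the response column.
#' @param highdim character vector of high-dimensional (penalized) columns;
#'   the special value `"."` means all columns not claimed by another role.
#' @param categorical character vector of unpenalized indicator columns.
#' @param continuous character vector of continuous (sieve) columns.
#' @param family model family.
#' @return a [gplm_data()].
#' @export
load_table <- function(path, response, highdim = ".", categorical = character(),
                       continuous = character(),
                       family = c("logistic", "poisson")) {
  family <- match.arg(family)
  df <- read_delim_auto(path)
  declared <- c(response, categorical, continuous)
  if (!identical(highdim, ".")) declared <- c(declared, highdim)
  missing_cols <- setdiff(declared, names(df))
  if (length(missing_cols)) {
    stop(sprintf("column(s) not found in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(declared)) {
    stop("column roles overlap: ",
         paste(unique(declared[duplicated(declared)]), collapse = ", "),
         call. = FALSE)
  }
  if (identical(highdim, ".")) {
    highdim <- setdiff(names(df), c(response, categorical, continuous))
  }
  as_num <- function(cols, role) {
    if (!length(cols)) return(NULL)
    M <- as.matrix(df[cols])
    if (!is.numeric(M)) {
      bad <- cols[!vapply(df[cols], is.numeric, logical(1))][1L]
      stop(sprintf("non-numeric values in column '%s' (role %s)", bad, role),
           call. = FALSE)
    }
    M
  }
  gplm_data(df[[response]],
            X = if (length(highdim)) as_num(highdim, "highdim")
                else matrix(numeric(0), nrow(df), 0),
            W = as_num(categorical, "categorical"),
            Z = as_num(continuous, "continuous"),
            family = family)
}

#' Load a dosage matrix (samples x SNPs) from a delimited file
#'
#' Accepts a plain CSV/TSV whose header names the SNPs; PLINK-style `.raw`
#' exports work as a whitespace-delimited dialect (the `FID IID PAT MAT SEX
#' PHENOTYPE` preamble columns are dropped when present).
#'
#' @param path file path.
#' @param sample_id optional name of a sample-identifier column to drop.
#' @return numeric dosage matrix with SNP column names.
#' @export
load_dosage <- function(path, sample_id = NULL) {
  if (grepl("\\.raw$", path)) {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE)
    pre <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                     names(df))
    df <- df[setdiff(names(df), pre)]
  } else {
    df <- read_delim_auto(path)
    if (!is.null(sample_id)) df <- df[setdiff(names(df), sample_id)]
  }
  as.matrix(df)
}

# coefficient table + psi curves + manifest written under a common prefix
write_fit_outputs <- function(fit, prefix, data = NULL, boot = NULL,
                              grid_len = 101L) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  co <- fit$coef
  blocks <- c(rep("intercept", 1L), rep("alpha", length(co$alpha)),
              rep("gamma", length(co$gamma)), rep("beta", length(co$beta)))
  est <- coef(fit)
  tab <- data.frame(name = names(est), block = blocks, estimate = est,
                    selected = c(rep(NA, length(est) - length(co$beta)),
                                 co$beta != 0), row.names = NULL)
  if (!is.null(boot)) {
    tab$boot_se <- boot$se[match(tab$name, names(boot$se))]
  }
  write.csv(tab, paste0(prefix, "_coefficients.csv"), row.names = FALSE)
  if (!is.null(fit$spec)) {
    ix <- 0L
    for (j in seq_along(fit$spec$degree)) {
      kj <- fit$spec$degree[j] + 1L
      gam <- co$gamma[ix + seq_len(kj)]
      ix <- ix + kj
      grid <- seq(fit$spec$lower[j], fit$spec$upper[j], length.out = grid_len)
      psi <- evaluate_psi(gam, grid, fit$spec, j)
      write.csv(data.frame(z = grid, psi_hat = psi),
                sprintf("%s_psi_%s.csv", prefix, fit$spec$names[j]),
                row.names = FALSE)
    }
  }
  manifest <- list(lambda = fit$lambda, xi = fit$xi,
                   lambda_rule = fit$control$lambda_rule,
                   iterations = fit$iterations, converged = fit$converged,
                   loglik = fit$loglik, n = fit$n, p = fit$p,
                   family = fit$family,
                   selected = length(fit$active_set),
                   package_version = as.character(utils::packageVersion("gplmbar")))
  jsonlite::write_json(manifest, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tab)
}
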