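#' Minor-allele-frequency filter for a dosage matrix
#'
#' Computes each SNP's allele frequency as `mean(dosage) / 2` over
#' non-missing entries and removes SNPs whose minor allele frequency
#' `min(f, 1 - f)` is below the threshold.  The boundary is inclusive:
#' MAF exactly equal to the threshold is retained ("less than" is removed).
#' All-missing columns are removed with reason `"no data"`.
#'
#' @param G numeric matrix `n x p` of genotype dosages in `[0, 2]` (NA for
#'   missing); columns are SNPs.
#' @param threshold MAF cutoff in `(0, 0.5]`; default 0.1.
#' @param max_missing maximum tolerated per-SNP missingness rate (default 1,
#'   i.e. no missingness filter).
#' @return list with `G` (retained columns), `report` (data.frame: snp, maf,
#'   n_used, removed, reason) and `kept` (column indices).
#' @export
maf_filter <- function(G, threshold = 0.1, max_missing = 1) {
  G <- as.matrix(G)
  if (!ncol(G) || !nrow(G)) stop("empty genotype matrix", call. = FALSE)
  if (!(threshold > 0 && threshold <= 0.5)) {
    stop("MAF threshold must be in (0, 0.5]", call. = FALSE)
  }
  ok <- is.finite(G)
  if (any(G[ok] < 0 | G[ok] > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  snp <- colnames(G)
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(G)))
  n_used <- colSums(ok)
  f <- ifelse(n_used > 0, colMeans(G, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(f, 1 - f)
  miss_rate <- 1 - n_used / nrow(G)
  reason <- rep(NA_character_, ncol(G))
  reason[n_used == 0] <- "no data"
  reason[is.na(reason) & miss_rate > max_missing] <- "missingness"
  reason[is.na(reason) & maf < threshold] <- "low MAF"
  removed <- !is.na(reason)
  report <- data.frame(snp = snp, maf = maf, n_used = n_used,
                       removed = removed, reason = reason,
                       stringsAsFactors = FALSE)
  list(G = G[, !removed, drop = FALSE], report = report,
       kept = which(!removed))
}

# single-SNP logistic regression (intercept + slope) by Newton; returns the
# Wald test for the slope.  On separation/divergence the model is refit with
# a small ridge and flagged.
uni_logit <- function(y, g, ridge = 0, maxit = 50L, tol = 1e-10) {
  ok <- is.finite(g)
  y <- y[ok]
  g <- g[ok]
  D <- cbind(1, g)
  th <- c(0, 0)
  flagged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% th)
    mu <- 1 / (1 + exp(-eta))
    v <- mu * (1 - mu)
    H <- crossprod(D * sqrt(pmax(v, 1e-12))) + diag(ridge, 2)
    gr <- drop(crossprod(D, y - mu)) - ridge * th
    step <- tryCatch(drop(solve(H, gr)), error = function(e) rep(NA_real_, 2))
    if (anyNA(step)) {
      flagged <- TRUE
      break
    }
    th <- th + step
    if (max(abs(step)) < tol) break
    if (abs(th[2]) > 15) { # unbounded slope: (quasi-)separation
      flagged <- TRUE
      break
    }
  }
  if (it == maxit) flagged <- TRUE
  if (flagged && ridge == 0) {
    res <- uni_logit(y, g, ridge = 1e-4, maxit = maxit, tol = tol)
    res$flagged <- TRUE
    return(res)
  }
  eta <- drop(D %*% th)
  mu <- 1 / (1 + exp(-eta))
  H <- crossprod(D * sqrt(pmax(mu * (1 - mu), 1e-12))) + diag(ridge, 2)
  se <- sqrt(diag(solve(H)))
  z <- th[2] / se[2]
  if (flagged) {
    # Wald is degenerate under separation (Hauck-Donner); use the
    # likelihood-ratio test of the stabilized fit against the null
    dev1 <- -2 * sum(y * eta - log1p(exp(eta)))
    p0 <- mean(y)
    dev0 <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
    pval <- pchisq(dev0 - dev1, df = 1, lower.tail = FALSE)
  } else {
    pval <- 2 * pnorm(-abs(z))
  }
  list(estimate = th[2], se = se[2], z = z,
       p_value = pval, flagged = flagged, n_used = length(y))
}

#' Univariate logistic screening of SNPs
#'
#' Fits `logit P(y = 1) = b0 + b1 g` separately for every SNP and retains
#' those with Wald p-value below `p_threshold` (strictly).  SNPs exhibiting
#' separation are refit with a small stabilizing ridge and flagged (they stay
#' eligible for retention).  Complete observations are used per SNP.
#'
#' @param y binary 0/1 response of length n.
#' @param G dosage matrix `n x p` (columns are SNPs; NA allowed).
#' @param p_threshold retention cutoff on the Wald p-value; default 0.1.
#' @return list with `table` (data.frame: snp, estimate, se, z, p_value,
#'   flagged, retained), `kept` (column indices) and `G` (retained columns).
#' @export
univariate_screen <- function(y, G, p_threshold = 0.1) {
  G <- as.matrix(G)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be a 0/1 vector", call. = FALSE)
  if (nrow(G) != length(y)) stop("y and G have different lengths",
                                 call. = FALSE)
  snp <- colnames(G)
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(G)))
  rows <- lapply(seq_len(ncol(G)), function(j) {
    r <- uni_logit(y, G[, j])
    data.frame(snp = snp[j], estimate = r$estimate, se = r$se, z = r$z,
               p_value = r$p_value, flagged = r$flagged,
               retained = r$p_value < p_threshold, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  kept <- which(tab$retained)
  list(table = tab, kept = kept, G = G[, kept, drop = FALSE])
}

#' Transform a continuous covariate, recording the rule
#'
#' @param values numeric vector.
#' @param rule `"identity"` or `"log"` (natural logarithm; requires strictly
#'   positive values).
#' @return numeric vector with attribute `transform` set to the rule, so the
#'   same rule can be replayed at prediction time.
#' @export
transform_continuous <- function(values, rule = c("identity", "log")) {
  rule <- match.arg(rule)
  if (rule == "log") {
    bad <- which(!(values > 0))
    if (length(bad)) {
      stop(sprintf("log transform requires positive values; first offending row: %d (value %g)",
                   bad[1L], values[bad[1L]]), call. = FALSE)
    }
    values <- log(values)
  }
  attr(values, "transform") <- rule
  values
}

#' SNP screening pipeline: MAF filter, then univariate logistic screening
#'
#' @param y binary response.
#' @param G dosage matrix.
#' @param maf MAF cutoff (see [maf_filter()]).
#' @param p_threshold screening p-value cutoff (see [univariate_screen()]).
#' @return list with the retained matrix `G`, both stage reports, and
#'   `counts` (SNPs entering, after the MAF filter, after screening).
#' @export
screen_snps <- function(y, G, maf = 0.1, p_threshold = 0.1) {
  stage1 <- maf_filter(G, threshold = maf)
  stage2 <- univariate_screen(y, stage1$G, p_threshold = p_threshold)
  list(G = stage2$G, maf_report = stage1$report, screen_table = stage2$table,
       counts = c(input = ncol(as.matrix(G)), after_maf = ncol(stage1$G),
                  after_screen = ncol(stage2$G)))
}
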