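# Sample QC, low-expression filtering, covariate screening, and
# brain-vs-nonbrain differential expression.

#' Retain samples passing mapping QC
#'
#' Samples are kept only when the number of uniquely mapped reads is
#' strictly greater than \code{minReads} AND the unique mapping rate is
#' strictly greater than \code{minRate} (so a sample at exactly 12 million
#' reads is removed). Removals are logged via message.
#'
#' @param study an [ExpressionStudy-class] whose metadata carries
#'   \code{uniquely_mapped_reads} and \code{unique_map_rate}.
#' @param minReads,minRate strict lower thresholds (defaults: 12 million
#'   reads, rate 0.70).
#' @return The filtered study.
#' @export
qcFilterSamples <- function(study, minReads = 12e6, minRate = 0.70) {
  cd <- colData(study)
  if (!all(c("uniquely_mapped_reads", "unique_map_rate") %in% colnames(cd)))
    stopf("sample metadata must carry uniquely_mapped_reads and unique_map_rate")
  keep <- cd$uniquely_mapped_reads > minReads & cd$unique_map_rate > minRate
  if (any(!keep))
    message("qcFilterSamples: removed ", sum(!keep), " sample(s): ",
            paste(colnames(study)[!keep], collapse = ", "))
  study[, keep]
}

#' Remove lowly expressed genes
#'
#' A gene is retained iff it has a nonzero count in strictly more than
#' \code{minFraction} of samples (a gene nonzero in exactly 20% of samples
#' is removed at the default).
#'
#' @param study an [ExpressionStudy-class].
#' @param minFraction strict lower bound on the expressed-sample fraction.
#' @return The filtered study.
#' @export
filterLowExpression <- function(study, minFraction = 0.20) {
  if (ncol(study) == 0) stopf("study has no samples")
  keep <- rowMeans(assay(study, "counts") > 0) > minFraction
  study[keep, ]
}

#' Screen covariates for imbalance between brain and nonbrain groups
#'
#' Numeric covariates (age, RIN) are compared with a two-sided
#' Mann-Whitney U test; categorical covariates (sex) with a Fisher exact
#' test. A covariate is flagged when p < 0.05; flagged covariates should be
#' included in the differential expression design. Constant covariates get
#' p = 1 and are never flagged.
#'
#' @param study an [ExpressionStudy-class].
#' @param covariates metadata columns to screen (those present are used).
#' @param alpha flagging threshold.
#' @return data.frame with columns covariate, type, statistic, p, flagged.
#' @export
covariateScreen <- function(study, covariates = c("age", "sex", "rin"),
                            alpha = 0.05) {
  cd <- colData(study)
  covariates <- intersect(covariates, colnames(cd))
  grp <- cd$group == "brain"
  if (sum(grp) < 2 || sum(!grp) < 2)
    stopf("covariate screen requires >= 2 samples per group")
  rows <- lapply(covariates, function(cv) {
    x <- cd[[cv]]
    if (is.numeric(x)) {
      if (length(unique(x)) == 1)
        return(data.frame(covariate = cv, type = "numeric",
                          statistic = NA_real_, p = 1))
      wt <- suppressWarnings(wilcox.test(x[grp], x[!grp],
                                         alternative = "two.sided"))
      data.frame(covariate = cv, type = "numeric",
                 statistic = unname(wt$statistic), p = wt$p.value)
    } else {
      tab <- table(factor(grp, c(TRUE, FALSE)), as.character(x))
      if (ncol(tab) < 2)
        return(data.frame(covariate = cv, type = "categorical",
                          statistic = NA_real_, p = 1))
      ft <- fisher.test(tab)
      data.frame(covariate = cv, type = "categorical",
                 statistic = NA_real_, p = ft$p.value)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(covariate = character(), type = character(),
                      statistic = numeric(), p = numeric())
  out$flagged <- out$p < alpha
  out
}

# Vectorized Welch two-sample t-test on rows of y (genes x samples).
welchRows <- function(y, grp) {
  n1 <- sum(grp); n0 <- sum(!grp)
  m1 <- rowMeans(y[, grp, drop = FALSE])
  m0 <- rowMeans(y[, !grp, drop = FALSE])
  v1 <- apply(y[, grp, drop = FALSE], 1, stats::var)
  v0 <- apply(y[, !grp, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate rows: zero variance in both groups
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m0[degen], 1, 0)
  list(log2fc = m1 - m0, p = p)
}

#' Brain-versus-nonbrain differential expression
#'
#' Fits, per gene, a linear model on \code{y = log2(count / sizeFactor + 1)}
#' with the brain/nonbrain group term plus any flagged covariates; with no
#' covariates this reduces to a Welch two-sample t-test. The reported
#' \code{log2fc} is always \code{mean(y[brain]) - mean(y[nonbrain])}.
#' P-values are BH-adjusted and a gene is called (\code{up_in_brain} /
#' \code{down_in_brain}) iff \code{fdr < q} and \code{|log2fc| >= lfcMin}.
#'
#' Covariates collinear with the group (e.g. perfectly confounded) are
#' dropped with a warning.
#'
#' @param study an [ExpressionStudy-class].
#' @param sizeFactors per-sample size factors (computed with
#'   [sizeFactorsMedianOfRatios()] when omitted).
#' @param covariates character vector of metadata columns to adjust for
#'   (typically the flagged rows of [covariateScreen()]).
#' @param q FDR threshold (default 0.05).
#' @param lfcMin inclusive absolute log2 fold-change gate (default 1.5).
#' @return A [DEResult-class] with one row per gene.
#' @export
brainVsNonbrainDE <- function(study, sizeFactors = NULL,
                              covariates = character(0),
                              q = 0.05, lfcMin = 1.5) {
  cts <- assay(study, "counts")
  grp <- colData(study)$group == "brain"
  if (sum(grp) < 2 || sum(!grp) < 2)
    stopf("differential expression requires >= 2 samples per group")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianOfRatios(cts)
  y <- log2(sweep(cts, 2, sizeFactors[colnames(cts)], "/") + 1)

  if (length(covariates)) {
    cd <- as.data.frame(colData(study))[, covariates, drop = FALSE]
    X <- model.matrix(~ grp + ., data = cd)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      droppedCols <- colnames(X)[qrX$pivot[seq_len(ncol(X))] >
                                   qrX$rank][integer(0)]
      # identify covariates whose columns are linearly dependent
      keepIdx <- qrX$pivot[seq_len(qrX$rank)]
      lost <- colnames(X)[setdiff(seq_len(ncol(X)), keepIdx)]
      warnf("dropping covariate column(s) collinear with the design: %s",
            paste(lost, collapse = ", "))
      X <- X[, sort(keepIdx), drop = FALSE]
    }
    if (!"grpTRUE" %in% colnames(X))
      stopf("group term lost from the design; cannot test")
    fit <- lm.fit(X, t(y))
    cf <- fit$coefficients
    res <- fit$residuals
    dfres <- nrow(X) - fit$rank
    sigma2 <- colSums(res^2) / dfres
    xtxi <- chol2inv(qr.R(qr(X)))
    j <- which(colnames(X) == "grpTRUE")
    se <- sqrt(sigma2 * xtxi[j, j])
    tstat <- cf[j, ] / se
    p <- 2 * pt(-abs(tstat), dfres)
    p[se == 0] <- ifelse(cf[j, se == 0] == 0, 1, 0)
    lfc <- rowMeans(y[, grp, drop = FALSE]) -
      rowMeans(y[, !grp, drop = FALSE])
  } else {
    w <- welchRows(y, grp)
    lfc <- w$log2fc
    p <- w$p
  }
  fdr <- bhAdjust(p)
  call <- rep("ns", nrow(y))
  call[fdr < q & lfc >= lfcMin] <- "up_in_brain"
  call[fdr < q & lfc <= -lfcMin] <- "down_in_brain"
  out <- DataFrame(log2fc = unname(lfc), p = unname(p), fdr = unname(fdr),
                   call = call, row.names = rownames(y))
  metadata(out) <- list(q = q, lfcMin = lfcMin, covariates = covariates)
  new("DEResult", out)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (sort ascending, \code{adj_i = min_{k >= i}
#' m p_k / k}, capped at 1, original order restored). Values outside [0, 1]
#' are rejected.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return Adjusted values in the original order.
#' @export
bhAdjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1] with no missing values")
  p.adjust(pvalues, method = "BH")
}
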