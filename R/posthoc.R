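## Multiple-comparison procedures for haplotype phenotype contrasts:
## Duncan's multiple range test and Fisher's LSD, with compact letter
## displays. Exact studentized-range quantiles (stats::qtukey) are used, not
## table lookups.

## One-way ANOVA pieces shared by both procedures.
anova_pieces <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2)
    ag_stop("post-hoc tests need at least 2 groups", "alkagerm_validation_error")
  ns <- table(groups)
  if (any(ns < 2))
    ag_stop("every group needs at least 2 observations", "alkagerm_validation_error")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  list(values = values, groups = groups,
       means = tapply(values, groups, mean), ns = ns,
       mse = an[2, "Mean Sq"], df_error = an[2, "Df"],
       F = an[1, "F value"], p = an[1, "Pr(>F)"])
}

## Compact letter display from an ordered non-significance relation.
## `nonsig[i, j]` refers to means ordered decreasing; the relation is an
## interval property (closure enforced by the callers), so letters are the
## maximal index intervals whose endpoints do not differ. Letters are
## inserted largest-mean first and intervals contained in an already-lettered
## one are absorbed.
letters_from_nonsig <- function(nonsig) {
  k <- nrow(nonsig)
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    intervals[[length(intervals) + 1L]] <- c(i, j)
  }
  ## absorb intervals contained in an earlier (larger) one
  keep <- list()
  for (iv in intervals) {
    contained <- any(vapply(keep, function(kv)
      kv[1] <= iv[1] && iv[2] <= kv[2], logical(1)))
    if (!contained) keep[[length(keep) + 1L]] <- iv
  }
  lab <- rep("", k)
  for (li in seq_along(keep)) {
    iv <- keep[[li]]
    lab[iv[1]:iv[2]] <- paste0(lab[iv[1]:iv[2]], letters[li])
  }
  lab
}

#' Duncan's multiple range test
#'
#' Step-down multiple comparison of group means after one-way ANOVA. Means
#' `p` steps apart in the descending order are compared against the critical
#' range `q(alpha_p, p, df_error) * sqrt(MSE / n_h)`, where
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` is Duncan's protection level, `q` the
#' studentized-range quantile and `n_h` the harmonic mean group size (the
#' unequal-n convention). A range found non-significant protects all the
#' ranges it contains. With zero residual variance and unequal means, all
#' pairs are declared different.
#'
#' @param values numeric response (e.g. a ratio trait per accession).
#' @param groups group labels (e.g. haplotype), same length.
#' @param alpha test level (default 0.05).
#' @return Object of class `duncan_test`: `table` (group, n, mean, letters,
#'   ordered by decreasing mean), `F`, `p`, `mse`, `df_error`, `alpha`,
#'   `critical_ranges`.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  an <- anova_pieces(values, groups)
  o <- order(an$means, decreasing = TRUE)
  means <- an$means[o]; ns <- an$ns[o]
  k <- length(means)
  n_h <- k / sum(1 / ns)
  crit <- vapply(2:max(k, 2), function(p)
    stats::qtukey((1 - alpha)^(p - 1), p, an$df_error) * sqrt(an$mse / n_h),
    numeric(1))
  names(crit) <- paste0("range", 2:max(k, 2))
  zero_mse <- an$mse <= .Machine$double.eps * max(abs(an$values), 1)
  ## step-down significance: protected ranges
  nonsig <- matrix(TRUE, k, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      diff <- means[i] - means[j]
      if (zero_mse) {
        nonsig[i, j] <- nonsig[j, i] <- diff == 0
      } else {
        protected <- FALSE
        if (span < k) {
          ## contained in a non-significant wider range?
          for (a in seq_len(k - span)) {
            b <- a + span
            if (a <= i && j <= b && nonsig[a, b]) { protected <- TRUE; break }
          }
        }
        nonsig[i, j] <- nonsig[j, i] <-
          protected || diff <= crit[span - 1L]
      }
    }
  }
  tab <- data.frame(group = names(means), n = as.integer(ns),
                    mean = as.numeric(means),
                    letters = letters_from_nonsig(nonsig),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, F = an$F, p = an$p, mse = an$mse,
                 df_error = an$df_error, alpha = alpha,
                 critical_ranges = crit, method = "duncan"),
            class = "duncan_test")
}

#' @export
print.duncan_test <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g)\n", x$alpha))
  cat(sprintf("ANOVA F = %.3f, p = %.3g, MSE = %.4g on %d df\n",
              x$F, x$p, x$mse, x$df_error))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fisher's least significant difference test
#'
#' Pairwise t-comparisons on the pooled ANOVA mean square; groups are
#' lettered by the same compact-display rule as [duncan_mrt()]. Used for the
#' haplotype-combination (pyramiding) comparison.
#'
#' @inheritParams duncan_mrt
#' @return Object of class `duncan_test` with `method = "lsd"`.
#' @export
lsd_test <- function(values, groups, alpha = 0.05) {
  an <- anova_pieces(values, groups)
  o <- order(an$means, decreasing = TRUE)
  means <- an$means[o]; ns <- an$ns[o]
  k <- length(means)
  tcrit <- stats::qt(1 - alpha / 2, an$df_error)
  zero_mse <- an$mse <= .Machine$double.eps * max(abs(an$values), 1)
  nonsig <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (zero_mse) {
        nonsig[i, j] <- nonsig[j, i] <- means[i] == means[j]
      } else {
        lsd <- tcrit * sqrt(an$mse * (1 / ns[i] + 1 / ns[j]))
        nonsig[i, j] <- nonsig[j, i] <- (means[i] - means[j]) <= lsd
      }
    }
  }
  ## enforce interval closure for the letter display
  for (span in 2:max(k - 1, 2)) {
    if (span > k - 1) break
    for (i in seq_len(k - span)) {
      j <- i + span
      if (nonsig[i, j]) {
        for (a in i:j) for (b in i:j) nonsig[a, b] <- TRUE
      }
    }
  }
  tab <- data.frame(group = names(means), n = as.integer(ns),
                    mean = as.numeric(means),
                    letters = letters_from_nonsig(nonsig),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, F = an$F, p = an$p, mse = an$mse,
                 df_error = an$df_error, alpha = alpha,
                 critical_ranges = NULL, method = "lsd"),
            class = "duncan_test")
}
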