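## Germination trait computation: the seven condition traits, their
## stress:control ratios, summaries, correlations and group comparisons.

trait_names_condition <- function() {
  c("MGTS", "MGTC", "GRS", "GRC", "GIS", "GIC", "VIS", "VIC",
    "RLS", "RLC", "SLS", "SLC", "GES", "GEC")
}

trait_names_ratio <- function() {
  c("RMGT", "RGR", "RGI", "RVI", "RRL", "RSL", "RGE")
}

#' Germination rate through a given day
#'
#' Cumulative germinated fraction: GR (day 7) and GE, the germination energy
#' (day 3), are both this statistic at different days.
#'
#' @param new_counts integer vector of newly germinated seeds on days 1..7.
#' @param n0 total number of sown seeds.
#' @param day cutoff day in 1..7 (7 for GR, 3 for GE).
#' @return Proportion in `[0, 1]`.
#' @export
germination_rate <- function(new_counts, n0, day = 7) {
  stopifnot(length(new_counts) == 7, day >= 1, day <= 7)
  if (n0 == 0) ag_stop("no seeds sown (N0 = 0)", "alkagerm_validation_error")
  sum(new_counts[seq_len(day)]) / n0
}

#' Mean germination time
#'
#' Count-weighted mean day of new germinations,
#' `MGT = sum(t * N_t) / sum(N_t)`. Undefined (NA) when no seed germinated.
#'
#' @inheritParams germination_rate
#' @return Days in `[1, 7]`, or `NA` when nothing germinated.
#' @export
mean_germination_time <- function(new_counts) {
  stopifnot(length(new_counts) == 7)
  tot <- sum(new_counts)
  if (tot == 0) return(NA_real_)
  sum((1:7) * new_counts) / tot
}

#' Germination index
#'
#' Day-weighted germination statistic rewarding early germination:
#' `GI = (1/N0) * sum_t C_t / t`, where `C_t` is the cumulative number of
#' germinated seeds through day `t`. The `1/N0` normalization puts GI on the
#' same 0..2.593 scale for any seed number; complete germination on day 3
#' gives `sum_{t=3..7} 1/t = 1.093`.
#'
#' @inheritParams germination_rate
#' @return Dimensionless index in `[0, sum_{t=1..7} 1/t]`.
#' @export
germination_index <- function(new_counts, n0) {
  stopifnot(length(new_counts) == 7)
  if (n0 == 0) ag_stop("no seeds sown (N0 = 0)", "alkagerm_validation_error")
  cum <- cumsum(new_counts)
  sum(cum / (1:7)) / n0
}

#' Vigor index
#'
#' `VI = mean shoot length (cm) x GI`. Missing inputs propagate.
#'
#' @param mean_shoot_length mean shoot length in cm.
#' @param gi germination index.
#' @return cm-scaled index, or NA.
#' @export
vigor_index <- function(mean_shoot_length, gi) {
  if (is.na(mean_shoot_length) || is.na(gi)) return(NA_real_)
  stopifnot(mean_shoot_length >= 0, gi >= 0)
  mean_shoot_length * gi
}

## Traits of one replicate record (a one-row slice of germination_counts).
replicate_traits <- function(row) {
  cnt <- as.numeric(unlist(row[paste0("d", 1:7)]))
  n0 <- as.numeric(row[["total_seeds"]])
  gi <- germination_index(cnt, n0)
  sl <- as.numeric(row[["shoot_length_cm"]])
  c(MGT = mean_germination_time(cnt),
    GR = germination_rate(cnt, n0, 7),
    GE = germination_rate(cnt, n0, 3),
    GI = gi,
    RL = as.numeric(row[["root_length_cm"]]),
    SL = sl,
    VI = vigor_index(sl, gi))
}

#' Per-accession 21-trait table
#'
#' Computes the seven germination-related traits per replicate, averages the
#' replicates within each condition (suffix `S` for alkali stress, `C` for
#' control), then forms the seven stress:control ratio traits (`RMGT` ... `RGE`)
#' from the replicate-averaged condition values. A ratio is missing when its
#' control value is 0 (e.g. `RGE` when `GEC = 0`).
#'
#' @param gc a `germination_counts` table ([read_phenotype_table()]).
#' @return data.frame of class `trait_table`: one row per accession with
#'   columns `accession`, `MGTS` ... `GEC`, `RMGT` ... `RGE`.
#' @export
compute_trait_table <- function(gc) {
  base <- c("MGT", "GR", "GE", "GI", "RL", "SL", "VI")
  per_rep <- t(vapply(seq_len(nrow(gc)),
                      function(i) replicate_traits(gc[i, , drop = FALSE]),
                      numeric(7)))
  acc <- unique(gc$accession)
  cond_mean <- function(a, cond) {
    sel <- gc$accession == a & gc$condition == cond
    if (!any(sel)) return(stats::setNames(rep(NA_real_, 7), base))
    ## average over replicates where the trait is defined (MGT can be
    ## undefined in a single zero-germination replicate)
    m <- colMeans(per_rep[sel, , drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }
  rows <- lapply(acc, function(a) {
    s <- cond_mean(a, "stress")
    c <- cond_mean(a, "control")
    ratio <- ifelse(!is.na(c) & c == 0, NA_real_, s / c)
    names(ratio) <- paste0("R", base)
    out <- c(stats::setNames(as.vector(rbind(s, c)),
                             as.vector(rbind(paste0(base, "S"), paste0(base, "C")))),
             ratio)
    out
  })
  tab <- as.data.frame(do.call(rbind, rows))
  ## canonical column order
  ord <- c("MGTS", "MGTC", "GRS", "GRC", "GIS", "GIC", "VIS", "VIC",
           "RLS", "RLC", "SLS", "SLC", "GES", "GEC",
           "RMGT", "RGR", "RGI", "RVI", "RRL", "RSL", "RGE")
  tab <- tab[, ord]
  tab <- cbind(accession = acc, tab)
  rownames(tab) <- NULL
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Summarize traits (range, mean, SD, CV)
#'
#' Sample SD uses the n-1 denominator; `CV = SD / mean` (NA when the mean is
#' 0). Traits with fewer than 2 non-missing values are flagged missing.
#'
#' @param traits a `trait_table` (or any data.frame of numeric trait columns).
#' @return data.frame with columns `trait`, `min`, `max`, `mean`, `sd`, `cv`,
#'   `n`.
#' @export
summarize_traits <- function(traits) {
  num <- traits[, vapply(traits, is.numeric, logical(1)), drop = FALSE]
  rows <- lapply(names(num), function(tr) {
    x <- num[[tr]][!is.na(num[[tr]])]
    if (length(x) < 2)
      return(data.frame(trait = tr, min = NA_real_, max = NA_real_,
                        mean = NA_real_, sd = NA_real_, cv = NA_real_,
                        n = length(x)))
    m <- mean(x); s <- stats::sd(x)
    data.frame(trait = tr, min = min(x), max = max(x), mean = m, sd = s,
               cv = if (m != 0) s / m else NA_real_, n = length(x))
  })
  do.call(rbind, rows)
}

#' Relative alkali damage from ratio-trait means
#'
#' Converts mean ratio traits into damage percentages: MGT is *delayed* by
#' `100 * (mean RMGT - 1)` percent; every other trait is *reduced* by
#' `100 * (1 - mean ratio)` percent. Traits are returned ordered by decreasing
#' damage.
#'
#' @param ratio_means named numeric vector of ratio-trait means with names
#'   among `RMGT`, `RGR`, `RGI`, `RVI`, `RRL`, `RSL`, `RGE` (e.g. the `mean`
#'   column of [summarize_traits()]), or a `trait_table` whose ratio columns
#'   are averaged over accessions.
#' @return data.frame with columns `trait` (base trait name), `ratio_mean`,
#'   `damage_pct`, `direction` (`delay` for MGT, `reduction` otherwise),
#'   sorted by decreasing `damage_pct`.
#' @export
relative_damage <- function(ratio_means) {
  if (is.data.frame(ratio_means)) {
    keep <- intersect(trait_names_ratio(), names(ratio_means))
    ratio_means <- vapply(ratio_means[keep], function(x) mean(x, na.rm = TRUE),
                          numeric(1))
  }
  keep <- intersect(trait_names_ratio(), names(ratio_means))
  ratio_means <- ratio_means[keep]
  base <- sub("^R", "", names(ratio_means))
  damage <- ifelse(base == "MGT",
                   100 * (ratio_means - 1),
                   100 * (1 - ratio_means))
  out <- data.frame(trait = base, ratio_mean = as.numeric(ratio_means),
                    damage_pct = as.numeric(damage),
                    direction = ifelse(base == "MGT", "delay", "reduction"),
                    stringsAsFactors = FALSE)
  out[order(-out$damage_pct), , drop = FALSE]
}

#' Spearman correlation matrix across traits
#'
#' Tie-corrected Spearman rank correlations on pairwise-complete observations;
#' cells with fewer than 3 complete pairs are set to NA.
#'
#' @param traits a `trait_table` or numeric data.frame.
#' @return Symmetric correlation matrix.
#' @export
correlate_traits <- function(traits) {
  num <- as.matrix(traits[, vapply(traits, is.numeric, logical(1)), drop = FALSE])
  rho <- suppressWarnings(
    stats::cor(num, method = "spearman", use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(num))
  rho[npair < 3] <- NA_real_
  rho
}

#' Compare a trait between subpopulations
#'
#' One-way ANOVA across all subpopulations with at least `min_n` members, plus
#' two-tailed Welch and pooled-variance t-tests for a stated pair.
#'
#' @param traits a `trait_table`.
#' @param metadata accession metadata ([read_metadata()]).
#' @param trait trait column name (e.g. `"RGE"`).
#' @param pair character vector of two subpopulations for the t-tests.
#' @param min_n minimum group size to enter the ANOVA.
#' @return List with `anova` (`F`, `p`, `df`), `welch` and `pooled` t-test
#'   results (`t`, `p`) for `pair`, and the group sizes.
#' @export
compare_subpopulations <- function(traits, metadata, trait,
                                   pair = c("Xian", "Geng"), min_n = 2) {
  y <- traits[[trait]]
  grp <- metadata$subpopulation[match(traits$accession, metadata$accession)]
  ok <- !is.na(y) & !is.na(grp)
  y <- y[ok]; grp <- grp[ok]
  keep <- names(which(table(grp) >= min_n))
  if (length(keep) < 2)
    ag_stop("need at least two subpopulations with enough members",
            "alkagerm_validation_error")
  sel <- grp %in% keep
  y <- y[sel]; grp <- factor(grp[sel])
  fit <- stats::aov(y ~ grp)
  an <- summary(fit)[[1]]
  res <- list(anova = list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
                           df = unname(an[, "Df"])),
              groups = table(grp))
  if (all(pair %in% levels(grp))) {
    a <- y[grp == pair[1]]; b <- y[grp == pair[2]]
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
      res$welch <- res$pooled <- list(t = 0, p = 1)
    } else {
      w <- stats::t.test(a, b)
      p <- stats::t.test(a, b, var.equal = TRUE)
      res$welch <- list(t = unname(w$statistic), p = w$p.value)
      res$pooled <- list(t = unname(p$statistic), p = p$p.value)
    }
  }
  res
}
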