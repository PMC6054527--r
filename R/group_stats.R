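#' Median and quartile summary of a group
#'
#' Quartiles use the linear-interpolation convention (`stats::quantile`
#' type 7).
#'
#' @param values numeric vector; non-finite values are dropped.
#' @param label optional group label.
#' @return one-row data.frame `group`, `n`, `median`, `q25`, `q75`.
#' @export
summarize_group <- function(values, label = NA_character_) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no finite values to summarize")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(group = label, n = length(v), median = q[2], q25 = q[1],
             q75 = q[3], stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Thin contract over `stats::wilcox.test` (normal approximation with ties);
#' degenerate all-tied input returns p = 1.
#'
#' @param a,b numeric vectors (non-finite values dropped).
#' @return two-sided p-value.
#' @export
ranksum_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1) return(1)
  suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
}

#' Two-sided paired t comparison
#'
#' @param pre,post equal-length paired vectors; pairs with a non-finite
#'   member are dropped.
#' @return two-sided p-value; exactly identical vectors give 1 (the test is
#'   undefined at zero variance).
#' @export
paired_compare <- function(pre, post) {
  if (length(pre) != length(post)) stop("paired vectors differ in length")
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  stopifnot(length(pre) >= 2)
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(if (all(d == 0)) 1 else 0)
  }
  stats::t.test(post, pre, paired = TRUE)$p.value
}

#' Two-way factorial ANOVA contract
#'
#' Fits `response ~ genotype * session` with `stats::aov` and reports F and p
#' for the two main effects and their interaction. If any design cell is
#' empty the interaction is reported missing and an additive model is fitted
#' for the main effects.
#'
#' @param values numeric response.
#' @param genotype,session factors (coerced).
#' @return data.frame `effect`, `F`, `p` with rows genotype, session,
#'   interaction.
#' @export
factorial_compare <- function(values, genotype, session) {
  g <- factor(genotype); s <- factor(session)
  stopifnot(nlevels(g) >= 2, nlevels(s) >= 2, length(values) == length(g),
            length(g) == length(s))
  full_cells <- table(g, s)
  has_empty <- any(full_cells == 0)
  # interaction needs residual df beyond the cell means
  df_resid_full <- length(values) - sum(full_cells > 0)
  if (has_empty || df_resid_full <= 0) {
    tab <- summary(stats::aov(values ~ g + s))[[1]]
    rownames(tab) <- trimws(rownames(tab))
    data.frame(effect = c("genotype", "session", "interaction"),
               F = c(tab["g", "F value"], tab["s", "F value"], NA_real_),
               p = c(tab["g", "Pr(>F)"], tab["s", "Pr(>F)"], NA_real_),
               stringsAsFactors = FALSE)
  } else {
    tab <- summary(stats::aov(values ~ g * s))[[1]]
    rownames(tab) <- trimws(rownames(tab))
    data.frame(effect = c("genotype", "session", "interaction"),
               F = c(tab["g", "F value"], tab["s", "F value"],
                     tab["g:s", "F value"]),
               p = c(tab["g", "Pr(>F)"], tab["s", "Pr(>F)"],
                     tab["g:s", "Pr(>F)"]),
               stringsAsFactors = FALSE)
  }
}

#' Equalized downsampling comparison across groups
#'
#' Group sizes are equalized to the reference group's size `n_target`: in
#' each iteration, `n_target` values are drawn without replacement from every
#' non-reference group (the reference group passes through unchanged) and
#' each requested pairwise comparison is tested with the rank-sum test. The
#' fraction of iterations with p below `alpha` is reported per comparison,
#' together with the full p-value distribution. Deterministic given `seed`.
#'
#' @param groups named list of numeric vectors.
#' @param comparisons list of length-2 character vectors naming group pairs.
#' @param reference name of the group that sets `n_target` and is never
#'   resampled.
#' @param n_target subsample size; defaults to the reference group's size.
#' @param n_iterations number of downsampling iterations (default 200).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return list `fraction_significant` (named per comparison), `p_values`
#'   (iterations x comparisons matrix), `n_target`, `n_iterations`.
#' @export
downsampling_analysis <- function(groups, comparisons, reference,
                                  n_target = NULL, n_iterations = 200,
                                  alpha = 0.05, seed = 1) {
  stopifnot(reference %in% names(groups), n_iterations >= 1)
  if (is.null(n_target)) n_target <- length(groups[[reference]])
  for (nm in setdiff(names(groups), reference))
    if (length(groups[[nm]]) < n_target)
      stop(sprintf("group '%s' has fewer than n_target = %d values", nm, n_target))
  labels <- vapply(comparisons, paste, character(1), collapse = " vs ")
  pmat <- matrix(NA_real_, n_iterations, length(comparisons),
                 dimnames = list(NULL, labels))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (it in seq_len(n_iterations)) {
    sub <- lapply(names(groups), function(nm) {
      v <- groups[[nm]]
      if (nm == reference) v else v[sample.int(length(v), n_target)]
    })
    names(sub) <- names(groups)
    for (k in seq_along(comparisons)) {
      pr <- comparisons[[k]]
      pmat[it, k] <- ranksum_compare(sub[[pr[1]]], sub[[pr[2]]])
    }
  }
  list(fraction_significant = colMeans(pmat < alpha),
       p_values = pmat, n_target = n_target, n_iterations = n_iterations)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Percentage of run-active cells among putative pyramidal cells
#'
#' Depends only on the summed counts, not on their partition across animals:
#' `100 * sum(active) / sum(putative)`, rounded to the nearest integer for
#' reporting (the unrounded value is also returned).
#'
#' @param putative,active per-animal counts (`NA` rows dropped pairwise).
#' @return list `percent` (rounded), `percent_raw`, `n_active`, `n_putative`;
#'   `percent` is `NA` when no putative cells were counted.
#' @export
classification_percentages <- function(putative, active) {
  ok <- !is.na(putative) & !is.na(active)
  putative <- putative[ok]; active <- active[ok]
  stopifnot(all(putative >= 0), all(active >= 0), all(active <= putative))
  np <- sum(putative); na <- sum(active)
  if (np == 0) return(list(percent = NA_real_, percent_raw = NA_real_,
                           n_active = na, n_putative = np))
  raw <- 100 * na / np
  list(percent = round(raw), percent_raw = raw, n_active = na, n_putative = np)
}
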