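#' Shapiro-Wilk normality gate
#'
#' Annotates whether a sample is compatible with normality at `alpha`. The
#' choice of downstream test per comparison is fixed by the analysis design;
#' this gate only annotates reports.
#'
#' @param values numeric vector, n >= 3 and non-constant.
#' @param alpha significance level (default 0.05).
#' @return list with `normal` (logical), `p_value`, `statistic`, `n`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop_mi("normality test needs n >= 3")
  if (stats::sd(values) == 0)
    stop_mi("degenerate input: all values identical")
  st <- stats::shapiro.test(values)
  list(normal = st$p.value > alpha, p_value = st$p.value,
       statistic = unname(st$statistic), n = length(values))
}

#' Paired Wilcoxon signed-rank test over features
#'
#' Two-sided Wilcoxon signed-rank test on per-feature pairs (case vs
#' control), the comparison used for methylated/unmethylated domains, CGI
#' classes, maternal gDMRs and the maintenance ratio. Zero differences are
#' excluded by the standard convention. The exact null distribution is used
#' below 25 informative pairs, the continuity-corrected normal approximation
#' from 25 up.
#'
#' @param case,control equal-length paired numeric vectors.
#' @return list with `statistic` (V), `p_value`, `direction` (sign of the
#'   median difference), `n_pairs`, `n_nonzero`, `degenerate` (TRUE when all
#'   differences are zero, reported as p = 1).
#' @export
paired_feature_test <- function(case, control) {
  if (length(case) != length(control))
    stop_mi("paired vectors must have equal length")
  keep <- !is.na(case) & !is.na(control)
  case <- case[keep]; control <- control[keep]
  if (length(case) < 2) stop_mi("need at least 2 pairs")
  d <- case - control
  nz <- sum(d != 0)
  if (nz == 0)
    return(list(statistic = NA_real_, p_value = 1, direction = 0,
                n_pairs = length(d), n_nonzero = 0L, degenerate = TRUE))
  wt <- suppressWarnings(
    stats::wilcox.test(case, control, paired = TRUE,
                       exact = nz < 25, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = sign(stats::median(d)), n_pairs = length(d),
       n_nonzero = nz, degenerate = FALSE)
}

#' Unpaired two-tailed t test
#'
#' Student's pooled-variance t test, the comparison used for global CpG
#' methylation and ZFP57-binding-site methylation between case and control
#' oocytes.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return list with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
unpaired_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop_mi("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop_mi("zero pooled variance; t test undefined")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

# Brown-Forsythe ANOVA for means: F* with Satterthwaite denominator df
brown_forsythe_anova <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  s2 <- vapply(groups, stats::var, numeric(1))
  grand <- sum(unlist(groups)) / N
  num <- sum(n * (m - grand)^2)
  den_terms <- (1 - n / N) * s2
  den <- sum(den_terms)
  if (den == 0) stop_mi("all groups have zero variance")
  fstar <- num / den
  c_i <- den_terms / den
  df2 <- 1 / sum(c_i^2 / (n - 1))
  list(statistic = fstar, df1 = k - 1, df2 = df2,
       p_value = stats::pf(fstar, k - 1, df2, lower.tail = FALSE))
}

#' Effect-size comparison across region classes
#'
#' Heteroscedasticity-robust omnibus tests (Welch ANOVA and Brown-Forsythe
#' ANOVA for means) over region-class value sets, followed by Dunnett-T3
#' style pairwise comparisons of every other class against the reference
#' class (the gDMRs). Pairwise p values use the Welch t statistic with
#' Satterthwaite degrees of freedom and a Sidak-type studentized-maximum-
#' modulus adjustment over the number of comparisons. A pairwise comparison
#' in which both groups have zero variance is flagged rather than fabricated.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param control name of the reference group (default the first).
#' @return list with `welch` (statistic, df, p_value), `brown_forsythe`
#'   (statistic, df1, df2, p_value) and `pairwise` (tibble: group, diff,
#'   statistic, df, p_value, p_adjusted, flagged).
#' @export
effect_size_anova <- function(groups, control = names(groups)[1]) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_mi("groups must be named")
  if (length(groups) < 2) stop_mi("need >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 3)) stop_mi("each group needs n >= 3")
  if (!control %in% names(groups))
    stop_mi("control group '%s' not found", control)
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    stop_mi("all groups have zero variance")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  ow <- stats::oneway.test(x ~ g, var.equal = FALSE)
  bf <- brown_forsythe_anova(groups)
  others <- setdiff(names(groups), control)
  m <- length(others)
  ctrl <- groups[[control]]
  pw <- lapply(others, function(nm) {
    gi <- groups[[nm]]
    v1 <- stats::var(ctrl) / length(ctrl)
    v2 <- stats::var(gi) / length(gi)
    if (v1 + v2 == 0)
      return(tibble(group = nm, diff = mean(gi) - mean(ctrl),
                    statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_, p_adjusted = NA_real_,
                    flagged = TRUE))
    tstat <- (mean(gi) - mean(ctrl)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(ctrl) - 1) + v2^2 / (length(gi) - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    tibble(group = nm, diff = mean(gi) - mean(ctrl), statistic = tstat,
           df = df, p_value = p,
           p_adjusted = 1 - (1 - p)^m, flagged = FALSE)
  })
  list(welch = list(statistic = unname(ow$statistic),
                    df = unname(ow$parameter),
                    p_value = ow$p.value),
       brown_forsythe = bf,
       pairwise = bind_rows(pw))
}
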