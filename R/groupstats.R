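# Nonparametric group inference. The per-cue participant-level metric
# distributions fail normality and homoscedasticity checks, so the main
# effect is tested with a tie-corrected Kruskal-Wallis one-way ANOVA and
# all-pairs comparisons use the Dwass-Steel-Critchlow-Fligner procedure,
# whose familywise control comes from the studentized-range distribution.

as_group_list <- function(groups, min_n = 2L, caller = "this test") {
  if (is.data.frame(groups)) stopf("pass a named list of numeric vectors")
  if (!is.list(groups) || length(groups) < 2L)
    stopf("%s needs at least 2 groups", caller)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (!is.numeric(g) || anyNA(g) || any(!is.finite(g)))
      stopf("group '%s' must be finite numeric without missing values", nm)
    if (length(g) < min_n)
      stopf("group '%s' has n = %d; %s needs n >= %d per group",
            nm, length(g), caller, min_n)
  }
  groups
}

#' Mid-ranks of a numeric vector
#'
#' Ranks with ties resolved by averaging (mid-ranks), the convention shared
#' by the Kruskal-Wallis and DSCF statistics; the rank sum is always
#' `N(N+1)/2`.
#'
#' @param x Finite numeric values.
#' @return Numeric vector of mid-ranks.
#' @examples
#' ranks_with_ties(c(1, 2, 2, 3))  # 1 2.5 2.5 4
#' @export
ranks_with_ties <- function(x) {
  if (anyNA(x) || any(!is.finite(x))) stopf("values must be finite")
  rank(x, ties.method = "average")
}

#' Kruskal-Wallis one-way analysis of variance by ranks
#'
#' Tie-corrected statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \tfrac{N+1}{2})^2 / C,
#'   \quad C = 1 - \frac{\sum (t^3 - t)}{N^3 - N}}
#' with p-value from the upper tail of the chi-square distribution on
#' `k - 1` degrees of freedom. When every pooled observation is identical
#' the tie correction degenerates (`C = 0`); by convention that returns
#' `H = 0`, `p = 1`.
#'
#' @param groups Named list of finite numeric vectors, each of length >= 2.
#' @return A `kw_result`: list with `H`, `df`, `p`, `tie_correction`, `n`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups, min_n = 2L, caller = "kruskal_wallis")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  k <- length(groups)
  r <- ranks_with_ties(x)
  t_counts <- table(x)
  C <- 1 - sum(t_counts^3 - t_counts) / (N^3 - N)
  result <- function(H, p) structure(
    list(H = H, df = k - 1L, p = p, tie_correction = C,
         n = lengths(groups)), class = "kw_result")
  if (C <= 0) return(result(0, 1))  # all observations identical
  rbar <- tapply(r, g, mean)
  H <- (12 / (N * (N + 1))) * sum(lengths(groups) * (rbar - (N + 1) / 2)^2) / C
  result(H, pchisq(H, df = k - 1L, lower.tail = FALSE))
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-square(%d) = %.4g, p = %.4g (tie correction %.4g)\n",
              x$df, x$H, x$p, x$tie_correction))
  invisible(x)
}

#' Dwass-Steel-Critchlow-Fligner all-pairs comparisons
#'
#' For each pair of groups the combined values are mid-ranked and the
#' rank sum `T` of the second group is standardized with the exact
#' (tie-corrected) permutation moments,
#' \deqn{W = \sqrt{2}\,(T - E[T]) / \sqrt{Var[T]},}
#' \deqn{Var[T] = \frac{n_i n_j}{m(m-1)}\Big(\sum r^2 - \frac{m(m+1)^2}{4}\Big),
#'   \quad m = n_i + n_j,}
#' and referred to the studentized-range distribution with `k` groups and
#' infinite degrees of freedom, which controls the familywise error over
#' all `k(k-1)/2` comparisons. Pairs whose pooled values are all tied have
#' zero variance and are reported as `W = 0`, `p = 1`, `degenerate = TRUE`.
#'
#' @param groups Named list of finite numeric vectors (>= 2 values each).
#'   Ordinarily run only after a significant Kruskal-Wallis main effect.
#' @return Tibble with one row per unordered pair: `group1`, `group2`, `W`,
#'   `p` (familywise-adjusted), `degenerate`.
#' @export
dscf_pairwise <- function(groups) {
  groups <- as_group_list(groups, min_n = 2L, caller = "dscf_pairwise")
  k <- length(groups)
  nms <- names(groups)
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    xi <- groups[[i]]; xj <- groups[[j]]
    ni <- length(xi); nj <- length(xj); m <- ni + nj
    r <- ranks_with_ties(c(xi, xj))
    Tj <- sum(r[(ni + 1L):m])
    ET <- nj * (m + 1) / 2
    VarT <- ni * nj / (m * (m - 1)) * (sum(r^2) - m * (m + 1)^2 / 4)
    if (VarT <= 0) {
      W <- 0; pval <- 1; degen <- TRUE
    } else {
      W <- sqrt(2) * (Tj - ET) / sqrt(VarT)
      pval <- ptukey(abs(W), nmeans = k, df = Inf, lower.tail = FALSE)
      degen <- FALSE
    }
    tibble::tibble(group1 = nms[i], group2 = nms[j], W = W, p = pval,
                   degenerate = degen)
  })
  do.call(rbind, rows)
}

#' Levene's test of homogeneity of variance
#'
#' Classical mean-centered Levene statistic: with
#' `z_ij = |x_ij - center_i|`,
#' \deqn{W = \frac{N - k}{k - 1} \cdot
#'   \frac{\sum_i n_i (\bar z_i - \bar z)^2}{\sum_i \sum_j (z_{ij} - \bar z_i)^2}}
#' referred to `F(k - 1, N - k)`. `center = "median"` gives the
#' Brown-Forsythe variant. If every deviation is identical the statistic
#' degenerates and `W = 0`, `p = 1` is returned with `degenerate = TRUE`.
#'
#' @param groups Named list of finite numeric vectors, each n >= 2.
#' @param center `"mean"` (classical, default) or `"median"`
#'   (Brown-Forsythe).
#' @return List with `W`, `df1`, `df2`, `p`, `center`, `degenerate`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- as_group_list(groups, min_n = 2L, caller = "levene_test")
  cfun <- if (center == "mean") mean else median
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  ni <- lengths(z)
  N <- sum(ni)
  k <- length(z)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  ssb <- sum(ni * (zbar_i - zbar)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2),
                    numeric(1)))
  if (ssw <= 0 && ssb <= 0)
    return(list(W = 0, df1 = k - 1L, df2 = N - k, p = 1, center = center,
                degenerate = TRUE))
  if (ssw <= 0)  # perfectly separated deviations: infinitely significant
    return(list(W = Inf, df1 = k - 1L, df2 = N - k, p = 0, center = center,
                degenerate = FALSE))
  W <- ((N - k) / (k - 1)) * ssb / ssw
  list(W = W, df1 = k - 1L, df2 = N - k,
       p = pf(W, k - 1L, N - k, lower.tail = FALSE),
       center = center, degenerate = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the host implementation of Royston's approximation
#' (`stats::shapiro.test`); used only to gate the parametric-vs-
#' nonparametric branch of the workflow.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L) stopf("Shapiro-Wilk needs at least 3 observations")
  if (length(x) > 5000L) stopf("Shapiro-Wilk supports at most 5000 observations")
  st <- shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Inter-participant outlier flags by the 1.5 x IQR rule
#'
#' Flags values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with
#' quartiles by linear interpolation of order statistics
#' (`quantile(type = 7)`). Values equal to a collapsed bound (IQR 0) are
#' not outside it, so constant samples flag nothing. With fewer than 4
#' values no flags are produced and a warning is raised.
#'
#' @param x Numeric values.
#' @return Logical vector, `TRUE` = outlier.
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100))  # only 100 flagged
#' @export
iqr_outliers <- function(x) {
  if (length(x) < 4L) {
    warning("fewer than 4 values; IQR outlier rule skipped", call. = FALSE)
    return(rep(FALSE, length(x)))
  }
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
}

#' Assumption checks and nonparametric main-effect workflow
#'
#' Reproduces the group-level inference chain for one metric x direction
#' stratum: (1) label and drop inter-participant outliers per cue by the
#' 1.5 x IQR rule; (2) record Levene and per-group Shapiro-Wilk assumption
#' checks; (3) run the tie-corrected Kruskal-Wallis main-effect test; (4)
#' if significant at `alpha`, run DSCF pairwise comparisons over every cue
#' pair (21 pairs for the 7-cue design).
#'
#' @param summaries A [summarize_participants()] tibble.
#' @param metric `"fa"` or `"pv"` (participant-level magnitudes).
#' @param direction `"focus"` or `"defocus"`.
#' @param alpha Significance level gating the pairwise stage.
#' @param remove_outliers Apply the IQR rule before inference.
#' @return A `group_inference` object: list with `metric`, `direction`,
#'   `groups` (values used), `n_outliers_removed`, `assumptions` (Levene +
#'   Shapiro results and `parametric_ok`), `kw` (a `kw_result`), and
#'   `pairwise` (DSCF tibble, or `NULL` with `pairwise_reason` when the
#'   main effect is not significant).
#' @export
main_effect_workflow <- function(summaries, metric = c("fa", "pv"),
                                 direction = c("focus", "defocus"),
                                 alpha = 0.05, remove_outliers = TRUE) {
  metric <- match.arg(metric)
  direction <- match.arg(direction)
  col <- if (metric == "fa") "mean_fa" else "mean_pv"
  sub <- summaries[summaries$direction == direction & !is.na(summaries[[col]]), ]
  if (!nrow(sub)) stopf("no participant summaries for %s/%s", metric, direction)
  groups <- split(sub[[col]], sub$cue)
  groups <- groups[order(match(names(groups), CUE_CODES))]
  n_out <- 0L
  if (remove_outliers) {
    groups <- lapply(groups, function(g) {
      flags <- if (length(g) >= 4L) iqr_outliers(g) else rep(FALSE, length(g))
      n_out <<- n_out + sum(flags)
      g[!flags]
    })
  }
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) < 2L) stopf("need >= 2 cue groups after outlier removal")
  lev <- levene_test(groups)
  shap <- lapply(groups, function(g) {
    if (length(g) < 3L || diff(range(g)) == 0)
      return(list(W = NA_real_, p = NA_real_))
    shapiro_wilk(g)
  })
  shap_p <- vapply(shap, `[[`, numeric(1), "p")
  parametric_ok <- lev$p >= alpha && all(shap_p >= alpha, na.rm = TRUE)
  kw <- kruskal_wallis(groups)
  if (kw$p < alpha) {
    pairwise <- dscf_pairwise(groups)
    reason <- NULL
  } else {
    pairwise <- NULL
    reason <- sprintf("main effect not significant (p = %.3g >= alpha = %g)",
                      kw$p, alpha)
  }
  structure(list(
    metric = metric, direction = direction, alpha = alpha,
    groups = groups, n_outliers_removed = n_out,
    assumptions = list(levene = lev, shapiro = shap,
                       parametric_ok = parametric_ok),
    kw = kw, pairwise = pairwise, pairwise_reason = reason
  ), class = "group_inference")
}

#' @export
print.group_inference <- function(x, ...) {
  cat(sprintf("<group_inference> %s / %s over %d cues (%d IQR outliers removed)\n",
              toupper(x$metric), x$direction, length(x$groups),
              x$n_outliers_removed))
  cat(sprintf("  Levene p = %.3g; Shapiro min p = %.3g; parametric assumptions %s\n",
              x$assumptions$levene$p,
              min(vapply(x$assumptions$shapiro, `[[`, numeric(1), "p"),
                  na.rm = TRUE),
              if (x$assumptions$parametric_ok) "met" else "violated"))
  print(x$kw)
  if (is.null(x$pairwise)) {
    cat(" ", x$pairwise_reason %||% "no pairwise comparisons", "\n")
  } else {
    sig <- sum(x$pairwise$p < x$alpha)
    cat(sprintf("  DSCF: %d/%d pairs significant at alpha = %g\n",
                sig, nrow(x$pairwise), x$alpha))
  }
  invisible(x)
}
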