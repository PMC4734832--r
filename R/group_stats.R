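#' One-way fixed-effects ANOVA from sums of squares
#'
#' Between/within decomposition computed directly: `F = MSB / MSW`, p from
#' the upper tail of the F distribution. Implemented from first principles
#' so every number in the pipeline is reproducible by hand; agreement with
#' `aov` is pinned by tests.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return An `anova_result` data frame with one row (`effect = "group"`)
#'   and columns `F`, `df_num`, `df_den`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  n_i <- vapply(groups, length, integer(1))
  if (any(n_i < 2L)) stop("each group needs at least 2 values")
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(seq_along(groups),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  df_num <- length(groups) - 1L
  df_den <- sum(n_i) - length(groups)
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f <- (ssb / df_num) / (ssw / df_den)
    p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  }
  out <- data.frame(effect = "group", F = f, df_num = df_num,
                    df_den = df_den, p = p)
  class(out) <- c("anova_result", class(out))
  out
}

#' Two-way fixed-effects ANOVA (balanced complete design)
#'
#' Factorial sums of squares for two crossed factors with equal cell sizes
#' (e.g. training session x instrumented-vs-sham group): main effects and
#' their interaction, each tested against the within-cell error.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible) of the same length.
#' @return An `anova_result` data frame with rows `A`, `B`, `A:B`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- as.factor(factor_a); b <- as.factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  tab <- table(a, b)
  if (length(unique(as.vector(tab))) != 1L || any(tab < 2L)) {
    stop("design must be balanced and complete with >= 2 replicates/cell")
  }
  n_rep <- tab[1L, 1L]
  I <- nlevels(a); J <- nlevels(b)
  grand <- mean(values)
  m_a <- tapply(values, a, mean)
  m_b <- tapply(values, b, mean)
  m_ab <- tapply(values, list(a, b), mean)
  ss_a <- J * n_rep * sum((m_a - grand)^2)
  ss_b <- I * n_rep * sum((m_b - grand)^2)
  ss_ab <- n_rep * sum((m_ab - outer(m_a, rep(1, J)) -
                        outer(rep(1, I), m_b) + grand)^2)
  cell_means <- m_ab[cbind(as.integer(a), as.integer(b))]
  ss_e <- sum((values - cell_means)^2)
  df <- c(I - 1L, J - 1L, (I - 1L) * (J - 1L))
  df_e <- I * J * (n_rep - 1L)
  ss <- c(ss_a, ss_b, ss_ab)
  ms_e <- ss_e / df_e
  f <- ifelse(rep(ms_e == 0, 3L),
              ifelse(ss == 0, 0, Inf),
              (ss / df) / ms_e)
  p <- ifelse(is.infinite(f), 0,
              ifelse(f == 0 & ms_e == 0, 1,
                     stats::pf(f, df, df_e, lower.tail = FALSE)))
  out <- data.frame(effect = c("A", "B", "A:B"), F = f,
                    df_num = df, df_den = df_e, p = p)
  class(out) <- c("anova_result", class(out))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All pairwise two-sample t tests (pooled variance) between groups, with
#' the Bonferroni adjustment `p_adj = min(m * p, 1)` over the `m` pairs.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param alpha Familywise significance level (default 0.05).
#' @return A `pairwise_result` data frame: `group1`, `group2`, `t`, `df`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups for pairwise comparisons")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    x <- groups[[i1]]; y <- groups[[i2]]
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- if (se == 0) {
      if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
    } else (mean(x) - mean(y)) / se
    df <- n1 + n2 - 2L
    p <- if (is.infinite(tstat)) 0 else
      2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    data.frame(group1 = names(groups)[i1], group2 = names(groups)[i2],
               t = tstat, df = df, p_raw = p,
               p_adj = min(m * p, 1))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  class(out) <- c("pairwise_result", class(out))
  out
}
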