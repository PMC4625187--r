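# Common result container for the statistical battery.
theta_test <- function(method, statistic, df = NULL, p = NULL, n = NULL,
                       correction = "none", extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p = p, n = n, correction = correction), extra),
            class = "theta_test")
}

#' @export
print.theta_test <- function(x, ...) {
  stat <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
                collapse = ", ")
  dfs <- if (is.null(x$df)) "" else
    paste0(", df = ", paste(signif(x$df, 5), collapse = ", "))
  cat(x$method, ": ", stat, dfs,
      if (!is.null(x$p)) sprintf(", p = %.4g", x$p),
      if (!identical(x$correction, "none")) paste0(" [", x$correction, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Friedman rank test across training days
#'
#' Friedman's chi-square (`Xr^2`) for a complete subjects x days table of
#' within-subject measurements (e.g. daily escape latencies), with
#' mid-ranked ties and the usual tie correction, `df = k - 1`.
#'
#' @param values numeric matrix, subjects in rows, days (conditions) in
#'   columns; no missing cells.
#' @return A `theta_test` with `Xr2`, `df` and `p`.
#' @export
friedman_rank_test <- function(values) {
  m <- as.matrix(values)
  if (anyNA(m)) stop("design error: missing cells in the subject x day table")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 days")
  if (all(apply(m, 1, stats::var) == 0)) {
    # no within-subject variation at all: no day effect by convention
    return(theta_test("Friedman rank test", statistic = c(Xr2 = 0),
                      df = ncol(m) - 1, p = 1, n = nrow(m)))
  }
  ft <- stats::friedman.test(m)
  theta_test("Friedman rank test",
             statistic = c(Xr2 = unname(ft$statistic)),
             df = unname(ft$parameter), p = ft$p.value, n = nrow(m))
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact distribution for small samples (n <= 25, no ties among the
#' nonzero differences), normal approximation with tie correction
#' otherwise; the method used is recorded in the result.  All paired
#' differences equal to zero is a degenerate design and raises an error.
#'
#' @param a,b paired numeric vectors of equal length (n >= 2).
#' @return A `theta_test` with `V`, `p` and the method used.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2) stop("need n >= 2 pairs")
  d <- a - b
  if (all(d == 0)) stop("degenerate: all paired differences are zero")
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz))) && all(d != 0)
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = exact, correct = TRUE))
  theta_test("Wilcoxon signed-rank (paired)",
             statistic = c(V = unname(wt$statistic)), p = wt$p.value,
             n = length(a),
             extra = list(method_detail = if (exact) "exact"
                          else "normal approximation with tie correction"))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples; exact p-value
#' for small samples without ties (both n <= 25), normal approximation
#' with tie correction otherwise.  The reported `U` counts, for each pair
#' (i, j), the arrangements in which the first sample's value is smaller,
#' so `U_a + U_b = n_a * n_b`.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return A `theta_test` with `U`, `p` and the method used.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per sample")
  exact <- length(a) <= 25 && length(b) <= 25 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  theta_test("Mann-Whitney U",
             statistic = c(U = unname(wt$statistic)), p = wt$p.value,
             n = c(length(a), length(b)),
             extra = list(method_detail = if (exact) "exact"
                          else "normal approximation with tie correction"))
}

#' Randomised-block ANOVA with Tukey HSD post-hoc
#'
#' One observation per block (subject) and treatment level (training day):
#' the day effect is tested against the block-adjusted error term, and
#' Tukey's honest significant differences compare all day pairs on that
#' same error term.
#'
#' @param values numeric matrix, blocks (subjects) in rows, days in
#'   columns; complete (no missing cells).
#' @return A `theta_test` with `F`, `df = (df1, df2)`, `p`, and a
#'   `$tukey` data frame of pairwise day comparisons.
#' @export
blocked_anova_tukey <- function(values) {
  m <- as.matrix(values)
  if (anyNA(m)) stop("design error: incomplete blocks")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 blocks and >= 2 days")
  if (is.null(colnames(m))) colnames(m) <- paste0("d", seq_len(ncol(m)))
  df <- data.frame(value = as.vector(m),
                   block = factor(rep(seq_len(nrow(m)), ncol(m))),
                   day = factor(rep(colnames(m), each = nrow(m)),
                                levels = colnames(m)))
  fit <- stats::aov(value ~ block + day, data = df)
  degenerate <- stats::var(as.vector(m)) == 0
  tab <- if (degenerate) suppressWarnings(stats::anova(fit))
         else stats::anova(fit)
  i <- which(rownames(tab) == "day")
  if (stats::var(colMeans(m)) == 0) {  # no day effect at all: F = 0 by convention
    tab$`F value`[i] <- 0
    tab$`Pr(>F)`[i] <- 1
  }
  # NB: with very small designs (error df near 0) the studentised-range
  # p-values are NaN; that is reported as-is rather than warned about
  tk <- suppressWarnings(stats::TukeyHSD(fit, "day")$day)
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  theta_test("Randomised-block ANOVA (day effect)",
             statistic = c(F = tab$`F value`[i]),
             df = c(tab$Df[i], tab$Df[nrow(tab)]),
             p = tab$`Pr(>F)`[i], n = nrow(m),
             extra = list(tukey = tukey))
}

#' Repeated-measures ANOVA (within-subject day and frequency factors)
#'
#' Univariate repeated-measures ANOVA for designs with one or two
#' within-subject factors (typically training day and 0.5-Hz frequency
#' bin) and an optional between-subject group factor.  The design must be
#' balanced: every subject must have every within-factor cell (this is
#' validated, not assumed); replicate observations within a cell (e.g.
#' four daily trials) are averaged first.  F ratios use the conventional
#' subject-by-factor error strata with uncorrected degrees of freedom;
#' Greenhouse-Geisser corrected p-values are additionally reported with
#' `gg = TRUE` for inference robust to non-sphericity.
#'
#' @param data data frame in long format.
#' @param dv name of the response column.
#' @param subject name of the subject-identifier column.
#' @param within character vector of 1 or 2 within-subject factor names.
#' @param between optional name of a between-subject factor (e.g. group).
#' @param days optional subset of day levels to retain (the column named
#'   `"day"`), e.g. `c(1, 2, 5, 6)`.
#' @param gg logical; also report Greenhouse-Geisser corrected p-values.
#' @return An object of class `rm_anova`: data frame of effects with
#'   `effect`, `df1`, `df2`, `F`, `p` (and `eps_gg`, `p_gg` when
#'   requested).
#' @export
rm_anova <- function(data, dv, subject, within, between = NULL,
                     days = NULL, gg = FALSE) {
  data <- as.data.frame(data)
  if (!is.null(days)) {
    if (!"day" %in% names(data)) stop("days subset requested but no 'day' column")
    data <- data[data$day %in% days, , drop = FALSE]
  }
  for (v in c(subject, within, between)) {
    if (!v %in% names(data)) stop("missing column: ", v)
    data[[v]] <- factor(data[[v]])
  }
  data[[dv]] <- as.numeric(data[[dv]])
  # average replicates so each subject contributes one value per cell
  cells <- data[, c(subject, within, between), drop = FALSE]
  agg <- stats::aggregate(data[[dv]], by = as.list(cells), FUN = mean)
  names(agg)[ncol(agg)] <- dv
  if (nlevels(agg[[subject]]) < 2) {
    stop("design error: need at least 2 subjects for a repeated-measures ANOVA")
  }
  # a factor observed at a single level contributes nothing: drop it, so a
  # degenerate two-factor call collapses to the one-way analysis
  within <- within[vapply(within, function(v) nlevels(agg[[v]]) > 1, NA)]
  if (!length(within)) stop("design error: no within factor with >= 2 levels")
  # validate balance: every subject x within-cell combination present
  tab <- table(agg[, c(subject, within), drop = FALSE])
  if (any(tab != 1)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    lab <- apply(miss, 1, function(i) {
      paste(mapply(function(d, j) dimnames(tab)[[d]][j],
                   seq_along(i), i), collapse = "/")
    })
    stop("design error: unbalanced design; missing cells: ",
         paste(utils::head(lab, 5), collapse = ", "),
         if (length(lab) > 5) " ...")
  }
  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "), "))")
  fml <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(fml, data = agg)
  res <- extract_aov_effects(fit)
  if (gg) {
    res$eps_gg <- NA_real_
    res$p_gg <- NA_real_
    for (i in seq_len(nrow(res))) {
      wpart <- intersect(strsplit(res$effect[i], ":")[[1]], within)
      if (!length(wpart)) next
      eps <- gg_epsilon(agg, dv, subject, wpart, within, between)
      res$eps_gg[i] <- eps
      res$p_gg[i] <- stats::pf(res$F[i], eps * res$df1[i], eps * res$df2[i],
                               lower.tail = FALSE)
    }
  }
  class(res) <- c("rm_anova", "data.frame")
  res
}

# Pull every tested effect out of a multi-stratum aov fit.
extract_aov_effects <- function(fit) {
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    resid <- which(rn == "Residuals")
    if (!length(resid)) next
    for (i in setdiff(seq_len(nrow(tab)), resid)) {
      out[[length(out) + 1L]] <- data.frame(
        effect = rn[i], df1 = tab$Df[i], df2 = tab$Df[resid],
        F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
    }
  }
  do.call(rbind, out)
}

# Greenhouse-Geisser epsilon for the within-factor combination `wpart`,
# from the subject x cell matrix (cells = interaction of wpart, averaging
# over the other within factors), with covariance pooled across any
# between groups.  eps = tr(S)^2 / (d * sum(S^2)) on the orthonormal
# contrast projection S of the cell covariance.
gg_epsilon <- function(agg, dv, subject, wpart, within, between) {
  cellf <- interaction(agg[wpart], drop = TRUE, lex.order = TRUE)
  avg <- stats::aggregate(agg[[dv]],
                          by = c(list(subject = agg[[subject]], cell = cellf),
                                 if (!is.null(between)) list(grp = agg[[between]])),
                          FUN = mean)
  Y <- stats::xtabs(x ~ subject + cell, data = avg)
  Y <- matrix(Y, nrow = nrow(Y), dimnames = dimnames(Y))
  if (!is.null(between)) {
    grp <- avg$grp[match(rownames(Y), avg$subject)]
    S <- 0; ntot <- 0
    for (g in levels(grp)) {
      Yg <- Y[grp == g, , drop = FALSE]
      if (nrow(Yg) < 2) next
      S <- S + stats::cov(Yg) * (nrow(Yg) - 1)
      ntot <- ntot + nrow(Yg) - 1
    }
    S <- S / ntot
  } else {
    S <- stats::cov(Y)
  }
  k <- ncol(Y)
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")   # orthonormal contrasts
  M <- t(C) %*% S %*% C
  d <- k - 1
  eps <- sum(diag(M))^2 / (d * sum(M^2))
  min(1, max(1 / d, eps))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' Paired t-tests with Bonferroni correction
#'
#' Runs a family of paired two-sided t-tests, reporting per comparison the
#' raw p, the Bonferroni-adjusted p (`min(1, m * p)`), and significance at
#' `alpha / m`.  Comparisons whose paired differences have zero variance
#' are flagged as degenerate rather than producing an infinite t.
#'
#' @param comparisons named list; each element a list (or two-column
#'   matrix / data frame) with paired vectors `a` and `b`.
#' @param alpha family-wise significance level (default 0.05).
#' @return An object of class `paired_t_set`: data frame with `comparison`,
#'   `t`, `df`, `p`, `p_bonferroni`, `significant`, `degenerate`; the
#'   number of tests `m` as an attribute.
#' @export
paired_t_bonferroni <- function(comparisons, alpha = 0.05) {
  m <- length(comparisons)
  if (m < 1) stop("no comparisons supplied")
  nm <- names(comparisons)
  if (is.null(nm)) nm <- paste0("cmp", seq_len(m))
  rows <- lapply(seq_len(m), function(i) {
    el <- comparisons[[i]]
    if (is.matrix(el) || is.data.frame(el)) el <- list(a = el[, 1], b = el[, 2])
    a <- as.numeric(el$a); b <- as.numeric(el$b)
    if (length(a) != length(b) || length(a) < 2) {
      stop("comparison '", nm[i], "': paired vectors of length >= 2 required")
    }
    d <- a - b
    if (stats::sd(d) == 0) {
      return(data.frame(comparison = nm[i], t = NA_real_,
                        df = length(a) - 1, p = NA_real_,
                        p_bonferroni = NA_real_, significant = NA,
                        degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(comparison = nm[i], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * m),
               significant = tt$p.value < alpha / m, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("paired_t_set", "data.frame")
  out
}
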