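# Repeated-measures inference for the humidity x time sealing design.
# Both factors are within-subject (subject = leaf); error terms are the
# factor x subject interactions.

rm_required_cols <- c("subject", "condition", "time_min")

#' Validate a repeated-measures table
#'
#' Long-format table with columns `subject`, `condition`, `time_min` and a
#' value column; every subject must contribute exactly one value per
#' condition x time cell (fully crossed design, no imputation).
#'
#' @param table data frame.
#' @param value name of the value column (default `"gamma_deg"`).
#' @return the table, invisibly, with factors coerced.
#' @export
validate_rm_table <- function(table, value = "gamma_deg") {
  if (!all(c(rm_required_cols, value) %in% names(table)))
    stopf("table needs columns %s",
          paste(c(rm_required_cols, value), collapse = ", "))
  check_finite(table[[value]], value)
  key <- interaction(table$subject, table$condition, table$time_min, drop = FALSE)
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stopf("duplicated (subject, condition, time) cells: %s",
          paste(utils::head(as.character(dup), 5), collapse = "; "))
  counts <- table(table$subject, interaction(table$condition, table$time_min))
  if (any(counts != 1)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    lab <- apply(utils::head(miss, 5), 1, function(i)
      paste(rownames(counts)[i[1]], colnames(counts)[i[2]], sep = " x "))
    stopf("design is not fully crossed; missing cells: %s",
          paste(lab, collapse = "; "))
  }
  invisible(table)
}

#' Rank-transform a repeated-measures table
#'
#' Pools all values across the entire table and replaces them by their ranks
#' (ties receive average ranks).  Ranking is invariant to any strictly
#' monotone transform of the raw values, which is what makes the subsequent
#' ANOVA rank-based.
#'
#' @inheritParams validate_rm_table
#' @return the table with the value column replaced by global ranks.
#' @export
rank_transform <- function(table, value = "gamma_deg") {
  validate_rm_table(table, value)
  table[[value]] <- rank(table[[value]], ties.method = "average")
  table
}

# table -> array (n_subjects x a x b), with dimnames
rm_table_to_array <- function(table, value) {
  s <- factor(table$subject)
  a <- factor(table$condition)
  b <- factor(table$time_min)
  arr <- array(NA_real_, dim = c(nlevels(s), nlevels(a), nlevels(b)),
               dimnames = list(levels(s), levels(a), levels(b)))
  arr[cbind(as.integer(s), as.integer(a), as.integer(b))] <- table[[value]]
  arr
}

# orthonormal contrast matrix, k x (k-1), columns orthonormal and orthogonal
# to the unit vector
orthonormal_contrasts <- function(k) {
  if (k < 2) stopf("need at least 2 levels")
  qr.Q(qr(stats::contr.helmert(k)))
}

# Mauchly's W, its chi-square approximation, and Greenhouse-Geisser epsilon
# for one within-subject effect, from the subject x response matrix D of
# orthonormal-contrast scores (n x p).
sphericity_from_scores <- function(D) {
  n <- nrow(D); p <- ncol(D)
  eps_lb <- 1 / p
  if (p == 1)
    return(list(W = 1, chi2 = NA_real_, df = 0L, p = NA_real_,
                gg_epsilon = 1, lower_bound = 1))
  S <- stats::cov(D)
  trS <- sum(diag(S))
  gg <- trS^2 / (p * sum(S^2))
  gg <- min(max(gg, eps_lb), 1)
  detS <- det(S)
  if (n - 1 < p || detS <= 0)   # singular covariance: test undefined
    return(list(W = NA_real_, chi2 = NA_real_,
                df = as.integer(p * (p + 1) / 2 - 1), p = NA_real_,
                gg_epsilon = gg, lower_bound = eps_lb))
  W <- detS / (trS / p)^p
  # Box chi-square approximation with the second-order correction term
  nd <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nd)
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * p + 2) /
    (288 * p^2 * nd^2 * rho^2)
  chi2 <- -nd * rho * log(W)
  df <- as.integer(p * (p + 1) / 2 - 1)
  pval <- stats::pchisq(chi2, df, lower.tail = FALSE) +
    w2 * (stats::pchisq(chi2, df + 4, lower.tail = FALSE) -
          stats::pchisq(chi2, df, lower.tail = FALSE))
  list(W = W, chi2 = chi2, df = df, p = pval,
       gg_epsilon = gg, lower_bound = eps_lb)
}

# full sums-of-squares partition for an n x a x b fully within design
rm_anova_core <- function(arr) {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  if (n < 3) stopf("need at least 3 subjects")
  if (a < 2 || b < 2) stopf("both within-subject factors need >= 2 levels")
  M <- mean(arr)
  ms <- apply(arr, 1, mean); ma <- apply(arr, 2, mean); mb <- apply(arr, 3, mean)
  mab <- apply(arr, c(2, 3), mean)
  msa <- apply(arr, c(1, 2), mean)
  msb <- apply(arr, c(1, 3), mean)
  ss_a <- b * n * sum((ma - M)^2)
  ss_b <- a * n * sum((mb - M)^2)
  ss_ab <- n * sum((mab - outer(ma, rep(1, b)) - outer(rep(1, a), mb) + M)^2)
  ss_as <- b * sum((msa - outer(ms, rep(1, a)) - outer(rep(1, n), ma) + M)^2)
  ss_bs <- a * sum((msb - outer(ms, rep(1, b)) - outer(rep(1, n), mb) + M)^2)
  resid <- arr
  for (s in seq_len(n)) for (i in seq_len(a)) for (j in seq_len(b))
    resid[s, i, j] <- arr[s, i, j] - msa[s, i] - msb[s, j] - mab[i, j] +
      ms[s] + ma[i] + mb[j] - M
  ss_abs <- sum(resid^2)
  df <- c(a - 1, (a - 1) * (n - 1),
          b - 1, (b - 1) * (n - 1),
          (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1))
  ss <- c(ss_a, ss_as, ss_b, ss_bs, ss_ab, ss_abs)
  msq <- ss / df
  f <- msq[c(1, 3, 5)] / msq[c(2, 4, 6)]
  list(n = n, a = a, b = b,
       effects = data.frame(
         effect = c("condition", "time", "condition:time"),
         df1 = as.integer(df[c(1, 3, 5)]), df2 = as.integer(df[c(2, 4, 6)]),
         ss_effect = ss[c(1, 3, 5)], ss_error = ss[c(2, 4, 6)],
         F = f,
         p = stats::pf(f, df[c(1, 3, 5)], df[c(2, 4, 6)], lower.tail = FALSE)))
}

# subject x cell response matrix, columns ordered condition-major to match
# kronecker(Qa, Qb)
rm_subject_matrix <- function(arr) {
  n <- dim(arr)[1]
  matrix(aperm(arr, c(1, 3, 2)), nrow = n)  # columns: b fast, a slow
}

#' Two-way repeated-measures ANOVA (both factors within subject)
#'
#' Partitions sums of squares for a fully within-subject two-factor design
#' (factors `condition` and `time_min`, subject = leaf), using the
#' factor x subject interactions as error terms.  For each effect, Mauchly's
#' test of sphericity and the Greenhouse-Geisser epsilon are computed from
#' the covariance of orthonormal-contrast scores, and both the uncorrected
#' and the epsilon-corrected p-value are reported.  For the rank-based
#' analysis of sealing experiments apply [rank_transform()] first (or use
#' `ranks = "global"`).
#'
#' @inheritParams validate_rm_table
#' @param ranks `"none"` (analyse values as given), `"global"` (pool all
#'   values, rank once, analyse ranks) or `"per-effect"` (aligned-rank
#'   transform: for each effect, strip the other estimated effects, rank the
#'   aligned values, refit, and read off that effect).
#' @return object of class `rm_anova` with components `effects` (one row per
#'   effect: F, df, p, Greenhouse-Geisser epsilon and corrected p) and
#'   `sphericity` (Mauchly's W, chi-square, df, p per effect).
#' @export
#' @examples
#' sim <- simulate_tracks(sealing_scenario(n_subjects = 5, seed = 2),
#'                        frames = "evaluation")
#' tab <- tracks_to_rm_table(sim$tracks)
#' rm_anova_two_way(tab, ranks = "global")
rm_anova_two_way <- function(table, value = "gamma_deg",
                             ranks = c("none", "global", "per-effect")) {
  ranks <- match.arg(ranks)
  validate_rm_table(table, value)
  if (ranks == "global") table <- rank_transform(table, value)
  arr <- rm_table_to_array(table, value)
  if (ranks == "per-effect") {
    fit <- rm_anova_art(arr)
  } else {
    fit <- rm_anova_core(arr)
  }
  # sphericity diagnostics always from the (possibly globally ranked) data
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  Qa <- orthonormal_contrasts(a); Qb <- orthonormal_contrasts(b)
  msa <- apply(arr, c(1, 2), mean); msb <- apply(arr, c(1, 3), mean)
  Y <- rm_subject_matrix(arr)
  sph <- list(condition = sphericity_from_scores(msa %*% Qa),
              time = sphericity_from_scores(msb %*% Qb),
              `condition:time` = sphericity_from_scores(Y %*% kronecker(Qa, Qb)))
  eff <- fit$effects
  eff$gg_epsilon <- vapply(sph, `[[`, numeric(1), "gg_epsilon")
  eff$p_gg <- stats::pf(eff$F, eff$df1 * eff$gg_epsilon,
                        eff$df2 * eff$gg_epsilon, lower.tail = FALSE)
  sphericity <- data.frame(
    effect = eff$effect,
    mauchly_W = vapply(sph, `[[`, numeric(1), "W"),
    chi2 = vapply(sph, `[[`, numeric(1), "chi2"),
    df = vapply(sph, `[[`, integer(1), "df"),
    p = vapply(sph, `[[`, numeric(1), "p"),
    row.names = NULL)
  structure(list(effects = eff, sphericity = sphericity,
                 n_subjects = n, ranks = ranks),
            class = "rm_anova")
}

# aligned-rank transform: per effect, remove the other effects' estimates,
# rank the aligned responses, run the full partition, keep that effect's row
rm_anova_art <- function(arr) {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  M <- mean(arr)
  ma <- apply(arr, 2, mean); mb <- apply(arr, 3, mean)
  mab <- apply(arr, c(2, 3), mean)
  est_a <- ma - M; est_b <- mb - M
  est_ab <- mab - outer(ma, rep(1, b)) - outer(rep(1, a), mb) + M
  cell <- function(i, j) mab[i, j]
  align_fit <- function(strip) {
    al <- arr
    for (i in seq_len(a)) for (j in seq_len(b))
      al[, i, j] <- arr[, i, j] - cell(i, j) + strip(i, j)
    al[] <- rank(al, ties.method = "average")
    rm_anova_core(al)
  }
  fa <- align_fit(function(i, j) est_a[i])
  fb <- align_fit(function(i, j) est_b[j])
  fab <- align_fit(function(i, j) est_ab[i, j])
  eff <- rbind(fa$effects[1, ], fb$effects[2, ], fab$effects[3, ])
  rownames(eff) <- NULL
  list(n = n, a = a, b = b, effects = eff)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (%s), n = %d subjects\n",
              switch(x$ranks, none = "raw values",
                     global = "globally rank-transformed data",
                     `per-effect` = "aligned-rank transform"),
              x$n_subjects))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-15s F(%d,%d) = %.2f, p = %.3g (GG eps = %.3f, p_GG = %.3g)\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i],
                e$gg_epsilon[i], e$p_gg[i]))
  s <- x$sphericity
  cat("Mauchly sphericity:\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-15s W = %.4g, p = %.3g\n", s$effect[i], s$mauchly_W[i],
                s$p[i]))
  invisible(x)
}

#' Bonferroni-adjusted pairwise paired t-tests on a within-subject factor
#'
#' Compares all level pairs of one factor using paired Student t-tests on
#' subject-wise values averaged over the other factor.  For the rank-based
#' analysis pass a rank-transformed table.  Adjusted p-values are
#' `min(1, m * p)` with `m = k (k - 1) / 2` comparisons.
#'
#' @inheritParams validate_rm_table
#' @param factor `"condition"` or `"time_min"`.
#' @return data frame: `level_a`, `level_b`, `t`, `df`, `p`, `p_bonferroni`.
#' @export
pairwise_bonferroni <- function(table, factor = c("condition", "time_min"),
                                value = "gamma_deg") {
  factor <- match.arg(factor)
  validate_rm_table(table, value)
  other <- setdiff(c("condition", "time_min"), factor)
  agg <- stats::aggregate(table[[value]],
                          by = list(subject = table$subject,
                                    level = table[[factor]]), FUN = mean)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "level",
                         direction = "wide")
  lev <- sub("^x\\.", "", names(wide)[-1])
  if (length(lev) < 2) stopf("factor '%s' needs >= 2 levels", factor)
  if (nrow(wide) < 2) stopf("need >= 2 subjects for paired t-tests")
  pairs <- utils::combn(seq_along(lev), 2)
  m <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- wide[[i + 1]] - wide[[j + 1]]
    if (stats::sd(d) == 0) {
      # degenerate: constant paired differences
      tt <- if (d[1] == 0) list(statistic = 0, parameter = length(d) - 1,
                                p.value = 1)
            else list(statistic = sign(d[1]) * Inf,
                      parameter = length(d) - 1, p.value = 0)
    } else {
      tt <- stats::t.test(wide[[i + 1]], wide[[j + 1]], paired = TRUE)
    }
    data.frame(level_a = lev[i], level_b = lev[j],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_bonferroni = min(1, m * tt$p.value))
  }))
  attr(out, "n_comparisons") <- m
  attr(out, "averaged_over") <- other
  out
}
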