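# Orthonormal between-level contrasts for a k-level within factor,
# returned as a (k-1) x k matrix with orthonormal rows.
#' @keywords internal
orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  t(apply(C, 2, function(v) v / sqrt(sum(v^2))))
}

# Greenhouse-Geisser epsilon for one within-subject effect family, from the
# pooled within-group covariance of the orthonormalized per-subject scores.
#' @keywords internal
gg_epsilon <- function(scores, group) {
  k <- ncol(scores)
  if (k == 1) return(1)
  centered <- scores
  for (g in unique(group)) {
    rows <- group == g
    centered[rows, ] <- sweep(scores[rows, , drop = FALSE], 2,
                              colMeans(scores[rows, , drop = FALSE]))
  }
  sigma <- crossprod(centered) / (nrow(scores) - length(unique(group)))
  tr <- sum(diag(sigma))
  eps <- tr^2 / (k * sum(sigma^2))
  min(1, max(eps, 1 / k))
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' Partitioned sums of squares for a design with one between-subjects
#' factor and one or two within-subjects factors, one observation per
#' participant x within-cell. Within-subject effects are tested against
#' their own participant-interaction error strata. For every within family
#' with three or more levels the Greenhouse-Geisser epsilon is estimated
#' from the double-centered covariance of the per-subject contrast scores
#' and the reported p value uses the epsilon-corrected (fractional) degrees
#' of freedom; two-level families have epsilon exactly 1. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)` with the effect's own
#' error stratum.
#'
#' @param data long-format data.frame.
#' @param dv name of the response column.
#' @param id name of the participant column.
#' @param between name of the between-subjects factor (or `NULL`).
#' @param within character vector of one or two within-subjects factor
#'   names.
#' @return object of class `anova_result` whose `table` holds, per effect:
#'   `effect`, `ss`, `ss_error`, `df`, `df_error`, `F`, `epsilon`,
#'   `df_gg`, `df_error_gg`, `p_uncorrected`, `p` (GG-corrected where the
#'   family has >= 3 levels), `pes`.
#' @export
mixed_rmanova <- function(data, dv, id, between = NULL, within) {
  stopifnot(length(within) %in% 1:2)
  for (v in c(dv, id, between, within)) {
    if (!v %in% names(data)) stop("column '", v, "' not found")
  }
  if (any(!is.finite(data[[dv]]))) stop("missing or non-finite responses")

  a_lev <- sort(unique(as.character(data[[within[1]]])))
  b_lev <- if (length(within) == 2) {
    sort(unique(as.character(data[[within[2]]])))
  } else "."
  a <- length(a_lev); b <- length(b_lev)
  cells <- paste(rep(a_lev, each = b), rep(b_lev, a), sep = "\r")
  cell_of <- paste(as.character(data[[within[1]]]),
                   if (b > 1) as.character(data[[within[2]]]) else ".",
                   sep = "\r")
  ids <- as.character(data[[id]])
  subj <- sort(unique(ids))
  N <- length(subj)

  # balance check: exactly one observation per participant x cell
  tab <- table(factor(ids, subj), factor(cell_of, cells))
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("unbalanced data: participant ", subj[bad[1, 1]], " has ",
         tab[bad[1, , drop = FALSE]], " observations in cell '",
         gsub("\r", ":", cells[bad[1, 2]]), "'")
  }
  Y <- matrix(NA_real_, N, a * b, dimnames = list(subj, cells))
  Y[cbind(match(ids, subj), match(cell_of, cells))] <- data[[dv]]

  if (is.null(between)) {
    group <- rep("all", N)
  } else {
    gmap <- unique(data.frame(i = ids, g = as.character(data[[between]])))
    if (nrow(gmap) != N) stop("participants must belong to a single group")
    group <- gmap$g[match(subj, gmap$i)]
  }
  groups <- sort(unique(group))
  n_g <- as.vector(table(factor(group, groups)))
  if (!is.null(between) && any(n_g < 2)) {
    stop("need at least two participants per group")
  }

  A_of_cell <- rep(seq_len(a), each = b)
  B_of_cell <- rep(seq_len(b), a)
  m <- mean(Y)
  m_s <- rowMeans(Y)
  m_g <- tapply(m_s, factor(group, groups), mean)
  W <- a * b

  # subject-level (between) stratum
  ss_group <- W * sum(n_g * (m_g - m)^2)
  ss_subj <- W * sum((m_s - m_g[group])^2)
  df_group <- length(groups) - 1
  df_subj <- N - length(groups)

  # per-subject marginal means over each within factor
  m_sa <- t(apply(Y, 1, function(y) tapply(y, A_of_cell, mean)))
  m_sb <- t(apply(Y, 1, function(y) tapply(y, B_of_cell, mean)))
  if (a == 1) m_sa <- matrix(rowMeans(Y), N, 1)
  if (b == 1) m_sb <- matrix(rowMeans(Y), N, 1)

  within_family <- function(m_sx, x, n_rep) {
    # n_rep = number of observations behind each (subject, level) mean
    m_x <- colMeans(m_sx)
    m_gx <- apply(m_sx, 2, function(col) tapply(col, factor(group, groups), mean))
    m_gx <- matrix(m_gx, nrow = length(groups))
    ss_x <- n_rep * sum(N * (m_x - m)^2)
    ss_xg <- n_rep * sum(n_g * sweep(sweep(m_gx, 1, m_g), 2, m_x - m)^2)
    dev <- m_sx
    for (i in seq_len(N)) {
      gi <- match(group[i], groups)
      dev[i, ] <- m_sx[i, ] - m_s[i] - m_gx[gi, ] + m_g[gi]
    }
    ss_err <- n_rep * sum(dev^2)
    list(ss_x = ss_x, ss_xg = ss_xg, ss_err = ss_err,
         df_x = x - 1, df_xg = (x - 1) * (length(groups) - 1),
         df_err = (x - 1) * df_subj)
  }

  famA <- within_family(m_sa, a, b)
  epsA <- if (a > 1) {
    gg_epsilon(m_sa %*% t(orth_contrasts(a)), group)
  } else 1

  rows <- list()
  add_row <- function(effect, ss, df, ss_err, df_err, eps) {
    F <- (ss / df) / (ss_err / df_err)
    p_unc <- stats::pf(F, df, df_err, lower.tail = FALSE)
    p_gg <- stats::pf(F, df * eps, df_err * eps, lower.tail = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(
      effect = effect, ss = ss, ss_error = ss_err, df = df,
      df_error = df_err, F = F, epsilon = eps,
      df_gg = df * eps, df_error_gg = df_err * eps,
      p_uncorrected = p_unc, p = p_gg,
      pes = ss / (ss + ss_err), stringsAsFactors = FALSE
    )
  }

  if (!is.null(between)) {
    add_row(between, ss_group, df_group, ss_subj, df_subj, 1)
  }
  nameA <- within[1]
  add_row(nameA, famA$ss_x, famA$df_x, famA$ss_err, famA$df_err, epsA)
  if (!is.null(between)) {
    add_row(paste(between, nameA, sep = ":"), famA$ss_xg, famA$df_xg,
            famA$ss_err, famA$df_err, epsA)
  }

  if (b > 1) {
    nameB <- within[2]
    famB <- within_family(m_sb, b, a)
    epsB <- gg_epsilon(m_sb %*% t(orth_contrasts(b)), group)
    add_row(nameB, famB$ss_x, famB$df_x, famB$ss_err, famB$df_err, epsB)
    if (!is.null(between)) {
      add_row(paste(between, nameB, sep = ":"), famB$ss_xg, famB$df_xg,
              famB$ss_err, famB$df_err, epsB)
    }

    # A x B family
    m_ab <- colMeans(Y)
    m_a <- colMeans(m_sa); m_b <- colMeans(m_sb)
    m_gab <- apply(Y, 2, function(col) tapply(col, factor(group, groups), mean))
    m_gab <- matrix(m_gab, nrow = length(groups))
    m_ga <- apply(m_sa, 2, function(col) tapply(col, factor(group, groups), mean))
    m_ga <- matrix(m_ga, nrow = length(groups))
    m_gb <- apply(m_sb, 2, function(col) tapply(col, factor(group, groups), mean))
    m_gb <- matrix(m_gb, nrow = length(groups))

    dev_ab <- m_ab - m_a[A_of_cell] - m_b[B_of_cell] + m
    ss_ab <- N * sum(dev_ab^2)
    dev_abg <- m_gab
    for (gi in seq_along(groups)) {
      dev_abg[gi, ] <- m_gab[gi, ] - m_ga[gi, A_of_cell] - m_gb[gi, B_of_cell] -
        m_ab + m_a[A_of_cell] + m_b[B_of_cell] + m_g[gi] - m
    }
    ss_abg <- sum(as.numeric(n_g) * rowSums(dev_abg^2))
    ss_all <- ss_group + ss_subj + famA$ss_x + famA$ss_xg + famA$ss_err +
      famB$ss_x + famB$ss_xg + famB$ss_err + ss_ab + ss_abg
    ss_total <- sum((Y - m)^2)
    ss_err_ab <- ss_total - ss_all
    df_ab <- (a - 1) * (b - 1)
    df_abg <- df_ab * (length(groups) - 1)
    df_err_ab <- df_ab * df_subj
    epsAB <- gg_epsilon(Y %*% t(kronecker(orth_contrasts(a), orth_contrasts(b))),
                        group)
    add_row(paste(nameA, nameB, sep = ":"), ss_ab, df_ab, ss_err_ab,
            df_err_ab, epsAB)
    if (!is.null(between)) {
      add_row(paste(between, nameA, nameB, sep = ":"), ss_abg, df_abg,
              ss_err_ab, df_err_ab, epsAB)
    }
  }

  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(
    list(table = table, n_per_group = stats::setNames(as.list(n_g), groups),
         design = list(between = between, within = within, dv = dv)),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-28s F(%.2f, %.2f) = %.2f, p = %.4g, pes = %.3f\n",
                t$effect[i], t$df_gg[i], t$df_error_gg[i], t$F[i], t$p[i],
                t$pes[i]))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' Pairwise t contrasts between the levels of one factor: paired t-tests on
#' per-participant level means for a within factor, pooled-variance
#' independent t-tests for a between factor. p values are
#' Bonferroni-adjusted over the family of comparisons made here.
#'
#' @param data long-format data.frame.
#' @param dv,id response and participant columns.
#' @param factor_name factor whose levels are compared.
#' @param paired `TRUE` for a within factor.
#' @return data.frame `level1`, `level2`, `mean_diff`, `t`, `df`, `p_raw`,
#'   `p_adj`.
#' @export
posthoc_pairwise <- function(data, dv, id, factor_name, paired = TRUE) {
  levs <- sort(unique(as.character(data[[factor_name]])))
  agg <- stats::aggregate(data[[dv]],
                          by = list(id = data[[id]],
                                    lev = as.character(data[[factor_name]])),
                          FUN = mean)
  out <- list()
  for (i in seq_along(levs)) {
    for (j in seq_along(levs)) {
      if (j <= i) next
      x <- agg$x[agg$lev == levs[i]]
      y <- agg$x[agg$lev == levs[j]]
      if (paired) {
        xi <- agg$id[agg$lev == levs[i]]
        yi <- agg$id[agg$lev == levs[j]]
        y <- y[match(xi, yi)]
        d <- x - y
        t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
        df <- length(d) - 1
        diff <- mean(d)
      } else {
        res <- ttest_ind(x, y)
        t <- res$t; df <- res$df; diff <- res$mean_diff
      }
      out[[length(out) + 1]] <- data.frame(
        level1 = levs[i], level2 = levs[j], mean_diff = diff, t = t, df = df,
        p_raw = 2 * stats::pt(-abs(t), df), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- bonferroni(res$p_raw, nrow(res))
  res
}
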