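#' Per-column cohort summary
#'
#' The descriptive summary of a cohort metric table: per numeric column the
#' number of non-missing cases, mean, sample standard deviation (n - 1),
#' minimum and maximum.  Missing values are dropped per column, so N varies
#' across metrics exactly as in heterogeneous biopsy panels.
#'
#' @param table cohort `data.frame`; non-numeric columns (e.g. `case_id`)
#'   are skipped.
#' @return `data.frame` with columns `Measurement`, `N`, `Mean`, `Std Dev`,
#'   `Minimum`, `Maximum`; all-missing columns yield an all-`NA` row.
#' @export
summarize_cohort <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  cols <- names(table)[num]
  rows <- lapply(cols, function(cn) {
    v <- table[[cn]][!is.na(table[[cn]])]
    if (!length(v))
      return(data.frame(Measurement = cn, N = 0L, Mean = NA_real_,
                        `Std Dev` = NA_real_, Minimum = NA_real_,
                        Maximum = NA_real_, check.names = FALSE))
    data.frame(Measurement = cn, N = length(v), Mean = mean(v),
               `Std Dev` = if (length(v) > 1) stats::sd(v) else NA_real_,
               Minimum = min(v), Maximum = max(v), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise-complete Pearson correlation report
#'
#' Pairwise Pearson correlations over all numeric metric columns with
#' two-sided t-test P values, per-pair complete-case counts, and
#' interpretation bands.  Pairwise-complete deletion is used because
#' per-metric N varies widely in biopsy panels and listwise deletion would
#' discard most cases.  Pairs with fewer complete observations than
#' `min_pairs` (or with a constant member) are reported as `NA` and flagged.
#' No multiple-testing correction is applied by default, matching raw-P
#' reporting conventions; set `p_adjust = "BH"` for Benjamini-Hochberg
#' adjusted values in the long-format output.
#'
#' @param table cohort `data.frame`.
#' @param min_pairs minimum pairwise-complete observations (>= 3).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return Object of class `correlation_report`: matrices `r`, `p`, `n`,
#'   `band`, plus `variables` and `p_adjust`.
#' @export
pearson_matrix <- function(table, min_pairs = 3, p_adjust = "none") {
  num <- vapply(table, is.numeric, logical(1))
  x <- as.matrix(table[num])
  vars <- colnames(x)
  k <- length(vars)
  if (k < 2) stop("need at least two numeric columns")
  if (min_pairs < 3) stop("'min_pairs' must be >= 3")
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  n <- matrix(0L, k, k, dimnames = list(vars, vars))
  dropped <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      nij <- sum(ok)
      n[i, j] <- n[j, i] <- nij
      if (i == j) { r[i, i] <- 1; p[i, i] <- 0; next }
      if (nij < min_pairs) next
      xi <- x[ok, i]; xj <- x[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        dropped <- c(dropped, sprintf("%s~%s", vars[i], vars[j]))
        next
      }
      rij <- stats::cor(xi, xj)
      r[i, j] <- r[j, i] <- rij
      tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.xmin))
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = nij - 2)
    }
  }
  if (length(dropped))
    warning("undefined correlation for constant column pair(s): ",
            paste(dropped, collapse = ", "))
  if (p_adjust != "none") {
    off <- upper.tri(p)
    p[off] <- stats::p.adjust(p[off], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  band <- matrix(NA_character_, k, k, dimnames = list(vars, vars))
  band[!is.na(r)] <- interpret_r(r[!is.na(r)])
  structure(list(r = r, p = p, n = n, band = band, variables = vars,
                 p_adjust = p_adjust),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat(sprintf("correlation_report: %d variables, pairwise-complete Pearson r\n",
              length(x$variables)))
  print(round(x$r, digits))
  invisible(x)
}

#' Interpretation band of a correlation coefficient
#'
#' Maps `|r|` to the conventional verbal bands: 0.90-1.0 "very high",
#' 0.70-0.90 "high", 0.50-0.70 "moderate", 0.30-0.50 "low", 0.00-0.30
#' "negligible".  The published band endpoints overlap, so a tie rule is
#' required: boundaries belong to the upper band (0.70 is "high").  The sign
#' of `r` is not part of the band; retrieve it separately.
#'
#' @param r correlation(s), `|r| <= 1`.
#' @return Character vector of band labels.
#' @export
interpret_r <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1")
  bands <- c("negligible", "low", "moderate", "high", "very high")
  out <- bands[findInterval(abs(r), c(0.3, 0.5, 0.7, 0.9)) + 1L]
  out[is.na(r)] <- NA_character_
  out
}

#' Order variables by hierarchical clustering of their correlations
#'
#' Agglomerative clustering (average linkage) on the dissimilarity
#' `d = 1 - r`, so strongly positively correlated measures cluster together
#' while anti-correlated ones land far apart (using `1 - |r|` instead would
#' merge them).  Undefined correlations are imputed to `r = 0` with a
#' warning before clustering.  The leaf ordering is what the clustered
#' correlation colour map is rendered with.
#'
#' @param report a [correlation_report][pearson_matrix].
#' @return List: `order` (integer leaf order), `labels` (variables in that
#'   order), `tree` (an [stats::hclust] object).
#' @export
cluster_variables <- function(report) {
  stopifnot(inherits(report, "correlation_report"))
  r <- report$r
  if (ncol(r) < 2) stop("need at least two variables to cluster")
  if (any(is.na(r))) {
    warning("undefined correlations imputed to r = 0 for clustering")
    r[is.na(r)] <- 0
  }
  d <- stats::as.dist(1 - r)
  tree <- stats::hclust(d, method = "average")
  list(order = tree$order, labels = report$variables[tree$order], tree = tree)
}

#' Rank cortex/medulla correlations of paired measures
#'
#' For each measure with a cortical and a medullary column, reports the
#' correlation between the two compartments, ranked by descending r and
#' grouped by strength ("Highly correlated" for the high / very-high bands,
#' "Moderately correlated" for the moderate band, "Weakly correlated"
#' below).
#'
#' @param report a [correlation_report][pearson_matrix].
#' @param pairs `data.frame` with columns `measure`, `var1`, `var2` naming
#'   the paired columns (e.g. `Ctx-Tri` / `Med-Tri`).
#' @return `data.frame` with `measure`, `r`, `p`, `n`, `band`, `group`,
#'   sorted by descending `r`.  Pairs whose members are missing from the
#'   report, or whose r is undefined, are skipped with a warning.
#' @export
rank_compartment_correlations <- function(report, pairs) {
  stopifnot(inherits(report, "correlation_report"),
            all(c("measure", "var1", "var2") %in% names(pairs)))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
    if (!v1 %in% report$variables || !v2 %in% report$variables) {
      warning(sprintf("pair '%s': column %s not in report; skipped",
                      pairs$measure[i],
                      if (v1 %in% report$variables) v2 else v1))
      next
    }
    rij <- report$r[v1, v2]
    if (is.na(rij)) {
      warning(sprintf("pair '%s': correlation undefined; skipped",
                      pairs$measure[i]))
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(measure = pairs$measure[i], r = rij,
                 p = report$p[v1, v2], n = report$n[v1, v2],
                 band = interpret_r(rij), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no rankable pairs")
  out <- do.call(rbind, rows)
  out <- out[order(-out$r), , drop = FALSE]
  out$group <- ifelse(out$band %in% c("high", "very high"), "Highly correlated",
               ifelse(out$band == "moderate", "Moderately correlated",
                      "Weakly correlated"))
  rownames(out) <- NULL
  out
}

#' Long-format view of a correlation report
#'
#' @param report a `correlation_report`.
#' @return `data.frame` with `var1`, `var2`, `n`, `r`, `p`, `band`, one row
#'   per unordered variable pair.
#' @export
correlation_long <- function(report) {
  stopifnot(inherits(report, "correlation_report"))
  k <- length(report$variables)
  ij <- which(upper.tri(report$r), arr.ind = TRUE)
  data.frame(var1 = report$variables[ij[, 1]],
             var2 = report$variables[ij[, 2]],
             n = report$n[ij], r = report$r[ij], p = report$p[ij],
             band = report$band[ij], stringsAsFactors = FALSE)
}

#' Clustered correlation colour map
#'
#' Renders the correlation matrix as a colour map with variables in
#' cluster order (blue = -1, white = 0, red = +1).
#'
#' @param x a `correlation_report`.
#' @param ... ignored.
#' @return Invisibly, the cluster ordering used.
#' @export
plot.correlation_report <- function(x, ...) {
  cl <- cluster_variables(x)
  r <- x$r
  r[is.na(r)] <- 0
  ro <- r[cl$order, cl$order]
  k <- ncol(ro)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(101)
  op <- graphics::par(mar = c(7, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(k), seq_len(k), t(ro[k:1, , drop = FALSE]),
                  col = pal, zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  main = "Clustered correlation map")
  graphics::axis(1, seq_len(k), cl$labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(cl$labels), las = 2, cex.axis = 0.7)
  invisible(cl)
}
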