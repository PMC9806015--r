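#' Pairwise Spearman rank correlation matrix
#'
#' Spearman's rho between every pair of columns, computed on pairwise-
#' complete observations with average ranks for ties. Pairs with fewer than
#' `min_n` complete observations, or with a constant variable, are reported
#' as `NA`.
#'
#' @param features A numeric data.frame or matrix (columns = variables).
#' @param min_n Minimum pairwise-complete observations (default 3).
#' @return An object of class `correlation_matrix`: list with symmetric
#'   matrices `rho`, `p` and `n` (observations used per pair).
#' @export
spearman_matrix <- function(features, min_n = 3) {
  x <- as.matrix(features)
  p <- ncol(x)
  vars <- colnames(x) %||% paste0("V", seq_len(p))
  rho <- pmat <- nmat <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p)) {
    for (j in i:p) {
      ok <- complete.cases(x[, i], x[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < min_n) next
      xi <- x[ok, i]; xj <- x[ok, j]
      if (i == j) {
        if (var(xi) > 0) {
          rho[i, j] <- 1
          pmat[i, j] <- 0
        }
        next
      }
      if (var(xi) == 0 || var(xj) == 0) next
      ct <- suppressWarnings(cor.test(xi, xj, method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pmat, n = nmat),
            class = "correlation_matrix")
}

#' Long-format view of a correlation matrix
#'
#' @param cm A `correlation_matrix`.
#' @return A data.frame `var1`, `var2`, `rho`, `p`, `n` over the upper
#'   triangle.
#' @export
correlation_pairs <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  vars <- rownames(cm$rho)
  idx <- which(upper.tri(cm$rho), arr.ind = TRUE)
  data.frame(var1 = vars[idx[, 1L]], var2 = vars[idx[, 2L]],
             rho = cm$rho[idx], p = cm$p[idx], n = cm$n[idx],
             stringsAsFactors = FALSE)
}

#' Compare a continuous variable between groups
#'
#' With two groups the default is the Wilcoxon rank-sum test (`test = "t"`
#' selects Welch's t-test); with more than two groups the Kruskal-Wallis H
#' test is used. p-values are two-sided.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each non-empty).
#' @param test `"auto"` (default), `"wilcox"`, `"t"` or `"kruskal"`.
#' @return List with `statistic`, `p.value`, `method`.
#' @export
compare_groups <- function(values, groups,
                           test = c("auto", "wilcox", "t", "kruskal")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("at least two groups required")
  if (any(tab == 0L)) stop("every group must contain observations")
  k <- length(tab)
  if (test == "auto") test <- if (k == 2L) "wilcox" else "kruskal"
  if (k > 2L && test != "kruskal") {
    stop("more than two groups require the Kruskal-Wallis test")
  }
  res <- switch(test,
    wilcox = suppressWarnings(
      wilcox.test(values ~ groups, exact = FALSE)),
    t = t.test(values ~ groups),
    kruskal = kruskal.test(values, groups)
  )
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = res$method)
}

#' Association test for a two-way contingency table
#'
#' Pearson's chi-square test without continuity correction by default; for a
#' 2x2 table with any expected cell count below 5, Fisher's exact test is
#' used instead.
#'
#' @param tab A matrix of non-negative counts.
#' @param force_chisq Skip the Fisher fallback.
#' @return List with `statistic` (`NA` for Fisher), `p.value`, `method`.
#' @export
chi_square_test <- function(tab, force_chisq = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (!force_chisq && all(dim(tab) == c(2L, 2L)) && any(expected < 5)) {
    res <- fisher.test(tab)
    return(list(statistic = NA_real_, p.value = res$p.value,
                method = res$method))
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = res$method)
}
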