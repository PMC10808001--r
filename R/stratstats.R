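#' Localization-stratified nonparametric statistics
#'
#' Group comparisons of element properties across predicted subcellular
#' localizations: Kruskal-Wallis omnibus tests, pairwise Wilcoxon rank-sum
#' tests with common-language effect sizes and median differences, Holm
#' adjustment across the pairwise family, and summary-statistic t tests.
#'
#' @name stratstats
NULL

.check_groups <- function(groups, min_groups = 2L) {
  if (!is.list(groups) || length(groups) < min_groups)
    stop("need at least ", min_groups, " groups")
  if (any(!vapply(groups, length, 1L)))
    stop("every group must be non-empty")
  if (any(!vapply(groups, function(g) all(is.finite(g)), TRUE)))
    stop("non-finite values in groups")
  invisible(groups)
}

#' Kruskal-Wallis rank-sum test over named groups
#'
#' H uses midranks with the standard tie correction; p comes from the
#' chi-square approximation (df = k-1), or from exact enumeration of all
#' distinct group assignments when total N <= `n_exact`. All-identical
#' values return H = 0, p = 1 by convention.
#'
#' @param groups named list of numeric vectors.
#' @param n_exact total-N threshold below which the exact permutation p is
#'   also computed (default 10).
#' @return list with `statistic`, `df`, `p_value`, and `p_exact` (NA unless
#'   computed).
#' @export
kruskal_wallis <- function(groups, n_exact = 10L) {
  .check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(x) < 3L) stop("need total N >= 3")
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                p_exact = NA_real_))
  kt <- stats::kruskal.test(x, g)
  p_exact <- NA_real_
  if (length(x) <= n_exact) {
    h_obs <- unname(kt$statistic)
    hs <- .kw_enumerate(x, lengths(groups))
    p_exact <- mean(hs >= h_obs - 1e-12)
  }
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, p_exact = p_exact)
}

# H statistic for a given assignment of pooled ranks to groups
.kw_stat <- function(ranks_by_group, tie_corr, n) {
  hsum <- sum(vapply(ranks_by_group, function(r) sum(r)^2 / length(r), 1))
  h <- 12 / (n * (n + 1)) * hsum - 3 * (n + 1)
  h / tie_corr
}

# enumerate all distinct assignments of observations to group sizes
.kw_enumerate <- function(x, sizes) {
  n <- length(x)
  rk <- rank(x)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  # breadth-first enumeration over index subsets
  assignments <- list(list(avail = seq_len(n), groups = list()))
  for (si in seq_along(sizes)) {
    nxt <- list()
    last <- si == length(sizes)
    for (a in assignments) {
      if (last) {
        nxt[[length(nxt) + 1L]] <- list(avail = integer(0),
                                        groups = c(a$groups, list(a$avail)))
      } else {
        cmb <- utils::combn(a$avail, sizes[si], simplify = FALSE)
        for (cc in cmb)
          nxt[[length(nxt) + 1L]] <- list(avail = setdiff(a$avail, cc),
                                          groups = c(a$groups, list(cc)))
      }
    }
    assignments <- nxt
  }
  vapply(assignments, function(a) {
    .kw_stat(lapply(a$groups, function(ix) rk[ix]), tie_corr, n)
  }, 1)
}

#' Monte Carlo permutation p-value for the Kruskal-Wallis statistic
#'
#' Reference distribution built by relabelling observations; used to check
#' the chi-square approximation at sample sizes where full enumeration is
#' infeasible.
#'
#' @param groups named list of numeric vectors.
#' @param B number of permutations.
#' @return permutation p-value (with the +1 continuity convention).
#' @export
kw_permutation_p <- function(groups, B = 10000L) {
  .check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  h_obs <- unname(stats::kruskal.test(x, g)$statistic)
  hs <- vapply(seq_len(B), function(b) {
    unname(stats::kruskal.test(x, sample(g))$statistic)
  }, 1)
  (1 + sum(hs >= h_obs - 1e-12)) / (B + 1)
}

#' Common-language effect size
#'
#' Probability that a random observation from `x` exceeds one from `y`,
#' ties counted half: CLES = (#(x>y) + 0.5 #(x=y)) / (nx*ny).
#'
#' @param x,y numeric vectors.
#' @return value in [0,1].
#' @export
cles <- function(x, y) {
  cmp <- outer(x, y, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(x) * length(y))
}

#' Pairwise Wilcoxon rank-sum tests with effect sizes
#'
#' For every unordered pair of groups: two-sided rank-sum p (exact when
#' both n <= `n_exact` and no ties; otherwise normal approximation with
#' tie/continuity correction), common-language effect size, difference of
#' medians, and Holm-adjusted p across all pairs in the family.
#'
#' @param groups named list of numeric vectors.
#' @param n_exact per-group size threshold for the exact test (default 10).
#' @return data.frame, one row per pair: `group1`, `group2`, `statistic`,
#'   `p_value`, `adjusted_p`, `effect_size`, `median_diff`.
#' @export
pairwise_rank_sum <- function(groups, n_exact = 10L) {
  .check_groups(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    x <- groups[[i]]; y <- groups[[j]]
    exact <- length(x) <= n_exact && length(y) <= n_exact &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    data.frame(group1 = nm[i], group2 = nm[j],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               effect_size = cles(x, y),
               median_diff = stats::median(x) - stats::median(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "holm")
  out[, c("group1", "group2", "statistic", "p_value", "adjusted_p",
          "effect_size", "median_diff")]
}

#' Unpaired two-sample t test from raw vectors or summary statistics
#'
#' @param mean1,mean2 group means, or raw numeric vectors (then sd/n are
#'   ignored and computed from the data).
#' @param sd1,sd2 group standard deviations.
#' @param n1,n2 group sizes (>= 2).
#' @param welch use the Welch-Satterthwaite df (default) or the pooled-df
#'   Student test.
#' @return list with `t`, `df`, `p_value` (two-tailed), `mean_diff`.
#' @export
unpaired_t <- function(mean1, sd1 = NULL, n1 = NULL,
                       mean2 = NULL, sd2 = NULL, n2 = NULL, welch = TRUE) {
  if (length(mean1) > 1L) {
    x <- mean1; y <- if (length(sd1) > 1L) sd1 else mean2
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  d <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0 && d == 0)
    return(list(t = 0, df = n1 + n2 - 2, p_value = 1, mean_diff = 0))
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tval <- d / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tval <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tval, df = df, p_value = 2 * stats::pt(-abs(tval), df),
       mean_diff = d)
}

#' Compare element properties across localization groups
#'
#' The stratified analysis behind localization-resolved element statistics:
#' per property, a Kruskal-Wallis omnibus test over groups plus all
#' pairwise rank-sum results (Holm-adjusted within the property), and group
#' medians/IQRs.
#'
#' @param elements data.frame of annotated elements carrying a `label`
#'   column plus the property columns.
#' @param properties character vector of property column names (e.g.
#'   `c("basic_fraction", "H", "muH")`).
#' @return list keyed by property; each entry has `omnibus` (from
#'   [kruskal_wallis()]), `pairwise` (from [pairwise_rank_sum()]), and
#'   `summary` (per-group n, median, IQR).
#' @export
compare_by_localization <- function(elements,
                                    properties = c("basic_fraction", "H", "muH")) {
  if (!"label" %in% names(elements)) stop("elements need a 'label' column")
  labs <- unique(elements$label)
  if (length(labs) < 2L) stop("need at least 2 localization groups")
  out <- list()
  for (p in properties) {
    if (!p %in% names(elements)) stop("missing property column: ", p)
    groups <- split(elements[[p]], elements$label)
    out[[p]] <- list(
      omnibus = kruskal_wallis(groups),
      pairwise = pairwise_rank_sum(groups),
      summary = data.frame(
        label = names(groups),
        n = lengths(groups),
        median = vapply(groups, stats::median, 1),
        iqr = vapply(groups, stats::IQR, 1),
        row.names = NULL, stringsAsFactors = FALSE))
  }
  out
}
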