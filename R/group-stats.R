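# tie-corrected Kruskal-Wallis H from pooled ranks (used by the exact
# permutation, where the rank vector is fixed and only labels move)
.hFromRanks <- function(r, g, tieCorrection) {
  N <- length(r)
  Rs <- tapply(r, g, sum)
  ns <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rs^2 / ns) - 3 * (N + 1)
  H / tieCorrection
}

.tieCorrection <- function(x) {
  N <- length(x)
  tt <- table(x)
  1 - sum(tt^3 - tt) / (N^3 - N)
}

# enumerate all distinct assignments of group sizes `ns` to positions 1..N
# and return the permutation distribution of H
.exactHDistribution <- function(r, ns, tieCorrection) {
  N <- sum(ns)
  out <- numeric(0)
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    first <- utils::combn(avail, sizes[1L], simplify = FALSE)
    res <- list()
    for (sel in first) {
      rest <- recurse(setdiff(avail, sel), sizes[-1L])
      for (rr in rest) res[[length(res) + 1L]] <- c(list(sel), rr)
    }
    res
  }
  assignments <- recurse(seq_len(N), ns)
  vapply(assignments, function(asg) {
    g <- integer(N)
    for (k in seq_along(asg)) g[asg[[k]]] <- k
    .hFromRanks(r, g, tieCorrection)
  }, 0)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based nonparametric comparison of two or more independent groups
#' with mid-rank tie handling and tie correction.  The p-value comes from
#' the chi-square approximation (via [stats::kruskal.test()]); for small
#' pooled samples (N <= `exactLimit`, default 10) an exact permutation
#' p-value is computed instead by enumerating every assignment of the group
#' labels.
#'
#' @param values numeric vector of observations, or a list of per-group
#'   numeric vectors (then `groups` is ignored).
#' @param groups group labels matching `values`.
#' @param exact force (TRUE) or suppress (FALSE) the exact permutation
#'   p-value; default NULL uses it when N <= `exactLimit`.
#' @param exactLimit largest pooled N for the default exact computation.
#' @return a [GroupComparisonResult-class] (pairwise table empty; see
#'   [posthocPairwise()]).
#' @examples
#' kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
kruskalWallis <- function(values, groups = NULL, exact = NULL,
                          exactLimit = 10L) {
  if (is.list(values)) {
    groups <- rep(names(values) %||% seq_along(values),
                  lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) == 0L)) stop("every group needs at least one observation")
  N <- length(values)
  df <- nlevels(g) - 1L
  tc <- .tieCorrection(values)
  useExact <- if (is.null(exact)) N <= exactLimit else isTRUE(exact)
  method <- if (useExact) "exact permutation" else "chi-square"
  if (tc <= 0) {                          # all pooled values identical
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, g)
    H <- unname(kt$statistic)
    if (useExact) {
      hd <- .exactHDistribution(rank(values), tabulate(g), tc)
      p <- mean(hd >= H - 1e-9)
    } else {
      p <- unname(kt$p.value)
    }
  }
  new("GroupComparisonResult", H = H, pValue = p, df = df, method = method,
      pairwise = data.frame())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "GroupComparisonResult", function(object) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (%s)\n",
              object@H, object@df, object@pValue, object@method))
  if (nrow(object@pairwise)) {
    cat("Post-hoc pairwise (Dunn):\n")
    print(object@pairwise, digits = 4)
  }
})

#' Dunn post-hoc pairwise comparisons
#'
#' Pairwise z statistics from the pooled mid-ranks with tie correction,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}},}
#' with two-sided normal p-values and (by default) Holm adjustment.  Rows
#' are ordered lexicographically by group name for determinism.
#'
#' @inheritParams kruskalWallis
#' @param method multiplicity adjustment: "holm" (default), "bonferroni",
#'   or "none".
#' @return data.frame with columns group1, group2, z, p, pAdj.
#' @export
posthocPairwise <- function(values, groups = NULL,
                            method = c("holm", "bonferroni", "none")) {
  method <- match.arg(method)
  if (is.list(values)) {
    groups <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 3L)
    stop("post-hoc pairwise comparisons need at least 3 groups; ",
         "with 2 groups use the omnibus test")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ns <- tabulate(g)
  tt <- table(values)
  sig2 <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  lev <- sort(levels(g))
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- match(pairs[1L, j], levels(g)); i2 <- match(pairs[2L, j], levels(g))
    denom <- sqrt(sig2 * (1 / ns[i1] + 1 / ns[i2]))
    z[j] <- if (denom > 0) (rbar[i1] - rbar[i2]) / denom else 0
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             pAdj = stats::p.adjust(p, method = method))
}

#' Validate a measurement table
#'
#' A measurement table holds one row per (subject, metric): columns
#' `subject`, `group`, `metric`, `value`.
#'
#' @param df a data.frame.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
measurementTable <- function(df) {
  need <- c("subject", "group", "metric", "value")
  if (!all(need %in% names(df)))
    stop("measurement table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[, c("subject", "metric")]) > 0L)
    stop("one value per (subject, metric) allowed")
  if (!is.numeric(df$value)) stop("value must be numeric")
  df
}

#' Correlation between two metrics
#'
#' Pearson correlation of paired per-subject values of two metrics
#' (e.g. SUVmax vs Ki), with R^2 and a two-sided p-value.
#'
#' @param table a [measurementTable()] data.frame.
#' @param metricA,metricB metric names to pair.
#' @param groups optional group labels to restrict to.
#' @return list with r, rSquared, pValue, n, and flag `degenerate` when an
#'   input is constant (correlation undefined).
#' @export
metricCorrelation <- function(table, metricA, metricB, groups = NULL) {
  table <- measurementTable(table)
  if (!is.null(groups)) table <- table[table$group %in% groups, ]
  a <- table[table$metric == metricA, c("subject", "value")]
  b <- table[table$metric == metricB, c("subject", "value")]
  m <- merge(a, b, by = "subject", suffixes = c("A", "B"))
  if (nrow(m) < 3L) stop("need at least 3 paired observations")
  if (stats::var(m$valueA) == 0 || stats::var(m$valueB) == 0) {
    warning("constant metric; correlation undefined")
    return(list(r = NA_real_, rSquared = NA_real_, pValue = NA_real_,
                n = nrow(m), degenerate = TRUE))
  }
  ct <- stats::cor.test(m$valueA, m$valueB, method = "pearson")
  list(r = unname(ct$estimate), rSquared = unname(ct$estimate)^2,
       pValue = ct$p.value, n = nrow(m), degenerate = FALSE)
}

#' Default lesion/location contrasts of the six-group design
#'
#' The comparison layout of the emulated study: lesion types compared at a
#' fixed body location, and each lesion type compared across locations.
#'
#' @return named list of character vectors of group names.
#' @export
defaultLesionContrasts <- function() {
  list(
    subcutaneous_lesions = c("subcutaneous_tumor",
                             "subcutaneous_inflammation_with_tumor",
                             "subcutaneous_inflammation_without_tumor"),
    in_situ_lesions = c("in_situ_tumor", "in_situ_inflammation"),
    tumors_by_location = c("subcutaneous_tumor", "in_situ_tumor"),
    inflammations_by_location = c("subcutaneous_inflammation_with_tumor",
                                  "subcutaneous_inflammation_without_tumor",
                                  "in_situ_inflammation",
                                  "spontaneous_liver_inflammation"))
}

#' Group comparison report over a measurement table
#'
#' For every requested metric and contrast: per-group summaries
#' (n, mean, SD), the Kruskal-Wallis omnibus test, and — when the omnibus
#' is significant at `alpha` and the contrast has at least 3 groups — the
#' Dunn post-hoc pairwise table.
#'
#' @param table a [measurementTable()] data.frame.
#' @param metrics metric names to analyse (default: all in the table).
#' @param contrasts named list of group-name vectors; NULL compares all
#'   groups present per metric.
#' @param alpha significance level (default 0.05).
#' @param posthocMethod adjustment for [posthocPairwise()].
#' @return list of class "fdgGroupAnalysis": per metric, per contrast, a
#'   list with `summary` (data.frame), `omnibus`
#'   ([GroupComparisonResult-class], pairwise filled when applicable).
#' @export
runGroupAnalysis <- function(table, metrics = NULL, contrasts = NULL,
                             alpha = 0.05, posthocMethod = "holm") {
  table <- measurementTable(table)
  metrics <- metrics %||% unique(table$metric)
  out <- list()
  for (met in metrics) {
    sub <- table[table$metric == met, ]
    if (!nrow(sub)) stop("no values for metric ", met)
    cons <- contrasts %||% list(all_groups = sort(unique(sub$group)))
    metOut <- list()
    for (cn in names(cons)) {
      gsel <- cons[[cn]]
      dat <- sub[sub$group %in% gsel, ]
      present <- intersect(gsel, unique(dat$group))
      if (length(present) < 2L)
        stop("missing contrast groups for ", met, " / ", cn)
      summ <- do.call(rbind, lapply(present, function(gr) {
        v <- dat$value[dat$group == gr]
        data.frame(group = gr, n = length(v), mean = mean(v),
                   sd = stats::sd(v))
      }))
      omni <- kruskalWallis(dat$value, dat$group)
      if (omni@pValue < alpha && length(present) >= 3L)
        omni@pairwise <- posthocPairwise(dat$value, dat$group,
                                         method = posthocMethod)
      metOut[[cn]] <- list(summary = summ, omnibus = omni)
    }
    out[[met]] <- metOut
  }
  structure(list(results = out, alpha = alpha), class = "fdgGroupAnalysis")
}

#' @export
print.fdgGroupAnalysis <- function(x, ...) {
  for (met in names(x$results)) {
    cat("==== Metric:", met, "====\n")
    for (cn in names(x$results[[met]])) {
      res <- x$results[[met]][[cn]]
      cat("--", cn, "--\n")
      s <- res$summary
      for (i in seq_len(nrow(s)))
        cat(sprintf("  %-42s n=%2d  %.4g +/- %.4g\n", s$group[i], s$n[i],
                    s$mean[i], s$sd[i]))
      show(res$omnibus)
    }
  }
  invisible(x)
}
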