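#' Normalized ranks for a one-directional gene list
#'
#' Converts a per-gene statistic into normalized ranks `rank/n` in `(0, 1]`,
#' with average ranks for ties. The smallest normalized rank belongs to the
#' most extreme gene in the chosen direction: `descending` puts the largest
#' statistic first (up-regulation list), `ascending` the smallest
#' (down-regulation list).
#'
#' @param stat Numeric vector of finite per-gene statistics.
#' @param direction `"descending"` or `"ascending"`.
#' @return Normalized ranks in `(0, 1]`, same length/names as `stat`.
#' @export
normalize_ranks <- function(stat, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  stop_if_not(length(stat) > 0, "empty statistic vector")
  stop_if_not(all(is.finite(stat)), "statistics must be finite")
  x <- if (direction == "descending") -stat else stat
  rank(x, ties.method = "average") / length(x)
}

#' Robust rank aggregation score for one gene
#'
#' Given a gene's normalized ranks across `k` studies, the aggregation score
#' is the minimum over order statistics `j` of the probability that the j-th
#' order statistic of `k` independent Uniform(0,1) variables is at most the
#' observed `r_(j)`, i.e. `min_j P(Beta(j, k - j + 1) <= r_(j))`. Small
#' scores indicate that the gene sits unusually high in several lists at
#' once. The Bonferroni-corrected p-value multiplies the score by the size of
#' the gene universe.
#'
#' @param r Normalized ranks in `(0, 1]`, one per study.
#' @param n_genes Optional gene-universe size for the Bonferroni correction.
#' @return List with `rho` and `corrected_p` (`NA` when `n_genes` missing).
#' @examples
#' rra_rho(c(0.1, 0.2, 0.9))$rho  # 0.104
#' @export
rra_rho <- function(r, n_genes = NULL) {
  stop_if_not(length(r) >= 1, "at least one rank required")
  stop_if_not(all(r > 0 & r <= 1), "ranks must lie in (0, 1]")
  k <- length(r)
  rs <- sort(r)
  rho <- min(stats::pbeta(rs, seq_len(k), k - seq_len(k) + 1))
  corrected <- if (is.null(n_genes)) NA_real_ else min(1, rho * n_genes)
  list(rho = rho, corrected_p = corrected)
}

#' DerSimonian-Laird random-effects pooling of per-study fold changes
#'
#' Pools per-study log2 fold changes `y` with sampling variances `v` using
#' the moment estimator of the between-study variance:
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with fixed
#' weights `w = 1/v` and Cochran's `Q`; the pooled estimate then uses
#' random-effects weights `1/(v + tau2)`.
#'
#' @param y Per-study log2 fold changes.
#' @param v Per-study sampling variances, all positive.
#' @return List with `meta_lfc`, `tau2`, `pooled_var`, `q` and `k`.
#' @export
pool_fold_changes <- function(y, v) {
  k <- length(y)
  stop_if_not(k >= 1, "at least one study required")
  stop_if_not(length(v) == k, "y and v must have equal length")
  stop_if_not(all(v > 0), "all sampling variances must be positive")
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  tau2 <- if (k > 1) {
    cc <- sum(w) - sum(w^2) / sum(w)
    max(0, (q - (k - 1)) / cc)
  } else 0
  wstar <- 1 / (v + tau2)
  list(meta_lfc = sum(wstar * y) / sum(wstar), tau2 = tau2,
       pooled_var = 1 / sum(wstar), q = q, k = k)
}

#' Fisher's combined probability test
#'
#' @param p P-values in `(0, 1]`.
#' @return List with `statistic` (`-2 * sum(log(p))`), `df` (`2m`) and
#'   `combined_p` (upper chi-square tail).
#' @export
fisher_combined <- function(p) {
  stop_if_not(length(p) >= 1, "at least one p-value required")
  stop_if_not(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = stat, df = df,
       combined_p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Per-study differential-expression summaries
#'
#' Welch two-sample statistics on log2 expression for each gene: effect
#' `y = mean(case) - mean(control)`, sampling variance
#' `v = s1^2/n1 + s2^2/n2`, Welch-Satterthwaite p-value, and the t statistic
#' used for rank lists.
#'
#' @param expr Genes-by-samples log2 expression matrix.
#' @param groups Factor/character per sample; `case_level` marks cases.
#' @param study_id Label carried into the output.
#' @param case_level Level treated as the case group (default `"sptb"`).
#' @return Data frame with columns `study_id`, `gene`, `y`, `v`, `p`, `t`.
#' @export
study_summary <- function(expr, groups, study_id = "study",
                          case_level = "sptb") {
  groups <- as.character(groups)
  stop_if_not(ncol(expr) == length(groups),
              "groups must have one entry per expression column")
  case <- groups == case_level
  stop_if_not(sum(case) >= 2 && sum(!case) >= 2,
              "each group needs at least two samples")
  m1 <- rowMeans(expr[, case, drop = FALSE])
  m0 <- rowMeans(expr[, !case, drop = FALSE])
  s1 <- apply(expr[, case, drop = FALSE], 1, stats::var)
  s0 <- apply(expr[, !case, drop = FALSE], 1, stats::var)
  n1 <- sum(case); n0 <- sum(!case)
  y <- m1 - m0
  v <- s1 / n1 + s0 / n0
  tt <- y / sqrt(v)
  df <- v^2 / ((s1 / n1)^2 / (n1 - 1) + (s0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(study_id = study_id, gene = rownames(expr), y = y, v = v,
             p = pmax(p, .Machine$double.xmin), t = tt,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-study differential-expression meta-analysis
#'
#' Integrates per-study summaries into one table per gene: DerSimonian-Laird
#' pooled log2 fold change with between-study variance, Fisher's combined
#' p-value, and robust-rank-aggregation scores computed separately on the
#' up-regulation (descending t) and down-regulation (ascending t) lists. A
#' gene's reported direction follows the sign of the pooled fold change, and
#' its reported RRA score is the one for that direction.
#'
#' @param studies List of per-study lists with elements `expr` (genes x
#'   samples, log2) and `groups`; alternatively a precomputed list of
#'   [study_summary()] data frames via `summaries`.
#' @param summaries Optional list of per-study summary data frames.
#' @param case_level Case label passed to [study_summary()].
#' @return Data frame with one row per gene: `gene`, `n_studies_present`,
#'   `meta_lfc`, `tau2`, `pooled_var`, `meta_z`, `rra_rho`, `rra_p`,
#'   `fisher_stat`, `fisher_df`, `fisher_p`, `direction`.
#' @export
meta_analyze <- function(studies = NULL, summaries = NULL,
                         case_level = "sptb") {
  if (is.null(summaries)) {
    stop_if_not(!is.null(studies), "provide studies or summaries")
    summaries <- lapply(seq_along(studies), function(i) {
      s <- studies[[i]]
      study_summary(s$expr, s$groups,
                    study_id = s$study_id %||% sprintf("study%02d", i),
                    case_level = case_level)
    })
  }
  k_total <- length(summaries)
  # per-study rank lists over that study's own gene universe
  summaries <- lapply(summaries, function(d) {
    d$r_up <- normalize_ranks(d$t, "descending")
    d$r_down <- normalize_ranks(d$t, "ascending")
    d
  })
  long <- do.call(rbind, summaries)
  genes <- unique(long$gene)
  n_genes <- length(genes)
  by_gene <- split(long, factor(long$gene, levels = genes))
  rows <- lapply(by_gene, function(d) {
    pooled <- pool_fold_changes(d$y, d$v)
    fc <- fisher_combined(d$p)
    up <- rra_rho(d$r_up, n_genes)
    down <- rra_rho(d$r_down, n_genes)
    dir_up <- pooled$meta_lfc >= 0
    rra <- if (dir_up) up else down
    data.frame(gene = d$gene[1], n_studies_present = nrow(d),
               meta_lfc = pooled$meta_lfc, tau2 = pooled$tau2,
               pooled_var = pooled$pooled_var,
               meta_z = pooled$meta_lfc / sqrt(pooled$pooled_var),
               rra_rho = rra$rho, rra_p = rra$corrected_p,
               fisher_stat = fc$statistic, fisher_df = fc$df,
               fisher_p = fc$combined_p,
               direction = if (dir_up) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_studies_total") <- k_total
  rownames(out) <- NULL
  out
}

#' Candidate filtering of meta-analysis results
#'
#' A gene is retained if it is present in all studies, its pooled
#' fold change on the fold scale (`2^|meta_lfc|`) is at least `min_abs_fc`,
#' and its meta p-value is below `max_p`. Retained genes are partitioned by
#' the sign of the pooled fold change.
#'
#' @param meta Data frame from [meta_analyze()].
#' @param min_abs_fc Minimum absolute fold change on the fold scale
#'   (default 1.2).
#' @param max_p Maximum meta p-value (default 0.05).
#' @param require_all_studies Require presence in every study (default TRUE).
#' @param p_col Column used as the meta p-value (default `"fisher_p"`).
#' @param n_studies_total Total study count; defaults to the attribute set by
#'   [meta_analyze()] or the maximum observed.
#' @return List with `up` and `down` gene vectors and a `counts` summary.
#' @export
filter_candidates <- function(meta, min_abs_fc = 1.2, max_p = 0.05,
                              require_all_studies = TRUE,
                              p_col = "fisher_p", n_studies_total = NULL) {
  stop_if_not(min_abs_fc > 0 && max_p > 0, "thresholds must be positive")
  if (nrow(meta) == 0) {
    return(list(up = character(), down = character(),
                counts = c(up = 0L, down = 0L, tested = 0L)))
  }
  n_total <- n_studies_total %||% attr(meta, "n_studies_total") %||%
    max(meta$n_studies_present)
  keep <- rep(TRUE, nrow(meta))
  if (require_all_studies) keep <- meta$n_studies_present == n_total
  keep <- keep & (2^abs(meta$meta_lfc) >= min_abs_fc) &
    (meta[[p_col]] < max_p)
  up <- meta$gene[keep & meta$meta_lfc > 0]
  down <- meta$gene[keep & meta$meta_lfc < 0]
  list(up = up, down = down,
       counts = c(up = length(up), down = length(down),
                  tested = nrow(meta)))
}
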