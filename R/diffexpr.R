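#' Median-of-ratios size factors
#'
#' The library-size correction behind "normalized read count": per sample,
#' the median ratio of its counts to the per-gene geometric mean, taken over
#' genes expressed in every sample. Identical columns get identical factors;
#' doubling a column doubles its factor.
#'
#' @param x A [reprog_counts] object or an integer matrix (genes x samples).
#' @return Named numeric vector of strictly positive per-sample factors.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "reprog_counts")) x$counts else x
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    stop("no gene has nonzero counts in every sample; ",
         "consider a pseudo-reference fallback (e.g. add a spiked-in ",
         "reference gene or filter samples)", call. = FALSE)
  }
  logm <- log(m[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(stats::median(col - loggeo)))
  names(sf) <- colnames(m)
  sf
}

#' Normalize a count matrix by median-of-ratios size factors
#'
#' @param x A [reprog_counts] object.
#' @return Object of class `reprog_norm`: list with `values` (counts divided
#'   by size factors), `size_factors`, and the sample `design`.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "reprog_counts"))
  sf <- size_factors(x)
  values <- sweep(x$counts, 2, sf, "/")
  structure(list(values = values, size_factors = sf, design = x$design),
            class = "reprog_norm")
}

#' @export
print.reprog_norm <- function(x, ...) {
  cat(sprintf("<reprog_norm> %d genes x %d samples; size factors in [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

# Group means of normalized values plus the variance of each group mean under
# the NB model var = mu + alpha mu^2 on the count scale, propagated through
# the per-sample size factors.
group_mean_var <- function(norm, samples, alpha) {
  v <- norm$values[, samples, drop = FALSE]
  sf <- norm$size_factors[samples]
  mu <- rowMeans(v)
  n <- length(samples)
  var_mean <- (mu * mean(1 / sf) + alpha * mu^2) / n
  list(mean = mu, var_mean = var_mean, n = n, mat = v)
}

# Gene-wise method-of-moments NB dispersion, pooled across the two groups.
# Per group: alpha_g = (s2 - mu * mean(1/sf)) / mu^2 on the normalized scale;
# groups combine weighted by residual df. Can be negative (Poisson-like
# genes); clamping happens after moderation.
mom_dispersion <- function(norm, samples_a, samples_b) {
  est_one <- function(samples) {
    v <- norm$values[, samples, drop = FALSE]
    sf <- norm$size_factors[samples]
    mu <- rowMeans(v)
    s2 <- rowSums((v - mu)^2) / (length(samples) - 1L)
    a <- (s2 - mu * mean(1 / sf)) / mu^2
    a[!is.finite(a)] <- 0
    a
  }
  wa <- length(samples_a) - 1L
  wb <- length(samples_b) - 1L
  (est_one(samples_a) * wa + est_one(samples_b) * wb) / (wa + wb)
}

# Mean-trend of the gene-wise dispersions: trimmed mean of alpha_mom within
# log-mean bins of roughly equal occupancy, interpolated at each gene's mean.
# Genes at very low means carry little information and inherit the nearest
# bin's value.
dispersion_trend <- function(alpha_mom, base_mean, n_bins = 20) {
  ok <- base_mean > 0 & is.finite(alpha_mom)
  if (sum(ok) < 10) {
    return(rep(max(mean(alpha_mom[ok]), 0), length(alpha_mom)))
  }
  lm <- log(base_mean[ok])
  breaks <- unique(stats::quantile(lm, probs = seq(0, 1, length.out =
                                                     n_bins + 1)))
  bin <- cut(lm, breaks, include.lowest = TRUE)
  centers <- tapply(lm, bin, mean)
  fit <- tapply(alpha_mom[ok], bin, mean, trim = 0.1)
  keep <- !is.na(centers) & !is.na(fit)
  out <- rep(NA_real_, length(alpha_mom))
  if (sum(keep) >= 2) {
    out[ok] <- stats::approx(centers[keep], fit[keep], xout = lm,
                             rule = 2)$y
  } else {
    out[ok] <- mean(alpha_mom[ok], trim = 0.1)
  }
  out[!ok] <- 0  # all-zero genes are never tested
  pmax(out, 0)
}

# Moderated dispersion: gene-wise MOM shrunk toward the mean-trend with
# prior_df pseudo-degrees of freedom (limma-style), then floored.
moderate_dispersion <- function(alpha_mom, alpha_trend, df_gene,
                                prior_df = 10, floor = 1e-8) {
  a <- (df_gene * pmax(alpha_mom, 0) + prior_df * alpha_trend) /
    (df_gene + prior_df)
  pmax(a, floor)
}

#' Negative-binomial Wald test for one two-group contrast
#'
#' The differential-expression engine: per gene, a method-of-moments NB
#' dispersion pooled across the two groups and moderated toward a mean-trend
#' fitted over all genes (`prior_df` pseudo-observations, floored at
#' `dispersion_floor`); a log2 fold change of normalized-count means
#' (pseudocount 0.5 applied to both means when either is zero); a
#' delta-method standard error on that log2 fold change; and a two-sided
#' Wald p-value referenced against a t-distribution with
#' `n_a + n_b - 2 + prior_df` degrees of freedom. The moderation mirrors
#' what genome-scale engines do: with a handful of replicates a purely
#' gene-wise variance makes extreme p-values unattainable (heavy t tails)
#' and occasionally far too small (underestimated dispersion), so dispersion
#' information is shared across genes. Benjamini-Hochberg q-values are
#' computed over all genes with nonzero total counts in the contrast
#' (genome-wide when the matrix is genome-wide); genes with all-zero counts
#' in both groups get `p = q = NA`.
#'
#' @param norm A [normalize_counts()] result.
#' @param group_a,group_b Group labels; `a` over `b` defines the fold-change
#'   sign.
#' @param time_a,time_b Optional time points restricting each group.
#' @param label Contrast label (default `"a_vs_b"`).
#' @param prior_df Weight (pseudo-degrees of freedom) of the dispersion
#'   trend in the moderated estimate.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @return A tibble of class `reprog_de`: `gene`, `mean_a`, `mean_b`,
#'   `log2fc`, `p`, `q`, with the contrast recorded in attributes.
#' @export
test_contrast <- function(norm, group_a, group_b,
                          time_a = NULL, time_b = NULL,
                          label = NULL, prior_df = 10,
                          dispersion_floor = 1e-8) {
  stopifnot(inherits(norm, "reprog_norm"))
  sa <- samples_of(norm$design, group_a, time_a)
  sb <- samples_of(norm$design, group_b, time_b)
  if (length(sa) < 2 || length(sb) < 2) {
    stop(sprintf("need >= 2 replicates per group (got %d in '%s', %d in '%s')",
                 length(sa), group_a, length(sb), group_b), call. = FALSE)
  }
  if (length(intersect(sa, sb)) > 0) {
    stop("contrast groups share samples", call. = FALSE)
  }
  df_gene <- length(sa) + length(sb) - 2
  alpha_mom <- mom_dispersion(norm, sa, sb)
  base_mean <- rowMeans(norm$values[, c(sa, sb), drop = FALSE])
  alpha_trend <- dispersion_trend(alpha_mom, base_mean)
  alpha <- moderate_dispersion(alpha_mom, alpha_trend, df_gene,
                               prior_df = prior_df,
                               floor = dispersion_floor)
  ga <- group_mean_var(norm, sa, alpha)
  gb <- group_mean_var(norm, sb, alpha)

  zero_pair <- ga$mean == 0 | gb$mean == 0
  ma <- ifelse(zero_pair, ga$mean + 0.5, ga$mean)
  mb <- ifelse(zero_pair, gb$mean + 0.5, gb$mean)
  log2fc <- log2(ma) - log2(mb)

  # delta method: Var(log2 m) = Var(m) / (m ln2)^2; zero-mean groups reuse
  # the pseudocounted mean so the statistic stays finite
  inv_sf_a <- mean(1 / norm$size_factors[sa])
  inv_sf_b <- mean(1 / norm$size_factors[sb])
  va <- ifelse(zero_pair, (ma * inv_sf_a + alpha * ma^2) / ga$n, ga$var_mean)
  vb <- ifelse(zero_pair, (mb * inv_sf_b + alpha * mb^2) / gb$n, gb$var_mean)
  se <- sqrt(va / ma^2 + vb / mb^2) / log(2)
  stat <- log2fc / se
  df <- df_gene + prior_df
  p <- 2 * stats::pt(-abs(stat), df = df)
  p[se == 0 & log2fc == 0] <- 1

  untested <- ga$mean == 0 & gb$mean == 0
  p[untested] <- NA_real_
  log2fc[untested] <- 0
  q <- rep(NA_real_, length(p))
  q[!untested] <- stats::p.adjust(p[!untested], method = "BH")

  out <- tibble::tibble(
    gene = rownames(norm$values),
    mean_a = unname(ga$mean), mean_b = unname(gb$mean),
    log2fc = unname(log2fc), p = unname(p), q = unname(q)
  )
  attr(out, "contrast") <- list(
    group_a = group_a, group_b = group_b,
    time_a = time_a, time_b = time_b,
    n_a = ga$n, n_b = gb$n,
    label = label %||% paste0(group_a, "_vs_", group_b)
  )
  class(out) <- c("reprog_de", class(out))
  out
}

#' Import an externally computed differential-expression table
#'
#' Escape hatch for results produced by another engine: any table with
#' `gene`, `log2fc` and `q` columns (optionally `p`, `mean_a`, `mean_b`)
#' feeds the downstream classifiers exactly like [test_contrast()] output.
#'
#' @param path Path to a TSV/CSV table, or a data frame.
#' @param label Contrast label to attach.
#' @return A `reprog_de` tibble.
#' @export
import_de_table <- function(path, label = NULL) {
  tb <- if (is.character(path) && length(path) == 1L) read_delim_auto(path)
        else tibble::as_tibble(path)
  need <- c("gene", "log2fc", "q")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0) {
    stop("DE table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    gene = as.character(tb$gene),
    mean_a = if ("mean_a" %in% names(tb)) as.numeric(tb$mean_a) else NA_real_,
    mean_b = if ("mean_b" %in% names(tb)) as.numeric(tb$mean_b) else NA_real_,
    log2fc = as.numeric(tb$log2fc),
    p = if ("p" %in% names(tb)) as.numeric(tb$p) else NA_real_,
    q = as.numeric(tb$q)
  )
  attr(out, "contrast") <- list(label = label %||% "imported")
  class(out) <- c("reprog_de", class(out))
  out
}

#' Write a differential-expression table to TSV
#' @param de A `reprog_de` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(tibble::as_tibble(de), path)
  invisible(path)
}

#' @rdname test_contrast
#' @param x A `reprog_de` tibble.
#' @param ... Unused.
#' @export
tidy.reprog_de <- function(x, ...) {
  tibble::tibble(
    gene = x$gene,
    estimate = x$log2fc,
    p.value = x$p,
    q.value = x$q,
    mean_a = x$mean_a,
    mean_b = x$mean_b
  )
}

#' @rdname test_contrast
#' @param fold,q Significance thresholds used for the tallies.
#' @export
glance.reprog_de <- function(x, fold = 2, q = 0.01, ...) {
  ctr <- attr(x, "contrast")
  tibble::tibble(
    label = ctr$label %||% NA_character_,
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$p)),
    n_up = sum(x$log2fc >= log2(fold) & x$q < q, na.rm = TRUE),
    n_down = sum(x$log2fc <= -log2(fold) & x$q < q, na.rm = TRUE)
  )
}
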