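#' Legitimacy-evaluation settings
#'
#' @param q_relaxed Relaxed q cutoff for target-vs-start enrichment
#'   (default 0.05): any significant difference counts, at any fold.
#' @param over_margin_fold How far past the target mean the induced mean must
#'   land, in the direction of change, to call overshoot (default 2-fold).
#' @param pseudocount Offset for the log2 distance space (default 1).
#' @param activity Activity threshold for the silent-in-both check.
#' @return Named list of settings.
#' @export
legitimacy_settings <- function(q_relaxed = 0.05, over_margin_fold = 2,
                                pseudocount = 1, activity = 50) {
  stopifnot(q_relaxed > 0, q_relaxed < 1, over_margin_fold >= 1,
            pseudocount > 0, activity > 0)
  list(q_relaxed = q_relaxed, over_margin_fold = over_margin_fold,
       pseudocount = pseudocount, activity = activity)
}

#' Relaxed target-vs-start enrichment labels
#'
#' Classifies each gene's standing in the target-vs-start contrast at a
#' relaxed significance level: `target_higher` when significantly higher in
#' the target state at any fold, `start_higher` the mirror, `silent_both`
#' when every replicate of both groups is below the activity threshold (and
#' the contrast is not significant), `equal` otherwise. This relaxed tier is
#' used only inside legitimacy evaluation; the strict fold-and-q rules of
#' [classify_state()] remain the reprogramome definition.
#'
#' @param de A `reprog_de` for the target-vs-start contrast (`a` = target).
#' @param norm The [normalize_counts()] result.
#' @param target_group,start_group Group labels.
#' @param genes Genes to label (default all in `de`).
#' @param settings From [legitimacy_settings()].
#' @return Tibble: `gene`, `enrichment`, `fold`, `q`.
#' @export
relaxed_enrichment <- function(de, norm, target_group, start_group,
                               genes = NULL,
                               settings = legitimacy_settings()) {
  stopifnot(inherits(de, "reprog_de"), inherits(norm, "reprog_norm"))
  genes <- as.character(genes %||% de$gene)
  untested <- setdiff(genes, de$gene)
  if (length(untested) > 0) {
    stop("genes not tested in the target-vs-start contrast: ",
         paste(utils::head(untested, 10), collapse = ", "), call. = FALSE)
  }
  st <- samples_of(norm$design, target_group)
  ss <- samples_of(norm$design, start_group)
  vt <- norm$values[genes, st, drop = FALSE]
  vs <- norm$values[genes, ss, drop = FALSE]
  thr <- settings$activity
  silent <- (rowSums(vt < thr) == ncol(vt)) & (rowSums(vs < thr) == ncol(vs))

  idx <- match(genes, de$gene)
  mt <- de$mean_a[idx]
  ms <- de$mean_b[idx]
  q <- de$q[idx]
  zero_pair <- !is.na(mt) & !is.na(ms) & (mt == 0 | ms == 0)
  fold <- ifelse(zero_pair, (mt + 0.5) / (ms + 0.5), mt / ms)
  sig <- !is.na(q) & q < settings$q_relaxed

  tibble::tibble(
    gene = genes,
    enrichment = dplyr::case_when(
      sig & mt > ms ~ "target_higher",
      sig & ms > mt ~ "start_higher",
      silent ~ "silent_both",
      TRUE ~ "equal"
    ),
    fold = fold,
    q = q
  )
}

#' Verdict table for reprogramming legitimacy
#'
#' The total map from (response direction, relaxed enrichment) to verdict:
#' a change toward the state the target cell type favours is legitimate; a
#' change away from it is wrong; a change in a gene the two states express
#' alike (or not at all) is unwanted.
#'
#' @param direction `"up"` or `"down"` (vectorized).
#' @param enrichment One of `"target_higher"`, `"start_higher"`, `"equal"`,
#'   `"silent_both"` (vectorized).
#' @return Character vector: `"legitimate"`, `"wrong"`, or `"unwanted"`.
#' @export
#' @examples
#' legitimacy_verdict("up", "target_higher")  # legitimate
#' legitimacy_verdict("up", "start_higher")   # wrong
#' legitimacy_verdict("down", "equal")        # unwanted
legitimacy_verdict <- function(direction, enrichment) {
  stopifnot(all(direction %in% c("up", "down")),
            all(enrichment %in% c("target_higher", "start_higher",
                                  "equal", "silent_both")))
  dplyr::case_when(
    direction == "up" & enrichment == "target_higher" ~ "legitimate",
    direction == "up" & enrichment == "start_higher" ~ "wrong",
    direction == "down" & enrichment == "start_higher" ~ "legitimate",
    direction == "down" & enrichment == "target_higher" ~ "wrong",
    TRUE ~ "unwanted"
  )
}

#' Evaluate reprogramming legitimacy of responsive genes
#'
#' Cross-classifies each responsive (up/down, non-exogenous) gene's
#' direction against its relaxed target-vs-start enrichment to give a
#' verdict, then sub-classifies legitimate genes by where the induced
#' samples landed. Distances are computed in `log2(normalized + pseudocount)`
#' space between the induced-sample mean and each of the target and start
#' group means: `over` when the induced mean overshoots the target mean by
#' more than the margin in the direction of change, otherwise `proper` when
#' the gene ends closer to the target than to the start, `insufficient` when
#' it moved significantly but remains closer to the start.
#'
#' @param responses A [call_responses()] (optionally
#'   [call_irresponsive()]-updated) result.
#' @param enrichments A [relaxed_enrichment()] table covering the responsive
#'   genes.
#' @param norm The [normalize_counts()] result.
#' @param target_group,start_group,response_group Group labels.
#' @param settings From [legitimacy_settings()].
#' @return Tibble of class `reprog_legit`: `gene`, `direction`,
#'   `enrichment`, `verdict`, `subclass`, `d_target`, `d_start`.
#' @export
evaluate_legitimacy <- function(responses, enrichments, norm,
                                target_group = "ESC",
                                start_group = "fibroblast_naive",
                                response_group = "OSKM",
                                settings = legitimacy_settings()) {
  stopifnot(inherits(norm, "reprog_norm"))
  resp <- responses[!responses$exogenous &
                      responses$direction %in% c("up", "down"), ]
  if (nrow(resp) == 0) {
    out <- tibble::tibble(gene = character(), direction = character(),
                          enrichment = character(), verdict = character(),
                          subclass = character(), d_target = double(),
                          d_start = double())
    class(out) <- c("reprog_legit", class(out))
    return(out)
  }
  eidx <- match(resp$gene, enrichments$gene)
  if (anyNA(eidx)) {
    stop("responsive genes missing from the enrichment table: ",
         paste(utils::head(resp$gene[is.na(eidx)], 10), collapse = ", "),
         call. = FALSE)
  }
  enr <- enrichments$enrichment[eidx]
  verdict <- legitimacy_verdict(resp$direction, enr)

  lg <- log2_matrix(norm, settings$pseudocount)
  st <- samples_of(norm$design, target_group)
  ss <- samples_of(norm$design, start_group)
  so <- norm$design$sample[norm$design$group == response_group]
  g <- resp$gene
  prof_t <- rowMeans(lg[g, st, drop = FALSE])
  prof_s <- rowMeans(lg[g, ss, drop = FALSE])
  prof_o <- rowMeans(lg[g, so, drop = FALSE])
  d_target <- abs(prof_o - prof_t)
  d_start <- abs(prof_o - prof_s)

  m_t <- rowMeans(norm$values[g, st, drop = FALSE])
  m_o <- rowMeans(norm$values[g, so, drop = FALSE])
  margin <- settings$over_margin_fold
  over <- (resp$direction == "up" & m_o > margin * m_t) |
    (resp$direction == "down" & m_o * margin < m_t)
  subclass <- dplyr::case_when(
    verdict != "legitimate" ~ "none",
    over ~ "over",
    d_target < d_start ~ "proper",
    TRUE ~ "insufficient"
  )

  out <- tibble::tibble(
    gene = g, direction = resp$direction, enrichment = enr,
    verdict = verdict, subclass = subclass,
    d_target = unname(d_target), d_start = unname(d_start)
  )
  attr(out, "settings") <- settings
  class(out) <- c("reprog_legit", class(out))
  out
}

#' Summarize legitimacy calls per response direction
#'
#' Counts of each verdict and subclass per direction plus the legitimate
#' fraction, `legitimate / (legitimate + wrong + unwanted)`. With no
#' responsive genes the summary is empty and fractions are `NA`.
#'
#' @param calls A [evaluate_legitimacy()] result.
#' @return Tibble: one row per direction with `n`, verdict counts, subclass
#'   counts, `legit_fraction`.
#' @export
legitimacy_summary <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(
      direction = character(), n = integer(), legitimate = integer(),
      wrong = integer(), unwanted = integer(), proper = integer(),
      insufficient = integer(), over = integer(),
      legit_fraction = double()))
  }
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(calls), .data$direction),
    n = dplyr::n(),
    legitimate = sum(.data$verdict == "legitimate"),
    wrong = sum(.data$verdict == "wrong"),
    unwanted = sum(.data$verdict == "unwanted"),
    proper = sum(.data$subclass == "proper"),
    insufficient = sum(.data$subclass == "insufficient"),
    over = sum(.data$subclass == "over"),
    legit_fraction = .data$legitimate / dplyr::n(),
    .groups = "drop"
  )
}

#' @rdname evaluate_legitimacy
#' @param x A `reprog_legit` tibble.
#' @param ... Unused.
#' @export
glance.reprog_legit <- function(x, ...) {
  s <- legitimacy_summary(x)
  tibble::tibble(
    n_responsive = sum(s$n),
    n_legitimate = sum(s$legitimate),
    n_wrong = sum(s$wrong),
    n_unwanted = sum(s$unwanted),
    legit_fraction_up = s$legit_fraction[s$direction == "up"][1],
    legit_fraction_down = s$legit_fraction[s$direction == "down"][1]
  )
}
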