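#' The four canonical reprogramming-factor symbols
#'
#' OCT4 (official symbol POU5F1), SOX2, KLF4 and MYC. Genes in this set are
#' flagged exogenous in response calls: their measured induction reflects the
#' delivered transgenes, so they are excluded from responsive-TF counts.
#'
#' @return Character vector of symbols.
#' @export
oskm_factors <- function() c("POU5F1", "SOX2", "KLF4", "MYC")

#' Run the response contrast grid
#'
#' One differential-expression contrast per (reference group x response time
#' point), with the induced (response) samples as group `a`, so positive
#' fold changes mean upregulation under induction.
#'
#' @param norm A [normalize_counts()] result.
#' @param response_group Group label of the induced samples (default
#'   `"OSKM"`).
#' @param references Character vector of reference group labels (default the
#'   naive fibroblasts and the GFP-transduced control).
#' @param time_points Numeric vector of response time points in hours;
#'   defaults to every time point present for the response group.
#' @return Tibble of class `reprog_de_grid`: `reference`, `time_h`, `de`
#'   (list column of `reprog_de` tibbles).
#' @export
response_de_grid <- function(norm, response_group = "OSKM",
                             references = c("fibroblast_naive",
                                            "fibroblast_GFP"),
                             time_points = NULL) {
  stopifnot(inherits(norm, "reprog_norm"))
  if (is.null(time_points)) {
    tp <- norm$design$time_h[norm$design$group == response_group]
    time_points <- sort(unique(tp[!is.na(tp)]))
    if (length(time_points) == 0) time_points <- NA_real_
  }
  grid <- tidyr::expand_grid(reference = references, time_h = time_points)
  grid$de <- purrr::pmap(grid, function(reference, time_h) {
    test_contrast(norm, response_group, reference,
                  time_a = if (is.na(time_h)) NULL else time_h,
                  label = sprintf("%s_%sh_vs_%s", response_group,
                                  format(time_h), reference))
  })
  class(grid) <- c("reprog_de_grid", class(grid))
  grid
}

# Long per-gene evidence table from a contrast grid: one row per
# gene x reference x time point with fold (response over reference) and q.
grid_evidence <- function(de_grid) {
  purrr::pmap_dfr(de_grid, function(reference, time_h, de) {
    tibble::tibble(gene = de$gene, reference = reference, time_h = time_h,
                   fold = 2^de$log2fc, q = de$q)
  })
}

#' Call transcriptional responses to factor induction
#'
#' A gene is called `up` only when it is at least `fold`-fold higher in the
#' induced samples than in EVERY reference at EVERY time point, each time
#' with q below the strict cutoff; `down` is the mirror. Requiring the
#' conjunction over references removes virus-per-se effects when a
#' GFP-transduced control is supplied. The delivered reprogramming factors
#' are flagged exogenous and never counted among responsive genes. All other
#' genes are `unclassified` pending the irresponsiveness rules
#' ([call_irresponsive()]).
#'
#' @param de_grid A [response_de_grid()] result (or a tibble with columns
#'   `reference`, `time_h`, `de`).
#' @param factors Symbols to flag as exogenous (default [oskm_factors()]).
#' @param fold Fold threshold (default 2).
#' @param q Strict q cutoff (default 0.01).
#' @return Tibble of class `reprog_response`: `gene`, `direction`
#'   (`up`/`down`/`unclassified`), `exogenous`, `n_contrasts`, plus
#'   `min_fold`/`max_fold`/`max_q` summaries; the full per-contrast
#'   evidence is in `attr(, "evidence")`.
#' @export
call_responses <- function(de_grid, factors = oskm_factors(),
                           fold = 2, q = 0.01) {
  if (nrow(de_grid) == 0) stop("empty contrast grid", call. = FALSE)
  ev <- grid_evidence(de_grid)
  n_contrasts <- nrow(de_grid)
  fold_thr <- fold
  q_thr <- q

  per_gene <- dplyr::summarise(
    dplyr::group_by(ev, .data$gene),
    n_seen = dplyr::n(),
    min_fold = min(.data$fold),
    max_fold = max(.data$fold),
    max_q = ifelse(all(is.na(.data$q)), NA_real_, max(.data$q, na.rm = FALSE)),
    up_all = all(!is.na(.data$q) & .data$fold >= .env$fold_thr &
                   .data$q < .env$q_thr),
    down_all = all(!is.na(.data$q) & .data$fold <= 1 / .env$fold_thr &
                     .data$q < .env$q_thr),
    .groups = "drop"
  )
  incomplete <- per_gene$gene[per_gene$n_seen < n_contrasts]
  if (length(incomplete) > 0) {
    stop("genes missing from some contrasts: ",
         paste(utils::head(incomplete, 10), collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(
    gene = per_gene$gene,
    direction = dplyr::case_when(
      per_gene$up_all ~ "up",
      per_gene$down_all ~ "down",
      TRUE ~ "unclassified"
    ),
    exogenous = per_gene$gene %in% factors,
    n_contrasts = n_contrasts,
    min_fold = per_gene$min_fold,
    max_fold = per_gene$max_fold,
    max_q = per_gene$max_q
  )
  attr(out, "evidence") <- ev
  attr(out, "thresholds") <- list(fold = fold, q = q)
  class(out) <- c("reprog_response", class(out))
  out
}

#' Apply the irresponsiveness rules to reprogramome genes
#'
#' A reprogramome member (activatome, erasome, or either enriched class) is
#' irresponsive to induction when, across every reference and time point:
#'
#' 1. its fold change is below the threshold in both directions;
#' 2. no contrast is significant at the strict q cutoff (a significant
#'    sub-threshold change disqualifies a gene regardless of fold);
#' 3. its distance from the target state has not collapsed: the
#'    induced-vs-target normalized-mean fold stays at or above the
#'    threshold at every time point, significance ignored;
#' 4. for upreprogramome genes only, a gene still inactive after induction
#'    (every induced replicate below the activity threshold at every time
#'    point) is irresponsive even when its fold change and significance
#'    would otherwise disqualify it.
#'
#' Rule 4 can override an `up` call; rules 1-3 only ever move `unclassified`
#' genes to `irresponsive`. Non-reprogramome genes are untouched.
#'
#' @param responses A [call_responses()] result.
#' @param state_calls A [classify_state()] result covering the same genes.
#' @param norm The [normalize_counts()] result.
#' @param target_group Target-state group label (default `"ESC"`).
#' @param response_group Induced group label (default `"OSKM"`).
#' @param time_points Response time points; default all present.
#' @param activity,fold,q Thresholds (defaults 50, 2, 0.01).
#' @return `responses` with direction updated to `"irresponsive"` where the
#'   rules apply, plus columns `reprogramome_side`, `post_induction_active`,
#'   `min_target_fold`.
#' @export
call_irresponsive <- function(responses, state_calls, norm,
                              target_group = "ESC", response_group = "OSKM",
                              time_points = NULL,
                              activity = 50, fold = 2, q = 0.01) {
  stopifnot(inherits(responses, "reprog_response"),
            inherits(norm, "reprog_norm"))
  ev <- attr(responses, "evidence")
  mem <- reprogramome_membership(state_calls)
  side <- dplyr::case_when(
    mem$upreprogramome ~ "up",
    mem$downreprogramome ~ "down",
    TRUE ~ NA_character_
  )
  names(side) <- mem$gene

  if (is.null(time_points)) {
    tp <- norm$design$time_h[norm$design$group == response_group]
    time_points <- sort(unique(tp[!is.na(tp)]))
  }
  st <- samples_of(norm$design, target_group)
  mt <- rowMeans(norm$values[, st, drop = FALSE])

  # per time point: induced-group mean and activity; target-distance fold
  per_tp <- purrr::map(time_points, function(t) {
    so <- samples_of(norm$design, response_group, t)
    vo <- norm$values[, so, drop = FALSE]
    mo <- rowMeans(vo)
    zero_pair <- mo == 0 | mt == 0
    r <- ifelse(zero_pair, (mo + 0.5) / (mt + 0.5), mo / mt)
    list(target_fold = pmax(r, 1 / r),
         inactive = rowSums(vo < activity) == ncol(vo))
  })
  min_target_fold <- do.call(pmin, purrr::map(per_tp, "target_fold"))
  inactive_all_tp <- Reduce(`&`, purrr::map(per_tp, "inactive"))

  gidx <- match(responses$gene, rownames(norm$values))
  out <- dplyr::mutate(
    responses,
    reprogramome_side = unname(side[.data$gene]),
    post_induction_active = !inactive_all_tp[gidx],
    min_target_fold = min_target_fold[gidx]
  )

  fold_thr <- fold
  q_thr <- q
  flat <- dplyr::summarise(
    dplyr::group_by(ev, .data$gene),
    sub_threshold = all(.data$fold < .env$fold_thr &
                          .data$fold > 1 / .env$fold_thr),
    never_significant = all(is.na(.data$q) | .data$q >= .env$q_thr),
    .groups = "drop"
  )
  fidx <- match(out$gene, flat$gene)

  rule4 <- !out$exogenous &
    !is.na(out$reprogramome_side) & out$reprogramome_side == "up" &
    !out$post_induction_active
  rules123 <- !out$exogenous &
    !is.na(out$reprogramome_side) &
    out$direction == "unclassified" &
    flat$sub_threshold[fidx] &
    flat$never_significant[fidx] &
    out$min_target_fold >= fold

  out$direction[rule4 | rules123] <- "irresponsive"
  attr(out, "evidence") <- ev
  attr(out, "thresholds") <- attr(responses, "thresholds")
  class(out) <- class(responses)
  out
}

#' @rdname call_responses
#' @param x A `reprog_response` tibble.
#' @param ... Unused.
#' @export
glance.reprog_response <- function(x, ...) {
  resp <- x[!x$exogenous, ]
  tibble::tibble(
    n_genes = nrow(x),
    n_up = sum(resp$direction == "up"),
    n_down = sum(resp$direction == "down"),
    n_irresponsive = sum(resp$direction == "irresponsive"),
    n_exogenous = sum(x$exogenous)
  )
}
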