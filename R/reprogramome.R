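#' State-classification thresholds
#'
#' The three dials behind the cell-state rules: the activity threshold on
#' normalized read counts (a gene is active in a group when every replicate
#' exceeds it, inactive when every replicate falls below it), the fold
#' threshold for enrichment, and the strict q-value cutoff.
#'
#' @param activity Normalized-count activity threshold (default 50).
#' @param fold Fold-change threshold (default 2).
#' @param q Strict q-value cutoff (default 0.01).
#' @return Named list of thresholds.
#' @export
state_thresholds <- function(activity = 50, fold = 2, q = 0.01) {
  stopifnot(activity > 0, fold >= 1, q > 0, q < 1)
  list(activity = activity, fold = fold, q = q)
}

#' Is a gene active in a set of replicates?
#'
#' Active means strictly greater than the threshold in every replicate; a
#' replicate exactly at the threshold fails. The mirror notion (inactive:
#' every replicate strictly below) is deliberately not the negation, so a
#' gene can be neither active nor inactive.
#'
#' @param norm_counts Numeric vector of per-replicate normalized counts.
#' @param threshold Activity threshold (default 50).
#' @return `TRUE` iff every replicate exceeds the threshold.
#' @export
#' @examples
#' is_active(c(60, 70, 55)) # TRUE
#' is_active(c(60, 49, 70)) # FALSE
#' is_active(c(50, 50, 50)) # FALSE (strict)
is_active <- function(norm_counts, threshold = 50) {
  if (length(norm_counts) == 0) {
    stop("empty replicate vector", call. = FALSE)
  }
  all(norm_counts > threshold)
}

is_inactive <- function(norm_counts, threshold = 50) {
  if (length(norm_counts) == 0) {
    stop("empty replicate vector", call. = FALSE)
  }
  all(norm_counts < threshold)
}

#' Cell-state category labels, in classification order
#' @return Character vector of the seven category labels.
#' @export
state_categories <- function() {
  c("inactive_both", "activatome", "erasome",
    "upreprogramome_enriched", "downreprogramome_enriched",
    "equal_active", "marginal")
}

#' Classify genes into cell-state categories
#'
#' Applies the rule cascade comparing a target cell state (e.g. pluripotent
#' stem cells) with a start state (e.g. fibroblasts), using the
#' target-vs-start differential-expression result plus per-replicate
#' normalized counts. The first matching rule wins:
#'
#' 1. `inactive_both`: every replicate of both groups below the activity
#'    threshold.
#' 2. `activatome`: active in the target, inactive in the start, fold
#'    strictly greater than the fold threshold toward the target, q below
#'    the strict cutoff.
#' 3. `erasome`: the mirror image (start-specific).
#' 4. `upreprogramome_enriched`: active in the target, fold at least the
#'    threshold toward the target, significant. The upreprogramome is the
#'    union of this class with the activatome; the class itself excludes
#'    activatome genes.
#' 5. `downreprogramome_enriched`: the mirror.
#' 6. `equal_active`: active in both groups, not significant at the strict
#'    cutoff, and fold below the threshold in both directions.
#' 7. `marginal`: everything else.
#'
#' `fold` in the output is the ratio of target to start normalized-count
#' means (pseudocount 0.5 added to both means when either is zero).
#'
#' @param de A `reprog_de` for the target-vs-start contrast (`a` = target).
#' @param norm The [normalize_counts()] result the contrast was run on.
#' @param target_group,start_group Group labels in `norm$design`.
#' @param params Thresholds from [state_thresholds()].
#' @param genes Optional subset of genes to classify (e.g. the TF catalog);
#'   defaults to every gene in `de`.
#' @return Tibble of class `reprog_state`: `gene`, `category`,
#'   `active_in_target`, `active_in_start`, `fold`, `q`.
#' @export
classify_state <- function(de, norm, target_group, start_group,
                           params = state_thresholds(), genes = NULL) {
  stopifnot(inherits(de, "reprog_de"), inherits(norm, "reprog_norm"))
  genes <- genes %||% de$gene
  genes <- as.character(genes)
  missing_de <- setdiff(genes, de$gene)
  if (length(missing_de) > 0) {
    stop("genes absent from the DE result: ",
         paste(utils::head(missing_de, 10), collapse = ", "), call. = FALSE)
  }
  missing_norm <- setdiff(genes, rownames(norm$values))
  if (length(missing_norm) > 0) {
    stop("genes absent from the normalized matrix: ",
         paste(utils::head(missing_norm, 10), collapse = ", "), call. = FALSE)
  }
  st <- samples_of(norm$design, target_group)
  ss <- samples_of(norm$design, start_group)
  if (length(st) == 0 || length(ss) == 0) {
    stop("target or start group has no samples", call. = FALSE)
  }

  vt <- norm$values[genes, st, drop = FALSE]
  vs <- norm$values[genes, ss, drop = FALSE]
  thr <- params$activity
  act_t <- rowSums(vt > thr) == ncol(vt)
  act_s <- rowSums(vs > thr) == ncol(vs)
  inact_t <- rowSums(vt < thr) == ncol(vt)
  inact_s <- rowSums(vs < thr) == ncol(vs)

  idx <- match(genes, de$gene)
  mt <- de$mean_a[idx]
  ms <- de$mean_b[idx]
  zero_pair <- !is.na(mt) & !is.na(ms) & (mt == 0 | ms == 0)
  fold <- ifelse(zero_pair, (mt + 0.5) / (ms + 0.5), mt / ms)
  q <- de$q[idx]
  f <- params$fold
  qs <- params$q
  sig <- !is.na(q) & q < qs

  category <- dplyr::case_when(
    inact_t & inact_s ~ "inactive_both",
    act_t & inact_s & fold > f & sig ~ "activatome",
    act_s & inact_t & (1 / fold) > f & sig ~ "erasome",
    act_t & fold >= f & sig ~ "upreprogramome_enriched",
    act_s & (1 / fold) >= f & sig ~ "downreprogramome_enriched",
    act_t & act_s & !is.na(q) & q > qs & fold < f & (1 / fold) < f ~
      "equal_active",
    TRUE ~ "marginal"
  )

  out <- tibble::tibble(
    gene = genes,
    category = factor(category, levels = state_categories()),
    active_in_target = act_t,
    active_in_start = act_s,
    fold = fold,
    q = q
  )
  attr(out, "params") <- params
  attr(out, "groups") <- list(target = target_group, start = start_group)
  class(out) <- c("reprog_state", class(out))
  out
}

#' Reprogramome membership from state calls
#'
#' The upreprogramome is the activatome plus the target-enriched class; the
#' downreprogramome is the erasome plus the start-enriched class.
#'
#' @param calls A `reprog_state` tibble.
#' @return `calls` with logical columns `upreprogramome`, `downreprogramome`.
#' @export
reprogramome_membership <- function(calls) {
  dplyr::mutate(
    calls,
    upreprogramome = .data$category %in%
      c("activatome", "upreprogramome_enriched"),
    downreprogramome = .data$category %in%
      c("erasome", "downreprogramome_enriched")
  )
}

#' Summarize state calls
#'
#' Category counts (always summing to the number of classified genes),
#' fold-change bins for the enriched-only classes in each direction
#' (2-3, 3-5, >5 fold, excluding activatome/erasome whose folds are
#' dominated by the pseudocount), and an optional family cross-tabulation.
#'
#' @param calls A `reprog_state` tibble.
#' @param catalog Optional `tf_catalog` for the family cross-tab.
#' @return List of class `reprog_state_summary` with tibbles
#'   `category_counts`, `fold_bins`, and `family_crosstab` (or `NULL`).
#' @export
summarize_state <- function(calls, catalog = NULL) {
  if (nrow(calls) == 0) stop("no state calls to summarize", call. = FALSE)
  category_counts <- dplyr::count(tibble::as_tibble(calls), .data$category,
                                  .drop = FALSE)

  bin_folds <- function(f) {
    cut(f, breaks = c(2, 3, 5, Inf), right = FALSE,
        labels = c("2-3", "3-5", ">5"))
  }
  up <- calls$fold[calls$category == "upreprogramome_enriched"]
  down <- 1 / calls$fold[calls$category == "downreprogramome_enriched"]
  fold_bins <- dplyr::bind_rows(
    dplyr::count(tibble::tibble(direction = "up", bin = bin_folds(up)),
                 .data$direction, .data$bin, .drop = FALSE),
    dplyr::count(tibble::tibble(direction = "down", bin = bin_folds(down)),
                 .data$direction, .data$bin, .drop = FALSE)
  )

  family_crosstab <- NULL
  if (!is.null(catalog)) {
    fam <- catalog$family[match(calls$gene, catalog$symbol)]
    fam[is.na(fam) | !fam %in% tf_family_levels()] <- "other"
    family_crosstab <- dplyr::count(
      tibble::tibble(category = calls$category, family = fam),
      .data$category, .data$family)
  }

  structure(list(category_counts = category_counts,
                 fold_bins = fold_bins,
                 family_crosstab = family_crosstab),
            class = "reprog_state_summary")
}

#' @export
print.reprog_state_summary <- function(x, ...) {
  cat("<reprog_state_summary>\nCategory counts:\n")
  print(x$category_counts)
  cat("Fold bins (enriched-only):\n")
  print(x$fold_bins)
  invisible(x)
}
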