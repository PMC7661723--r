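#' Assemble a run configuration
#'
#' Collects the group mapping, thresholds and (optionally) input paths of a
#' full pipeline run. A configuration serialized to an output directory can
#' be re-run with [run_reprogramome_config()] and reproduces every table.
#'
#' @param counts_path,design_path,catalog_path Optional input file paths
#'   (used by [run_reprogramome_config()]).
#' @param target_group,start_group,control_group,response_group Group labels
#'   in the design; `control_group = NULL` drops the second reference.
#' @param time_points Response time points; `NULL` = all present.
#' @param factors Exogenous factor symbols.
#' @param activity,fold,q_strict,q_relaxed,over_margin Thresholds.
#' @param seed Optional seed recorded with the run.
#' @return List of class `reprog_config`.
#' @export
reprog_config <- function(counts_path = NULL, design_path = NULL,
                          catalog_path = NULL,
                          target_group = "ESC",
                          start_group = "fibroblast_naive",
                          control_group = "fibroblast_GFP",
                          response_group = "OSKM",
                          time_points = NULL,
                          factors = oskm_factors(),
                          activity = 50, fold = 2,
                          q_strict = 0.01, q_relaxed = 0.05,
                          over_margin = 2,
                          seed = NULL) {
  structure(as.list(environment()), class = "reprog_config")
}

#' Run the full reprogramome pipeline
#'
#' Stages, in order: normalization; the target-vs-start contrast;
#' state classification over the TF set; the response contrast grid
#' (induced vs each reference at each time point); response and
#' irresponsiveness calls; relaxed enrichment and legitimacy evaluation;
#' summaries. With `out_dir` set, one TSV per stage plus `summary.json`,
#' the serialized `config.json` and a `run_log.txt` are written.
#'
#' @param counts A [reprog_counts] object.
#' @param catalog Optional `tf_catalog`; classification and response calls
#'   are restricted to its non-excluded symbols present in the matrix.
#'   `NULL` classifies every gene.
#' @param config A [reprog_config()].
#' @param out_dir Optional output directory.
#' @return List of class `reprog_run`: `norm`, `de_state`, `state`,
#'   `state_summary`, `de_grid`, `responses`, `enrichment`, `legitimacy`,
#'   `legit_summary`, `config`, `tf_genes`.
#' @export
run_reprogramome <- function(counts, catalog = NULL,
                             config = reprog_config(), out_dir = NULL) {
  stopifnot(inherits(counts, "reprog_counts"),
            inherits(config, "reprog_config"))
  stage <- "normalization"
  res <- tryCatch({
    norm <- normalize_counts(counts)

    stage <- "state contrast"
    de_state <- test_contrast(norm, config$target_group, config$start_group,
                              label = "target_vs_start")

    stage <- "state classification"
    tf_genes <- if (is.null(catalog)) rownames(norm$values) else
      intersect(active_tf_symbols(catalog), rownames(norm$values))
    if (length(tf_genes) == 0) {
      stop("no catalog symbol is present in the count matrix")
    }
    params <- state_thresholds(activity = config$activity,
                               fold = config$fold, q = config$q_strict)
    state <- classify_state(de_state, norm, config$target_group,
                            config$start_group, params = params,
                            genes = tf_genes)
    state_summary <- summarize_state(state, catalog = catalog)

    stage <- "response contrasts"
    references <- c(config$start_group, config$control_group)
    de_grid <- response_de_grid(norm, response_group = config$response_group,
                                references = references,
                                time_points = config$time_points)
    de_grid_tf <- dplyr::mutate(
      de_grid, de = purrr::map(.data$de, function(d) {
        out <- d[d$gene %in% tf_genes, ]
        attr(out, "contrast") <- attr(d, "contrast")
        class(out) <- class(d)
        out
      }))

    stage <- "response calls"
    responses <- call_responses(de_grid_tf, factors = config$factors,
                                fold = config$fold, q = config$q_strict)
    responses <- call_irresponsive(responses, state, norm,
                                   target_group = config$target_group,
                                   response_group = config$response_group,
                                   time_points = config$time_points,
                                   activity = config$activity,
                                   fold = config$fold, q = config$q_strict)

    stage <- "legitimacy"
    settings <- legitimacy_settings(q_relaxed = config$q_relaxed,
                                    over_margin_fold = config$over_margin,
                                    activity = config$activity)
    enrichment <- relaxed_enrichment(de_state, norm, config$target_group,
                                     config$start_group, genes = tf_genes,
                                     settings = settings)
    legit <- evaluate_legitimacy(responses, enrichment, norm,
                                 target_group = config$target_group,
                                 start_group = config$start_group,
                                 response_group = config$response_group,
                                 settings = settings)

    list(norm = norm, de_state = de_state, state = state,
         state_summary = state_summary, de_grid = de_grid_tf,
         responses = responses, enrichment = enrichment,
         legitimacy = legit, legit_summary = legitimacy_summary(legit),
         config = config, tf_genes = tf_genes)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(res) <- "reprog_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' Re-run a pipeline from a serialized configuration
#'
#' Reads `config.json` (as written by [run_reprogramome()]'s `out_dir`) or a
#' config list, loads the inputs it names, and repeats the run. Given the
#' same inputs the outputs are identical.
#'
#' @param config Path to a `config.json` or a `reprog_config` list.
#' @param out_dir Optional output directory for the new run.
#' @return A `reprog_run`.
#' @export
run_reprogramome_config <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg[vapply(cfg, function(x) length(x) == 0, logical(1))] <- list(NULL)
    config <- do.call(reprog_config, cfg[intersect(names(cfg),
                                                   names(formals(reprog_config)))])
  }
  stopifnot(inherits(config, "reprog_config"))
  if (is.null(config$counts_path) || is.null(config$design_path)) {
    stop("config carries no input paths; call run_reprogramome() directly",
         call. = FALSE)
  }
  counts <- read_counts(config$counts_path, config$design_path)
  catalog <- if (!is.null(config$catalog_path))
    load_tf_catalog(config$catalog_path) else NULL
  run_reprogramome(counts, catalog = catalog, config = config,
                   out_dir = out_dir)
}

#' Headline tallies of a pipeline run
#'
#' @param run A `reprog_run`.
#' @return Named list: TF universe size, per-category state counts,
#'   responsive counts, legitimacy counts and fractions.
#' @export
run_summary <- function(run) {
  sc <- run$state_summary$category_counts
  ls <- run$legit_summary
  resp <- run$responses[!run$responses$exogenous, ]
  list(
    n_tf = length(run$tf_genes),
    state_counts = stats::setNames(as.list(sc$n), as.character(sc$category)),
    upreprogramome = sum(sc$n[sc$category %in%
                                c("activatome", "upreprogramome_enriched")]),
    downreprogramome = sum(sc$n[sc$category %in%
                                  c("erasome",
                                    "downreprogramome_enriched")]),
    n_up = sum(resp$direction == "up"),
    n_down = sum(resp$direction == "down"),
    n_irresponsive = sum(resp$direction == "irresponsive"),
    n_exogenous = sum(run$responses$exogenous),
    legitimacy = ls
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  readr::write_tsv(tibble::as_tibble(run$de_state),
                   file.path(out_dir, "de_target_vs_start.tsv"))
  readr::write_tsv(tibble::as_tibble(run$state),
                   file.path(out_dir, "state_calls.tsv"))
  ev <- attr(run$responses, "evidence")
  readr::write_tsv(tibble::as_tibble(run$responses),
                   file.path(out_dir, "response_calls.tsv"))
  readr::write_tsv(ev, file.path(out_dir, "response_evidence.tsv"))
  readr::write_tsv(run$enrichment,
                   file.path(out_dir, "relaxed_enrichment.tsv"))
  readr::write_tsv(tibble::as_tibble(run$legitimacy),
                   file.path(out_dir, "legitimacy_calls.tsv"))
  lg <- log2_matrix(run$norm)
  readr::write_tsv(
    tibble::as_tibble(cbind(tibble::tibble(gene = rownames(lg)),
                            tibble::as_tibble(lg))),
    file.path(out_dir, "log2_normalized.tsv"))

  s <- run_summary(run)
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("reprogramome %s | R %s",
            as.character(utils::packageVersion("reprogramome")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %s", cfg$seed %||% "none"),
    sprintf("thresholds: activity=%s fold=%s q_strict=%s q_relaxed=%s over_margin=%s",
            cfg$activity, cfg$fold, cfg$q_strict, cfg$q_relaxed,
            cfg$over_margin),
    sprintf("groups: target=%s start=%s control=%s response=%s",
            cfg$target_group, cfg$start_group,
            cfg$control_group %||% "none", cfg$response_group)
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.reprog_run <- function(x, ...) {
  s <- run_summary(x)
  cat(sprintf("<reprog_run> %d TFs: up-reprogramome %d, down-reprogramome %d\n",
              s$n_tf, s$upreprogramome, s$downreprogramome))
  cat(sprintf("responsive: %d up, %d down, %d irresponsive (%d exogenous)\n",
              s$n_up, s$n_down, s$n_irresponsive, s$n_exogenous))
  print(s$legitimacy)
  invisible(x)
}

#' @rdname run_reprogramome
#' @param x A `reprog_run`.
#' @param ... Unused.
#' @export
tidy.reprog_run <- function(x, ...) {
  st <- tibble::as_tibble(x$state)[, c("gene", "category", "fold", "q")]
  rp <- tibble::as_tibble(x$responses)[, c("gene", "direction", "exogenous")]
  lg <- tibble::as_tibble(x$legitimacy)[, c("gene", "verdict", "subclass")]
  dplyr::left_join(dplyr::left_join(st, rp, by = "gene"), lg, by = "gene")
}

#' @rdname run_reprogramome
#' @export
glance.reprog_run <- function(x, ...) {
  s <- run_summary(x)
  tibble::tibble(
    n_tf = s$n_tf,
    upreprogramome = s$upreprogramome,
    downreprogramome = s$downreprogramome,
    n_up = s$n_up, n_down = s$n_down,
    n_irresponsive = s$n_irresponsive,
    legit_fraction_up =
      s$legitimacy$legit_fraction[s$legitimacy$direction == "up"][1],
    legit_fraction_down =
      s$legitimacy$legit_fraction[s$legitimacy$direction == "down"][1]
  )
}

#' Compare state calls from two data sets
#'
#' Intersects the strict target-enriched (upreprogramome) and start-enriched
#' (downreprogramome) sets of two runs over the same catalog. Genes unique
#' to one data set are re-tested in the other under relaxed criteria
#' (p below `p_relaxed` at any fold, mirroring the loosened cross-data-set
#' rescue rule, which deliberately uses p rather than q); genes significant
#' in opposite directions in the two data sets are flagged as conflicts.
#'
#' @param calls_a,calls_b `reprog_state` results over the same gene universe.
#' @param de_a,de_b The target-vs-start `reprog_de` tables of each run.
#' @param p_relaxed Relaxed p cutoff for the rescue (default 0.05).
#' @return List of class `reprog_compare`: per direction, tibbles `shared`,
#'   `unique_a`, `unique_b` (each unique gene with a `rescued` flag), and
#'   `conflicts`.
#' @export
compare_state_calls <- function(calls_a, calls_b, de_a, de_b,
                                p_relaxed = 0.05) {
  ua <- sort(calls_a$gene)
  ub <- sort(calls_b$gene)
  if (!identical(ua, ub)) {
    stop("state calls cover different gene universes (same catalog required)",
         call. = FALSE)
  }
  mem_a <- reprogramome_membership(calls_a)
  mem_b <- reprogramome_membership(calls_b)

  relaxed_dir <- function(de) {
    sig <- !is.na(de$p) & de$p < p_relaxed
    tibble::tibble(gene = de$gene,
                   dir = dplyr::case_when(
                     sig & de$log2fc > 0 ~ "target_higher",
                     sig & de$log2fc < 0 ~ "start_higher",
                     TRUE ~ "ns"))
  }
  rel_a <- relaxed_dir(de_a)
  rel_b <- relaxed_dir(de_b)

  one_direction <- function(col, relaxed_label) {
    set_a <- mem_a$gene[mem_a[[col]]]
    set_b <- mem_b$gene[mem_b[[col]]]
    shared <- intersect(set_a, set_b)
    uniq_a <- setdiff(set_a, set_b)
    uniq_b <- setdiff(set_b, set_a)
    rescue <- function(genes, rel_other) {
      d <- rel_other$dir[match(genes, rel_other$gene)]
      tibble::tibble(gene = genes, rescued = d == relaxed_label,
                     other_direction = d)
    }
    list(shared = tibble::tibble(gene = shared),
         unique_a = rescue(uniq_a, rel_b),
         unique_b = rescue(uniq_b, rel_a))
  }

  up <- one_direction("upreprogramome", "target_higher")
  down <- one_direction("downreprogramome", "start_higher")

  conflict_genes <- rel_a$gene[
    (rel_a$dir == "target_higher" & rel_b$dir[match(rel_a$gene,
                                                    rel_b$gene)] ==
       "start_higher") |
      (rel_a$dir == "start_higher" & rel_b$dir[match(rel_a$gene,
                                                     rel_b$gene)] ==
         "target_higher")]
  conflicts <- tibble::tibble(
    gene = conflict_genes,
    dir_a = rel_a$dir[match(conflict_genes, rel_a$gene)],
    dir_b = rel_b$dir[match(conflict_genes, rel_b$gene)])

  structure(list(up = up, down = down, conflicts = conflicts,
                 p_relaxed = p_relaxed),
            class = "reprog_compare")
}

#' @export
print.reprog_compare <- function(x, ...) {
  cat(sprintf(
    "<reprog_compare> up: %d shared, %d/%d unique-A rescued, %d/%d unique-B rescued\n",
    nrow(x$up$shared), sum(x$up$unique_a$rescued), nrow(x$up$unique_a),
    sum(x$up$unique_b$rescued), nrow(x$up$unique_b)))
  cat(sprintf(
    "               down: %d shared, %d/%d unique-A rescued, %d/%d unique-B rescued\n",
    nrow(x$down$shared), sum(x$down$unique_a$rescued), nrow(x$down$unique_a),
    sum(x$down$unique_b$rescued), nrow(x$down$unique_b)))
  cat(sprintf("conflicts: %d\n", nrow(x$conflicts)))
  invisible(x)
}
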