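#' Specification for the synthetic reprogramming data set
#'
#' Describes the simulated study: a target cell state (`ESC`), the starting
#' fibroblasts (`fibroblast_naive`), a virus-transduced control
#' (`fibroblast_GFP`) and induced samples (`OSKM`) at two response time
#' points, four replicates per group. TF genes carry a planted state class
#' and a planted response class; a background of non-TF genes with no
#' differential expression keeps normalization and the genome-wide FDR
#' realistic.
#'
#' Counts are negative binomial with variance `mu + dispersion * mu^2`;
#' per-sample library sizes are log-normal. Induced-sample means interpolate
#' in log space from the start mean toward the class's planned endpoint
#' (by default the endpoint is reached by the first time point and held).
#'
#' Response endpoints per planted class: `proper` lands on the target mean;
#' `insufficient` (planted on the erasome, where the start-target distance
#' is wide enough for a detectable move that still ends closer to the start)
#' moves `insufficient_move`-fold toward the target; `over` overshoots the
#' target by `over_move`-fold; `wrong` moves `wrong_move`-fold away from the
#' target; `unwanted` moves equally expressed or silent genes up;
#' `irresponsive` and `none` stay at the start mean.
#'
#' @param class_sizes Named integer vector of genes per planted state class.
#' @param state_fold Target-vs-start fold for the enriched classes.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param replicates Replicates per group.
#' @param libsize_sdlog Log-normal sd of per-sample library-size factors.
#' @param time_points Response time points (hours).
#' @param time_fraction Fraction of the planned log-scale move reached at
#'   each time point (same length as `time_points`).
#' @param virus_effect_fold Fold applied to the GFP control relative to the
#'   naive fibroblasts (1 = no virus effect).
#' @param inactive_mean Mean for silent genes.
#' @param active_meanlog,active_sdlog,active_floor Log-normal parameters and
#'   floor for active-gene means.
#' @param enriched_base_meanlog,enriched_base_sdlog,enriched_base_floor
#'   Parameters for the low side of enriched gene pairs.
#' @param marginal_mean_range,marginal_fold_range Ranges for the
#'   near-threshold class planted at the activity and fold boundaries.
#' @param response_plan Named list: per state class, a named numeric vector
#'   of response-class fractions (must sum to 1).
#' @param response_folds Named list with `insufficient_move`, `over_move`,
#'   `wrong_move`, `unwanted_move`, `unwanted_silent_move`.
#' @param n_background Number of non-TF background genes.
#' @param background_meanlog,background_sdlog Background mean distribution.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(class_sizes = c(activatome = 150, erasome = 150,
                                     upreprogramome_enriched = 200,
                                     downreprogramome_enriched = 200,
                                     equal_active = 250,
                                     inactive_both = 150,
                                     marginal = 50),
                     state_fold = 8,
                     dispersion = 0.05,
                     replicates = 4,
                     libsize_sdlog = 0.15,
                     time_points = c(48, 72),
                     time_fraction = c(1, 1),
                     virus_effect_fold = 1,
                     inactive_mean = 5,
                     active_meanlog = log(600), active_sdlog = 0.4,
                     active_floor = 300,
                     enriched_base_meanlog = log(150),
                     enriched_base_sdlog = 0.3,
                     enriched_base_floor = 100,
                     marginal_mean_range = c(40, 70),
                     marginal_fold_range = c(1.7, 2.3),
                     response_plan = default_response_plan(),
                     response_folds = list(insufficient_move = 4,
                                           over_move = 2.8,
                                           wrong_move = 6,
                                           wrong_floor = 60,
                                           unwanted_move = 4,
                                           unwanted_silent_move = 12),
                     plant_factors = TRUE,
                     factor_induction_fold = 50,
                     n_background = 14000,
                     background_meanlog = log(300),
                     background_sdlog = 1.5) {
  stopifnot(all(class_sizes >= 0), dispersion > 0, replicates >= 2,
            state_fold > 1, libsize_sdlog >= 0,
            length(time_fraction) == length(time_points))
  bad_plan <- names(response_plan)[
    vapply(response_plan, function(p) abs(sum(p) - 1) > 1e-8, logical(1))]
  if (length(bad_plan) > 0) {
    stop("response_plan fractions must sum to 1 for: ",
         paste(bad_plan, collapse = ", "), call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_spec")
}

#' Default response plan for the synthetic data
#'
#' Fractions of each planted state class assigned to each response class.
#' See [sim_spec()] for why `insufficient` is planted on the erasome only.
#'
#' @return Named list of named numeric vectors.
#' @export
default_response_plan <- function() {
  list(
    activatome = c(proper = 0.4, over = 0.2, irresponsive = 0.4),
    erasome = c(proper = 0.3, insufficient = 0.3, irresponsive = 0.4),
    upreprogramome_enriched = c(proper = 0.35, over = 0.15, wrong = 0.1,
                                irresponsive = 0.4),
    downreprogramome_enriched = c(proper = 0.3, over = 0.15, wrong = 0.15,
                                  irresponsive = 0.4),
    equal_active = c(unwanted = 0.15, none = 0.85),
    inactive_both = c(unwanted = 0.1, none = 0.9),
    marginal = c(none = 1)
  )
}

rlnorm_floor <- function(n, meanlog, sdlog, floor) {
  pmax(stats::rlnorm(n, meanlog, sdlog), floor)
}

# Deterministic integer split of n by fractions (largest-remainder).
split_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Simulate a reprogramming study with planted class labels
#'
#' Draws a full gene-by-sample count matrix for the groups
#' `{ESC, fibroblast_naive, fibroblast_GFP, OSKM x time points}` under a
#' [sim_spec()], together with a truth table recording every planted label.
#' Identical seeds give bit-identical output.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed.
#' @return List of class `reprog_sim`: `counts` (a [reprog_counts]), `truth`
#'   (tibble: `gene`, `is_tf`, `state_class`, `response_class`,
#'   `mean_target`, `mean_start`, `mean_oskm_end`), `catalog` (a
#'   `tf_catalog` over the TF genes), `spec`, `seed`.
#' @export
simulate_reprogramome <- function(spec = sim_spec(), seed) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(as.integer(seed), simulate_reprogramome_impl(spec, seed))
}

simulate_reprogramome_impl <- function(spec, seed) {
  cs <- spec$class_sizes
  n_tf <- sum(cs)
  tf_genes <- sprintf("TF%04d", seq_len(n_tf))
  state_class <- rep(names(cs), cs)

  response_class <- character(n_tf)
  for (k in names(cs)) {
    idx <- which(state_class == k)
    plan <- spec$response_plan[[k]] %||% c(none = 1)
    nsub <- split_counts(length(idx), plan)
    response_class[idx] <- rep(names(nsub), nsub)
  }

  mt <- ms <- numeric(n_tf)
  for (k in names(cs)) {
    idx <- which(state_class == k)
    nk <- length(idx)
    if (nk == 0) next
    if (k == "activatome") {
      mt[idx] <- rlnorm_floor(nk, spec$active_meanlog, spec$active_sdlog,
                              spec$active_floor)
      ms[idx] <- spec$inactive_mean
    } else if (k == "erasome") {
      ms[idx] <- rlnorm_floor(nk, spec$active_meanlog, spec$active_sdlog,
                              spec$active_floor)
      mt[idx] <- spec$inactive_mean
    } else if (k == "upreprogramome_enriched") {
      base <- rlnorm_floor(nk, spec$enriched_base_meanlog,
                           spec$enriched_base_sdlog, spec$enriched_base_floor)
      # wrong-planted genes here get a wrong-direction (silencing) move;
      # a higher start level keeps that move detectable and above the
      # activity threshold, so the planted label matches the rule outcome
      wr <- response_class[idx] == "wrong"
      base[wr] <- rlnorm_floor(sum(wr), log(500), spec$enriched_base_sdlog,
                               400)
      ms[idx] <- base
      mt[idx] <- base * spec$state_fold
    } else if (k == "downreprogramome_enriched") {
      base <- rlnorm_floor(nk, spec$enriched_base_meanlog,
                           spec$enriched_base_sdlog, spec$enriched_base_floor)
      mt[idx] <- base
      ms[idx] <- base * spec$state_fold
    } else if (k == "equal_active") {
      m <- rlnorm_floor(nk, spec$active_meanlog, spec$active_sdlog,
                        spec$active_floor)
      mt[idx] <- m
      ms[idx] <- m
    } else if (k == "inactive_both") {
      mt[idx] <- spec$inactive_mean
      ms[idx] <- spec$inactive_mean
    } else if (k == "marginal") {
      m <- stats::runif(nk, spec$marginal_mean_range[1],
                        spec$marginal_mean_range[2])
      f <- stats::runif(nk, spec$marginal_fold_range[1],
                        spec$marginal_fold_range[2])
      up <- seq_len(nk) %% 2 == 0
      mt[idx] <- ifelse(up, m * f, m)
      ms[idx] <- ifelse(up, m, m * f)
    } else {
      stop("unknown planted class: ", k, call. = FALSE)
    }
  }

  rf <- spec$response_folds
  toward_target <- sign(log(mt / ms))
  mend <- ms
  move <- function(m, log_step) m * exp(log_step)
  for (i in seq_len(n_tf)) {
    mend[i] <- switch(
      response_class[i],
      none = ,
      irresponsive = ms[i],
      proper = mt[i],
      insufficient = move(ms[i], toward_target[i] * log(rf$insufficient_move)),
      over = move(mt[i], toward_target[i] * log(rf$over_move)),
      # wrong-direction down-moves stay above the activity threshold so the
      # planted label matches the rule semantics (a silenced target-enriched
      # gene would rightly be re-called irresponsive by the inactivity rule)
      wrong = if (toward_target[i] > 0)
        max(ms[i] / rf$wrong_move, rf$wrong_floor) else
          ms[i] * rf$wrong_move,
      unwanted = if (state_class[i] == "inactive_both")
        ms[i] * rf$unwanted_silent_move else ms[i] * rf$unwanted_move,
      stop("unknown response class: ", response_class[i], call. = FALSE)
    )
  }

  if (isTRUE(spec$plant_factors)) {
    # the four delivered reprogramming factors: massive apparent induction
    # from the transgenes; flagged exogenous downstream
    fg <- oskm_factors()
    f_mt <- c(600, 600, 400, 400)
    f_ms <- c(spec$inactive_mean, spec$inactive_mean, 400, 400)
    f_state <- c("activatome", "activatome", "equal_active", "equal_active")
    tf_genes <- c(tf_genes, fg)
    state_class <- c(state_class, f_state)
    response_class <- c(response_class, rep("exogenous", 4))
    mt <- c(mt, f_mt)
    ms <- c(ms, f_ms)
    mend <- c(mend, f_ms * spec$factor_induction_fold)
    n_tf <- n_tf + 4L
  }

  bg_genes <- sprintf("BG%04d", seq_len(spec$n_background))
  bg_mean <- pmax(stats::rlnorm(spec$n_background, spec$background_meanlog,
                                spec$background_sdlog), 0.5)

  genes <- c(tf_genes, bg_genes)
  mean_target <- c(mt, bg_mean)
  mean_start <- c(ms, bg_mean)
  mean_end <- c(mend, bg_mean)

  groups <- list(
    list(group = "ESC", time_h = NA_real_, mean = mean_target),
    list(group = "fibroblast_naive", time_h = NA_real_, mean = mean_start),
    list(group = "fibroblast_GFP", time_h = NA_real_,
         mean = mean_start * spec$virus_effect_fold)
  )
  for (j in seq_along(spec$time_points)) {
    frac <- spec$time_fraction[j]
    mu <- mean_start * exp(frac * log(mean_end / mean_start))
    groups <- c(groups, list(list(group = "OSKM",
                                  time_h = spec$time_points[j], mean = mu)))
  }

  n_samples <- length(groups) * spec$replicates
  lib <- stats::rlnorm(n_samples, 0, spec$libsize_sdlog)
  counts <- matrix(0, nrow = length(genes), ncol = n_samples,
                   dimnames = list(genes, rep("", n_samples)))
  design <- vector("list", length(groups) * spec$replicates)
  s <- 0L
  size <- 1 / spec$dispersion
  for (gr in groups) {
    for (r in seq_len(spec$replicates)) {
      s <- s + 1L
      mu <- gr$mean * lib[s]
      counts[, s] <- if (spec$dispersion < 1e-12) stats::rpois(length(mu), mu)
        else stats::rnbinom(length(mu), mu = mu, size = size)
      id <- if (is.na(gr$time_h)) sprintf("%s_%d", gr$group, r)
        else sprintf("%s_%sh_%d", gr$group, format(gr$time_h), r)
      colnames(counts)[s] <- id
      design[[s]] <- tibble::tibble(sample = id, group = gr$group,
                                    time_h = gr$time_h, replicate = r)
    }
  }

  truth <- tibble::tibble(
    gene = genes,
    is_tf = genes %in% tf_genes,
    state_class = c(state_class, rep(NA_character_, length(bg_genes))),
    response_class = c(response_class, rep(NA_character_, length(bg_genes))),
    mean_target = mean_target,
    mean_start = mean_start,
    mean_oskm_end = mean_end
  )

  fams <- rep(tf_family_levels(), length.out = n_tf)
  catalog <- load_tf_catalog(tibble::tibble(symbol = tf_genes, family = fams),
                             remap = character(0), exclude = character(0))

  structure(list(counts = reprog_counts(counts, dplyr::bind_rows(design)),
                 truth = truth, catalog = catalog,
                 spec = spec, seed = as.integer(seed)),
            class = "reprog_sim")
}

#' @export
print.reprog_sim <- function(x, ...) {
  cat(sprintf("<reprog_sim> seed %d: %d genes (%d TF) x %d samples\n",
              x$seed, nrow(x$counts$counts), sum(x$truth$is_tf),
              ncol(x$counts$counts)))
  invisible(x)
}

#' Write a simulated data set to TSV files
#'
#' @param sim A [simulate_reprogramome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `counts.tsv`, `design.tsv`, `truth.tsv`.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"),
               file.path(dir, "design.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

# Observed per-gene outcome label combining response direction and
# legitimacy verdict/subclass, comparable to planted response classes.
observed_response_label <- function(responses, legitimacy) {
  lab <- dplyr::case_when(
    responses$exogenous ~ "exogenous",
    responses$direction == "irresponsive" ~ "irresponsive",
    responses$direction == "unclassified" ~ "none",
    TRUE ~ NA_character_
  )
  idx <- match(responses$gene, legitimacy$gene)
  hit <- !is.na(idx)
  lab[hit] <- ifelse(legitimacy$verdict[idx[hit]] == "legitimate",
                     legitimacy$subclass[idx[hit]],
                     legitimacy$verdict[idx[hit]])
  lab
}

#' Confusion matrices of planted versus recovered classes
#'
#' Compares the simulator's truth table with pipeline outputs. State rows
#' sum to the planted class sizes; response rows to the planted response
#' plan.
#'
#' @param truth The `truth` tibble of a [simulate_reprogramome()] result.
#' @param state_calls Optional [classify_state()] result on the TF genes.
#' @param responses Optional [call_responses()]/[call_irresponsive()] result.
#' @param legitimacy Optional [evaluate_legitimacy()] result.
#' @return List of class `reprog_recovery` with tibbles `state` and
#'   `response` (`planted`, `called`, `n`).
#' @export
recovery_report <- function(truth, state_calls = NULL, responses = NULL,
                            legitimacy = NULL) {
  tf <- truth[truth$is_tf, ]
  out <- list(state = NULL, response = NULL)

  if (!is.null(state_calls)) {
    missing <- setdiff(tf$gene, state_calls$gene)
    if (length(missing) > 0) {
      stop("truth genes absent from state calls: ",
           paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
    }
    called <- as.character(
      state_calls$category[match(tf$gene, state_calls$gene)])
    out$state <- dplyr::count(
      tibble::tibble(planted = tf$state_class, called = called),
      .data$planted, .data$called)
  }

  if (!is.null(responses)) {
    missing <- setdiff(tf$gene, responses$gene)
    if (length(missing) > 0) {
      stop("truth genes absent from response calls: ",
           paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
    }
    obs <- observed_response_label(
      responses,
      legitimacy %||% tibble::tibble(gene = character(), verdict = character(),
                                     subclass = character()))
    called <- obs[match(tf$gene, responses$gene)]
    out$response <- dplyr::count(
      tibble::tibble(planted = tf$response_class, called = called),
      .data$planted, .data$called)
  }

  structure(out, class = "reprog_recovery")
}

#' Per-class recovery rates from a confusion report
#'
#' @param report A [recovery_report()] result.
#' @return Tibble: `domain` (`state`/`response`), `planted`, `n`,
#'   `recovered`, `rate`.
#' @export
recovery_rates <- function(report) {
  one <- function(tab, domain) {
    if (is.null(tab)) return(NULL)
    dplyr::summarise(
      dplyr::group_by(tab, planted = .data$planted),
      recovered = sum(.data$n[.data$called == .data$planted]),
      n = sum(.data$n),
      .groups = "drop") |>
      dplyr::mutate(rate = .data$recovered / .data$n, domain = domain) |>
      dplyr::select("domain", "planted", "n", "recovered", "rate")
  }
  dplyr::bind_rows(one(report$state, "state"), one(report$response, "response"))
}

#' @export
print.reprog_recovery <- function(x, ...) {
  cat("<reprog_recovery>\n")
  print(recovery_rates(x), n = Inf)
  invisible(x)
}
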