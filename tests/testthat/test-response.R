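`%||%` <- rlang::`%||%`

# A hand-built contrast grid over two references and two time points.
# Fold/q values per gene are identical across contrasts unless overridden.
toy_grid <- function(genes, fold, q, overrides = list()) {
  grid <- tidyr::expand_grid(reference = c("naive", "gfp"),
                             time_h = c(48, 72))
  grid$de <- purrr::pmap(grid, function(reference, time_h) {
    f <- fold; qq <- q
    key <- paste(reference, time_h, sep = "_")
    if (!is.null(overrides[[key]])) {
      f <- overrides[[key]]$fold %||% f
      qq <- overrides[[key]]$q %||% qq
    }
    toy_de(genes, mean_a = 100 * f, mean_b = 100, q = qq,
           label = key)
  })
  class(grid) <- c("reprog_de_grid", class(grid))
  grid
}

test_that("a response requires every reference and time point to agree", {
  genes <- c("up4", "viral", "flat", "down4", "POU5F1")
  grid <- toy_grid(genes,
                   fold = c(4, 4, 1.1, 0.25, 50),
                   q = c(1e-6, 1e-6, 0.8, 1e-6, 1e-9),
                   overrides = list(
                     gfp_48 = list(fold = c(4, 1.3, 1.1, 0.25, 50)),
                     gfp_72 = list(fold = c(4, 1.3, 1.1, 0.25, 50))))
  calls <- call_responses(grid)
  got <- setNames(calls$direction, calls$gene)
  expect_equal(got[["up4"]], "up")
  expect_equal(got[["down4"]], "down")
  # virus-per-se effect: up versus naive only, flat versus the GFP control
  expect_equal(got[["viral"]], "unclassified")
  expect_equal(got[["flat"]], "unclassified")
  # delivered factors are flagged exogenous, not counted as responsive
  expect_true(calls$exogenous[calls$gene == "POU5F1"])
  expect_false(any(calls$exogenous[calls$gene != "POU5F1"]))

  g <- glance(calls)
  expect_equal(g$n_up, 1)
  expect_equal(g$n_down, 1)
  expect_equal(g$n_exogenous, 1)
})

test_that("boundary folds and significance act conjunctively", {
  genes <- c("edge", "sig_weak", "strong_nsig")
  grid <- toy_grid(genes,
                   fold = c(2, 1.9, 4),
                   q = c(0.009, 0.001, 0.02))
  calls <- call_responses(grid)
  got <- setNames(calls$direction, calls$gene)
  expect_equal(got[["edge"]], "up")            # fold exactly 2 counts
  expect_equal(got[["sig_weak"]], "unclassified")
  expect_equal(got[["strong_nsig"]], "unclassified")
})

test_that("no gene is both up and down; exogenous never responsive", {
  run <- default_run()
  resp <- run$responses
  expect_true(all(resp$direction %in%
                    c("up", "down", "irresponsive", "unclassified")))
  expect_false(any(resp$exogenous &
                     resp$direction %in% c("up", "down") &
                     !resp$gene %in% oskm_factors()))
  g <- glance(resp)
  expect_equal(g$n_up + g$n_down + g$n_irresponsive +
                 sum(resp$direction == "unclassified" & !resp$exogenous) +
                 g$n_exogenous, nrow(resp))
})

# Rule tests need exact normalized values for the induced and target groups.
irresponsive_fixture <- function() {
  # columns: T(3) S(3) O48(3) O72(3); values are normalized counts
  vals <- rbind(
    # upreprogramome gene still silent after induction (rule 4) even though
    # its fold change is large and significant
    rule4 = c(800, 820, 790, 10, 12, 11, 35, 40, 38, 36, 42, 39),
    # downreprogramome gene with a small but significant change (rule 2)
    rule2 = c(20, 22, 19, 400, 410, 390, 270, 265, 275, 268, 272, 266),
    # quiet reprogramome gene still far from the target: irresponsive
    quiet = c(900, 880, 920, 100, 95, 105, 108, 112, 110, 109, 111, 107),
    # quiet gene whose distance to the target has collapsed (rule 3)
    near  = c(150, 155, 145, 100, 95, 105, 110, 108, 112, 109, 111, 110)
  )
  colnames(vals) <- c(paste0("T", 1:3), paste0("S", 1:3),
                      paste0("O48_", 1:3), paste0("O72_", 1:3))
  norm <- toy_norm(vals,
                   groups = c(rep("T", 3), rep("S", 3), rep("O", 6)),
                   time_h = c(rep(NA, 6), rep(48, 3), rep(72, 3)))
  genes <- rownames(vals)
  state <- toy_state(genes, c("upreprogramome_enriched",
                              "downreprogramome_enriched",
                              "upreprogramome_enriched",
                              "upreprogramome_enriched"))
  # per-contrast evidence: folds are OSKM over the start reference
  mk <- function(fold, q) toy_de(genes, 100 * fold, 100, q = q)
  grid <- tidyr::expand_grid(reference = "S", time_h = c(48, 72))
  grid$de <- list(mk(c(3.8, 0.67, 1.1, 1.1), c(1e-7, 0.002, 0.8, 0.8)),
                  mk(c(3.9, 0.67, 1.1, 1.1), c(1e-7, 0.003, 0.7, 0.7)))
  class(grid) <- c("reprog_de_grid", class(grid))
  list(norm = norm, state = state, grid = grid)
}

test_that("the irresponsiveness rules apply in the stated order", {
  fx <- irresponsive_fixture()
  calls <- call_responses(fx$grid, factors = character(0))
  calls <- call_irresponsive(calls, fx$state, fx$norm,
                             target_group = "T", response_group = "O")
  got <- setNames(calls$direction, calls$gene)

  # rule 4 overrides: fold 3.8, q < 0.01, but induced counts all < 50
  expect_equal(got[["rule4"]], "irresponsive")
  # rule 2: 1.5-fold change but significant, removed from irresponsive
  expect_equal(got[["rule2"]], "unclassified")
  # rules 1-3 all hold: small fold, never significant, still >= 2-fold away
  expect_equal(got[["quiet"]], "irresponsive")
  # rule 3: within 2-fold of the target state, excluded
  expect_equal(got[["near"]], "unclassified")
})

test_that("irresponsive downreprogramome genes stay target-distant", {
  run <- default_run()
  resp <- run$responses
  down_irr <- resp$direction == "irresponsive" &
    !is.na(resp$reprogramome_side) & resp$reprogramome_side == "down"
  expect_gt(sum(down_irr), 0)
  expect_true(all(resp$min_target_fold[down_irr] >= 2))
})

test_that("planted irresponsive genes are recovered at high fidelity", {
  sim <- default_sim()
  run <- default_run()
  rr <- recovery_rates(recovery_report(sim$truth, state_calls = run$state,
                                       responses = run$responses,
                                       legitimacy = run$legitimacy))
  irr <- rr[rr$domain == "response" & rr$planted == "irresponsive", ]
  expect_gte(irr$rate, 0.99)
})

test_that("a missing contrast is reported by name", {
  genes <- c("a", "b")
  grid <- toy_grid(genes, fold = c(2, 2), q = c(0.001, 0.001))
  # drop one gene from one contrast
  grid$de[[2]] <- grid$de[[2]][grid$de[[2]]$gene != "b", ]
  expect_error(call_responses(grid), "b")
})
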