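test_that("the verdict table is total and matches the classification logic", {
  dirs <- c("up", "down")
  enr <- c("target_higher", "start_higher", "equal", "silent_both")
  combos <- expand.grid(direction = dirs, enrichment = enr,
                        stringsAsFactors = FALSE)
  v <- legitimacy_verdict(combos$direction, combos$enrichment)
  expect_length(v, 8)
  expect_true(all(v %in% c("legitimate", "wrong", "unwanted")))

  expect_equal(legitimacy_verdict("up", "target_higher"), "legitimate")
  expect_equal(legitimacy_verdict("up", "start_higher"), "wrong")
  expect_equal(legitimacy_verdict("up", "silent_both"), "unwanted")
  expect_equal(legitimacy_verdict("up", "equal"), "unwanted")
  expect_equal(legitimacy_verdict("down", "start_higher"), "legitimate")
  expect_equal(legitimacy_verdict("down", "target_higher"), "wrong")
  expect_equal(legitimacy_verdict("down", "equal"), "unwanted")
  expect_error(legitimacy_verdict("sideways", "equal"))
})

test_that("relaxed enrichment labels follow significance then activity", {
  vals <- rbind(
    sh = c(100, 95, 105, 150, 145, 140),  # modestly start-enriched, q 0.03
    eq = c(300, 310, 290, 280, 305, 300), # active both, q 0.5
    sb = c(10, 12, 9, 20, 22, 18)         # silent both
  )
  colnames(vals) <- paste0("s", 1:6)
  norm <- toy_norm(vals, rep(c("T", "S"), each = 3))
  de <- toy_de(rownames(vals),
               mean_a = c(100, 295, 13), mean_b = c(146, 293, 20),
               q = c(0.03, 0.5, 0.4))
  enr <- relaxed_enrichment(de, norm, "T", "S")
  got <- setNames(enr$enrichment, enr$gene)
  expect_equal(got[["sh"]], "start_higher")   # 1.46-fold, q < 0.05
  expect_equal(got[["eq"]], "equal")
  expect_equal(got[["sb"]], "silent_both")

  expect_error(relaxed_enrichment(de, norm, "T", "S", genes = "missing"),
               "missing")
})

test_that("strict state enrichment is a subset of relaxed enrichment", {
  run <- default_run()
  enr <- setNames(run$enrichment$enrichment, run$enrichment$gene)
  cat <- setNames(as.character(run$state$category), run$state$gene)
  up_strict <- names(cat)[cat %in% c("activatome",
                                     "upreprogramome_enriched")]
  down_strict <- names(cat)[cat %in% c("erasome",
                                       "downreprogramome_enriched")]
  expect_true(all(enr[up_strict] == "target_higher"))
  expect_true(all(enr[down_strict] == "start_higher"))
})

test_that("legitimacy verdicts and distance subclasses on hand-built genes", {
  # 12 samples: T(3) S(3) O(6); distances engineered via exact values
  vals <- rbind(
    proper_up  = c(800, 810, 790, 100, 95, 105, 780, 820, 800, 790, 805, 810),
    insuff_dn  = c(5, 6, 4, 400, 410, 390, 95, 105, 100, 98, 102, 99),
    over_up    = c(400, 410, 390, 50, 45, 55, 1700, 1680, 1720, 1690, 1705, 1695),
    wrong_up   = c(100, 95, 105, 400, 390, 410, 1300, 1280, 1320, 1290, 1310, 1300),
    unwanted_up = c(300, 310, 290, 295, 305, 300, 1250, 1230, 1270, 1240, 1255, 1260),
    silent_up  = c(10, 12, 9, 11, 13, 10, 90, 95, 85, 92, 88, 91)
  )
  colnames(vals) <- c(paste0("T", 1:3), paste0("S", 1:3), paste0("O", 1:6))
  norm <- toy_norm(vals, c(rep("T", 3), rep("S", 3), rep("O", 6)),
                   time_h = c(rep(NA, 6), rep(48, 6)))
  genes <- rownames(vals)
  de_ts <- toy_de(genes,
                  mean_a = rowMeans(vals[, 1:3]),
                  mean_b = rowMeans(vals[, 4:6]),
                  q = c(1e-8, 1e-8, 1e-8, 1e-6, 0.6, 0.5))
  enr <- relaxed_enrichment(de_ts, norm, "T", "S")

  responses <- tibble::tibble(
    gene = genes,
    direction = c("up", "down", "up", "up", "up", "up"),
    exogenous = FALSE)
  class(responses) <- c("reprog_response", class(responses))

  calls <- evaluate_legitimacy(responses, enr, norm,
                               target_group = "T", start_group = "S",
                               response_group = "O")
  got <- calls[match(genes, calls$gene), ]
  expect_equal(got$verdict,
               c("legitimate", "legitimate", "legitimate", "wrong",
                 "unwanted", "unwanted"))
  expect_equal(got$subclass,
               c("proper", "insufficient", "over", "none", "none", "none"))
  expect_equal(got$enrichment[4], "start_higher")
  expect_equal(got$enrichment[6], "silent_both")
  # distances: the proper gene ends next to the target profile
  expect_lt(got$d_target[1], 0.1)
  expect_gt(got$d_start[1], 2.5)
})

test_that("subclasses partition the legitimate calls on every run", {
  run <- default_run()
  lg <- run$legitimacy
  expect_true(all(lg$subclass[lg$verdict == "legitimate"] %in%
                    c("proper", "insufficient", "over")))
  expect_true(all(lg$subclass[lg$verdict != "legitimate"] == "none"))
  s <- legitimacy_summary(lg)
  expect_equal(s$proper + s$insufficient + s$over, s$legitimate)
  expect_equal(s$legitimate + s$wrong + s$unwanted, s$n)
})

test_that("summary fractions match printed-count arithmetic", {
  mk <- function(direction, verdict, n) {
    tibble::tibble(gene = sprintf("%s%03d", substr(verdict, 1, 2) , seq_len(n)),
                   direction = direction, enrichment = "equal",
                   verdict = verdict, subclass = "none",
                   d_target = 0, d_start = 0)
  }
  # 56 legitimate of 70 downregulated: 80.0%
  down <- dplyr::bind_rows(mk("down", "legitimate", 56),
                           mk("down", "wrong", 9), mk("down", "unwanted", 5))
  down$gene <- paste0(down$gene, seq_len(70))
  class(down) <- c("reprog_legit", class(down))
  s <- legitimacy_summary(down)
  expect_equal(s$legit_fraction, 56 / 70)
  expect_equal(round(100 * s$legit_fraction, 1), 80.0)

  # 129 legitimate of 219 upregulated: 58.9% to one decimal
  up <- dplyr::bind_rows(mk("up", "legitimate", 129),
                         mk("up", "wrong", 60), mk("up", "unwanted", 30))
  up$gene <- paste0(up$gene, seq_len(219))
  class(up) <- c("reprog_legit", class(up))
  expect_equal(round(100 * legitimacy_summary(up)$legit_fraction, 1), 58.9)

  # no responsive genes: empty summary, NA-safe glance
  empty <- down[0, ]
  class(empty) <- c("reprog_legit", class(empty))
  expect_equal(nrow(legitimacy_summary(empty)), 0)
  g <- glance(empty)
  expect_true(is.na(g$legit_fraction_up))
})

test_that("planted legitimacy subclasses recover at the stated fidelity", {
  sim <- default_sim()
  run <- default_run()
  rr <- recovery_rates(recovery_report(sim$truth, state_calls = run$state,
                                       responses = run$responses,
                                       legitimacy = run$legitimacy))
  rr <- rr[rr$domain == "response", ]
  for (cls in c("proper", "insufficient", "over")) {
    expect_gte(rr$rate[rr$planted == cls], 0.95)
  }
})
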