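# Shared fixtures, all built in code.

# Tiny count container: genes x samples with a two-group design.
toy_counts <- function(counts, groups, time_h = NULL) {
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  design <- tibble::tibble(sample = colnames(counts), group = groups)
  if (!is.null(time_h)) design$time_h <- time_h
  reprog_counts(counts, design)
}

# A reprog_norm built directly from known normalized values (factors 1),
# for rule tests that need exact replicate values.
toy_norm <- function(values, groups, time_h = NULL) {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  design <- tibble::tibble(sample = colnames(values), group = groups,
                           time_h = if (is.null(time_h))
                             NA_real_ else time_h,
                           replicate = seq_len(ncol(values)))
  structure(list(values = values,
                 size_factors = stats::setNames(rep(1, ncol(values)),
                                                colnames(values)),
                 design = design),
            class = "reprog_norm")
}

# A reprog_de built from explicit per-gene numbers.
toy_de <- function(gene, mean_a, mean_b, q, p = q, label = "toy") {
  out <- tibble::tibble(gene = gene, mean_a = mean_a, mean_b = mean_b,
                        log2fc = log2((mean_a + 0.5 * (mean_a == 0 |
                                                         mean_b == 0)) /
                                      (mean_b + 0.5 * (mean_a == 0 |
                                                         mean_b == 0))),
                        p = p, q = q)
  attr(out, "contrast") <- list(label = label)
  class(out) <- c("reprog_de", class(out))
  out
}

# A reprog_state table from explicit categories.
toy_state <- function(gene, category) {
  out <- tibble::tibble(gene = gene,
                        category = factor(category,
                                          levels = state_categories()),
                        active_in_target = NA, active_in_start = NA,
                        fold = NA_real_, q = NA_real_)
  class(out) <- c("reprog_state", class(out))
  out
}

# Small-but-complete simulated study reused across tests (cached).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_reprogramome(sim_spec(), seed = 7)
    cache
  }
})

default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- default_sim()
      cache <<- run_reprogramome(sim$counts, catalog = sim$catalog)
    }
    cache
  }
})

# Brute-force Benjamini-Hochberg step-up oracle, from the definition:
# the adjusted value of p_i is the smallest p_(j) * n / j over all sorted
# positions j at or after p_i's position, capped at 1. Deliberately written
# as explicit loops, independent of any vectorized implementation.
bh_oracle <- function(p) {
  n <- length(p)
  ps <- sort(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- 1
    for (j in seq_len(n)) {
      if (ps[j] >= p[i]) best <- min(best, ps[j] * n / j)
    }
    q[i] <- best
  }
  q
}
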