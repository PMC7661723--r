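#' Default symbol remapping for transcription-factor catalogs
#'
#' Alias corrections applied when a catalog is loaded: some widely circulated
#' TF lists carry symbols that differ from the current official gene symbols
#' (e.g. the historical symbol `T` for brachyury, now `TBXT`). Each name is
#' the symbol as found in the raw list, each value the official replacement.
#'
#' @return Named character vector mapping raw symbols to official symbols.
#' @export
#' @examples
#' default_symbol_remap()
default_symbol_remap <- function() {
  c(
    ZNF645 = "CBLL2",
    T      = "TBXT",
    ZUFSP  = "ZUP1",
    ZZZ3   = "AC118549.1"
  )
}

#' Default catalog exclusions
#'
#' Entries removed from analysis (but retained in the catalog with a reason):
#' pseudogenes and genes without an annotation in current genome builds.
#'
#' @return Named character vector; names are symbols, values the reason.
#' @export
default_symbol_exclusions <- function() {
  c(
    ZNF788 = "pseudogene",
    DUX1   = "not annotated",
    DUX3   = "not annotated"
  )
}

#' Controlled vocabulary of TF family labels
#' @return Character vector of family labels used by the catalog.
#' @export
tf_family_levels <- function() {
  c("zinc finger", "HOX", "forkhead", "T-box", "SOX", "POU", "SALL", "other")
}

# Prefix heuristic for family assignment; specific named families win over
# the broad zinc-finger designation so that SALL4 counts as "SALL" here while
# zinc_finger_symbols() still tallies it among zinc-finger designations.
infer_tf_family <- function(symbols) {
  dplyr::case_when(
    stringr::str_starts(symbols, "HOX") ~ "HOX",
    stringr::str_starts(symbols, "FOX") ~ "forkhead",
    stringr::str_starts(symbols, "TBX") ~ "T-box",
    stringr::str_starts(symbols, "SOX") ~ "SOX",
    stringr::str_starts(symbols, "POU") ~ "POU",
    stringr::str_starts(symbols, "SALL") ~ "SALL",
    stringr::str_starts(symbols, "ZNF") |
      stringr::str_starts(symbols, "ZFP") |
      stringr::str_starts(symbols, "ZIC") |
      stringr::str_starts(symbols, "ZSCAN") |
      stringr::str_starts(symbols, "GATA") |
      stringr::str_starts(symbols, "KLF") |
      stringr::str_starts(symbols, "ZBTB") ~ "zinc finger",
    TRUE ~ "other"
  )
}

#' Symbols counted under the zinc-finger designation
#'
#' The broad zinc-finger tally groups genes by symbol designation
#' (ZNF, ZFP, ZIC, ZSCAN, GATA, KLF, SALL, ZBTB), independently of the
#' specific family label a gene carries in the catalog.
#'
#' @param symbols Character vector of gene symbols.
#' @return Logical vector: does each symbol carry a zinc-finger designation?
#' @export
zinc_finger_symbols <- function(symbols) {
  stringr::str_starts(
    symbols,
    stringr::regex("ZNF|ZFP|ZIC|ZSCAN|GATA|KLF|SALL|ZBTB")
  )
}

#' Load and curate a transcription-factor catalog
#'
#' Reads a delimited catalog (or takes a data frame), applies symbol
#' remapping and exclusion rules, and assigns a family label to every entry.
#' Excluded entries are retained with their reason so that the raw entry
#' count is always `sum(!excluded) + sum(excluded)`.
#'
#' @param x Path to a headered TSV/CSV with at least a `symbol` column
#'   (optional `family` and `aliases` columns), or a data frame with those
#'   columns.
#' @param remap Named character vector mapping raw symbols to official
#'   symbols; defaults to [default_symbol_remap()].
#' @param exclude Named character vector of symbols to flag as excluded, with
#'   the reason as value; defaults to [default_symbol_exclusions()].
#' @return A tibble of class `tf_catalog` with columns `symbol`, `family`,
#'   `aliases`, `excluded`, `exclusion_reason`.
#' @export
#' @examples
#' cat <- load_tf_catalog(tibble::tibble(symbol = c("T", "ZUFSP", "FOXA1")))
#' cat$symbol # TBXT, ZUP1, FOXA1
load_tf_catalog <- function(x,
                            remap = default_symbol_remap(),
                            exclude = default_symbol_exclusions()) {
  raw <- if (is.character(x) && length(x) == 1L) read_delim_auto(x) else
    tibble::as_tibble(x)
  if (!"symbol" %in% names(raw)) {
    stop("catalog has no 'symbol' column; found: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
  raw$symbol <- as.character(raw$symbol)

  mapped <- ifelse(raw$symbol %in% names(remap),
                   unname(remap[raw$symbol]), raw$symbol)
  alias  <- ifelse(mapped != raw$symbol, raw$symbol, NA_character_)

  dup <- unique(mapped[duplicated(mapped)])
  if (length(dup) > 0) {
    stop("duplicate symbols after remapping: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  fam <- if ("family" %in% names(raw) && !all(is.na(raw$family))) {
    fam0 <- as.character(raw$family)
    ifelse(is.na(fam0) | fam0 == "", infer_tf_family(mapped), fam0)
  } else {
    infer_tf_family(mapped)
  }

  aliases <- if ("aliases" %in% names(raw)) {
    a0 <- as.character(raw$aliases)
    a0[is.na(a0)] <- ""
    ifelse(is.na(alias), a0,
           ifelse(a0 == "", alias, paste(a0, alias, sep = ";")))
  } else {
    ifelse(is.na(alias), "", alias)
  }

  out <- tibble::tibble(
    symbol = mapped,
    family = fam,
    aliases = aliases,
    excluded = mapped %in% names(exclude) | raw$symbol %in% names(exclude),
    exclusion_reason = NA_character_
  )
  keys <- ifelse(out$symbol %in% names(exclude), out$symbol, raw$symbol)
  out$exclusion_reason[out$excluded] <- unname(exclude[keys[out$excluded]])
  class(out) <- c("tf_catalog", class(out))
  out
}

#' Write a curated catalog back to TSV
#'
#' Round-trips with [load_tf_catalog()]: loading the written file with an
#' empty remap and the same exclusions reproduces the catalog.
#'
#' @param catalog A `tf_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tf_catalog <- function(catalog, path) {
  readr::write_tsv(tibble::as_tibble(catalog), path)
  invisible(path)
}

#' Active (non-excluded) catalog entries
#' @param catalog A `tf_catalog`.
#' @return Tibble of entries with `excluded == FALSE`.
#' @export
active_tf_symbols <- function(catalog) {
  catalog$symbol[!catalog$excluded]
}

#' Count catalog families within a gene set
#'
#' Tallies how many genes of a set belong to each TF family. Every gene must
#' be present in the catalog; genes whose family is not in the controlled
#' vocabulary are counted under "other". Counts always sum to the size of
#' the gene set.
#'
#' @param catalog A `tf_catalog`.
#' @param gene_set Character vector of symbols (all present in the catalog).
#' @return Tibble with columns `family`, `n`, sorted by descending `n`.
#' @export
family_counts <- function(catalog, gene_set) {
  gene_set <- as.character(gene_set)
  if (length(gene_set) == 0) {
    return(tibble::tibble(family = character(), n = integer()))
  }
  missing <- setdiff(gene_set, catalog$symbol)
  if (length(missing) > 0) {
    stop("symbols absent from catalog: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fam <- catalog$family[match(gene_set, catalog$symbol)]
  fam[!fam %in% tf_family_levels()] <- "other"
  dplyr::arrange(dplyr::count(tibble::tibble(family = fam), family),
                 dplyr::desc(n))
}

#' Fraction of a gene set carrying a zinc-finger designation
#'
#' @param gene_set Character vector of symbols.
#' @return List with `n` (zinc-finger count) and `fraction`.
#' @export
zinc_finger_fraction <- function(gene_set) {
  zf <- sum(zinc_finger_symbols(gene_set))
  list(n = zf,
       fraction = if (length(gene_set) > 0) zf / length(gene_set) else NA_real_)
}

#' Synthetic stand-in for a genome-wide TF catalog
#'
#' Builds a deterministic catalog of `n` invented entries shaped like the
#' curated human TF repertoire: it contains the handful of symbols the
#' default curation rules act on (`ZNF645`, `T`, `ZUFSP`, `ZZZ3`, `ZNF788`,
#' `DUX1`, `DUX3`), a core of well-known pluripotency and fibroblast TFs,
#' and filler symbols drawn from the major family designations. It is a
#' synthetic object for testing curation and tallying logic; it is not the
#' published TF list and its family labels are heuristic.
#'
#' @param n Number of raw entries (default 1639).
#' @return Tibble with a `symbol` column, suitable for [load_tf_catalog()].
#' @export
synthetic_tf_catalog <- function(n = 1639) {
  special <- c("ZNF645", "T", "ZUFSP", "ZZZ3", "ZNF788", "DUX1", "DUX3")
  core <- c("POU5F1", "SOX2", "KLF4", "MYC", "NANOG", "ZFP42", "ZSCAN10",
            "FOXD3", "PRDM14", "ZIC3", "SALL4", "LIN28A", "TBX3", "GATA4",
            "HOXA1", "HOXB4", "HOXD10", "FOXA1", "POU3F2", "SALL1", "SOX17",
            "TBX5", "KLF5", "ZBTB16", "DBP", "SNAI2", "TWIST1", "PRRX1")
  fillers <- character(0)
  stems <- c("ZNF", "ZNF", "ZNF", "HOXA", "FOX", "TBX", "SOX", "POU2F",
             "GATA", "KLF", "ZBTB", "ZSCAN", "ZIC", "NR", "TF", "BHLH")
  i <- 0L
  while (length(unique(c(special, core, fillers))) < n) {
    i <- i + 1L
    fillers <- c(fillers, paste0(stems[(i %% length(stems)) + 1L], 100L + i))
  }
  symbols <- unique(c(special, core, fillers))[seq_len(n)]
  tibble::tibble(symbol = symbols)
}
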