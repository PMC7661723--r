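# Delimiter by extension: .csv -> comma, anything else -> tab.
read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Construct a validated count matrix with its sample design
#'
#' The central container of the pipeline: an integer gene-by-sample count
#' matrix plus a design table assigning each sample to a group, an optional
#' time point (hours) and a replicate index. Validation enforces unique gene
#' and sample identifiers, integral non-negative counts, and a one-to-one
#' match between matrix columns and design rows.
#'
#' @param counts Numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids); or a data frame whose first
#'   column holds gene ids.
#' @param design Data frame with columns `sample`, `group`, optional
#'   `time_h`, optional `replicate`.
#' @return An object of class `reprog_counts`.
#' @export
reprog_counts <- function(counts, design) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1]])
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- ids
    counts <- m
  }
  storage.mode(counts) <- "double"
  design <- tibble::as_tibble(design)

  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g) > 0) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s) > 0) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-integer or negative counts at ",
         paste(sprintf("[%s, %s]", rownames(counts)[bad[, 1]],
                       colnames(counts)[bad[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(c("sample", "group") %in% names(design))) {
    stop("design needs 'sample' and 'group' columns", call. = FALSE)
  }
  design$sample <- as.character(design$sample)
  design$group <- as.character(design$group)
  if (!"time_h" %in% names(design)) design$time_h <- NA_real_
  design$time_h <- as.numeric(design$time_h)
  if (!"replicate" %in% names(design)) {
    design <- dplyr::mutate(
      dplyr::group_by(design, .data$group, .data$time_h),
      replicate = dplyr::row_number())
    design <- dplyr::ungroup(design)
  }
  design$replicate <- as.integer(design$replicate)
  missing_design <- setdiff(colnames(counts), design$sample)
  if (length(missing_design) > 0) {
    stop("samples missing from design: ",
         paste(missing_design, collapse = ", "), call. = FALSE)
  }
  missing_counts <- setdiff(design$sample, colnames(counts))
  if (length(missing_counts) > 0) {
    stop("design samples missing from counts: ",
         paste(missing_counts, collapse = ", "), call. = FALSE)
  }
  design <- design[match(colnames(counts), design$sample), ]

  structure(list(counts = counts, design = design),
            class = "reprog_counts")
}

#' Read a count matrix and sample design from disk
#'
#' Delimiter is chosen by extension (`.csv` comma, otherwise tab). The first
#' column of the matrix file is the gene identifier; remaining columns are
#' samples. Genes absent from any TF catalog are retained: normalization is
#' genome-wide and catalog subsetting happens downstream.
#'
#' @param matrix_path Path to the counts table (genes as rows).
#' @param design_path Path to the design table (columns `sample`, `group`,
#'   optional `time_h`, `replicate`).
#' @return A [reprog_counts] object.
#' @export
read_counts <- function(matrix_path, design_path) {
  reprog_counts(read_delim_auto(matrix_path), read_delim_auto(design_path))
}

#' Write a count matrix and design to TSV
#'
#' Inverse of [read_counts()]: reading the written files reproduces the
#' object exactly.
#'
#' @param x A [reprog_counts] object.
#' @param matrix_path,design_path Output TSV paths.
#' @return `matrix_path`, invisibly.
#' @export
write_counts <- function(x, matrix_path, design_path) {
  tb <- tibble::as_tibble(cbind(
    tibble::tibble(gene = rownames(x$counts)),
    tibble::as_tibble(x$counts)))
  readr::write_tsv(tb, matrix_path)
  readr::write_tsv(x$design, design_path)
  invisible(matrix_path)
}

#' @export
print.reprog_counts <- function(x, ...) {
  cat(sprintf("<reprog_counts> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- dplyr::count(x$design, .data$group, .data$time_h)
  print(tab)
  invisible(x)
}

#' @export
as_tibble.reprog_counts <- function(x, ...) {
  tibble::as_tibble(cbind(tibble::tibble(gene = rownames(x$counts)),
                          tibble::as_tibble(x$counts)))
}

#' @export
dim.reprog_counts <- function(x) dim(x$counts)

#' Samples belonging to a group (and optionally a time point)
#' @param design A design tibble.
#' @param group Group label.
#' @param time_h Optional time point in hours.
#' @return Character vector of sample ids.
#' @export
samples_of <- function(design, group, time_h = NULL) {
  keep <- design$group == group
  if (!is.null(time_h)) keep <- keep & !is.na(design$time_h) &
      design$time_h == time_h
  design$sample[keep]
}

#' Log2-transform a normalized matrix for visualization
#'
#' Element-wise `log2(normalized + pseudocount)`. Used only for heat-map and
#' distance computations; statistical tests always run on the count scale.
#'
#' @param norm A [normalize_counts()] result, or a numeric matrix of
#'   normalized values.
#' @param pseudocount Positive offset added before the log (default 1).
#' @return Numeric matrix of the same shape.
#' @export
#' @examples
#' log2_matrix(matrix(c(0, 63), 1, 2, dimnames = list("g", c("a", "b"))))
log2_matrix <- function(norm, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  values <- if (inherits(norm, "reprog_norm")) norm$values else norm
  log2(values + pseudocount)
}
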