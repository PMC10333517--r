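#' Count dataset container
#'
#' Bundles a genes x cells integer UMI count matrix with per-cell metadata
#' and the derived partition of cells into (treatment, time, replicate)
#' conditions. Each cell belongs to exactly one condition and every condition
#' has at least one cell.
#'
#' @param counts Non-negative integer matrix (genes x cells), dense or
#'   sparse (`dgCMatrix`). Stored sparse when density < 30%.
#' @param cell_meta Data frame with one row per cell and columns `cell_id`,
#'   `species`, `treatment`, `time_h`, `replicate`.
#' @param gene_ids Optional gene identifiers (default: rownames of counts).
#' @return Object of class `count_dataset`: list with `counts`, `gene_ids`,
#'   `cell_meta`, and `condition` (factor of length n_cells with levels
#'   "treatment_time_replicate").
#' @export
count_dataset <- function(counts, cell_meta, gene_ids = rownames(counts)) {
  required <- c("cell_id", "species", "treatment", "time_h", "replicate")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols) > 0) {
    stop("cell_meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (ncol(counts) != nrow(cell_meta)) {
    stop("dimension mismatch: counts has ", ncol(counts),
         " cells but metadata has ", nrow(cell_meta), " rows")
  }
  validate_counts(counts, cell_meta$cell_id)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))

  # conditions are the observed (treatment, time, replicate) combinations;
  # combinations absent from the data are simply absent conditions (no
  # imputation). But a condition label explicitly declared via factor levels
  # that no cell carries is an error rather than silently dropped.
  for (col in c("treatment", "time_h", "replicate")) {
    v <- cell_meta[[col]]
    if (is.factor(v)) {
      unused <- setdiff(levels(v), unique(as.character(v)))
      if (length(unused) > 0) {
        stop("labelled ", col, " with zero cells: ",
             paste(unused, collapse = ", "))
      }
    }
  }
  cond <- condition_key(cell_meta)

  counts <- maybe_sparse(counts)
  rownames(counts) <- gene_ids
  colnames(counts) <- as.character(cell_meta$cell_id)
  structure(list(counts = counts, gene_ids = gene_ids,
                 cell_meta = cell_meta, condition = cond),
            class = "count_dataset")
}

condition_key <- function(cell_meta) {
  interaction(cell_meta$treatment, cell_meta$time_h, cell_meta$replicate,
              sep = "_", drop = TRUE)
}

validate_counts <- function(counts, cell_ids) {
  x <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  bad <- which(x < 0 | x != floor(x))
  if (length(bad) > 0) {
    # locate the first offending entry by cell for a useful message
    m <- as.matrix(counts)
    off <- which(m < 0 | m != floor(m), arr.ind = TRUE)[1, ]
    stop("counts must be non-negative integers; offending entry in cell '",
         cell_ids[off[2]], "' (gene row ", off[1], ")")
  }
  invisible(TRUE)
}

maybe_sparse <- function(counts) {
  dens <- if (methods::is(counts, "sparseMatrix")) {
    length(counts@x) / prod(dim(counts))
  } else {
    mean(counts != 0)
  }
  if (dens < 0.3) {
    methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  } else {
    as.matrix(counts)
  }
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("<count_dataset> %d genes x %d cells, %d conditions\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$condition)))
  invisible(x)
}

#' Read a UMI count matrix with cell metadata
#'
#' Reads a genes x cells matrix from Matrix Market (`.mtx`) or CSV (header =
#' cell ids, first column = gene ids) together with a TSV metadata table
#' (columns `cell_id`, `species`, `treatment`, `time_h`, `replicate`, one row
#' per cell, in column order of the matrix), validates it, and derives the
#' condition partition.
#'
#' @param matrix_path Path to the `.mtx` or `.csv` counts file. For MTX, gene
#'   ids are read from `<matrix_path>.genes` if present (one id per line).
#' @param meta_path Path to the TSV metadata.
#' @param verbose Log dataset size to the console.
#' @return A [count_dataset()].
#' @export
read_counts <- function(matrix_path, meta_path, verbose = FALSE) {
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    counts <- Matrix::readMM(matrix_path)
    gene_file <- paste0(matrix_path, ".genes")
    gene_ids <- if (file.exists(gene_file)) readLines(gene_file) else NULL
  } else {
    tab <- utils::read.csv(matrix_path, check.names = FALSE)
    gene_ids <- as.character(tab[[1]])
    counts <- as.matrix(tab[, -1, drop = FALSE])
  }
  ds <- count_dataset(counts, meta, gene_ids = gene_ids)
  if (verbose) {
    message(sprintf("read %d genes, %d cells, %d conditions",
                    nrow(ds$counts), ncol(ds$counts), nlevels(ds$condition)))
  }
  ds
}

#' Write a count dataset to disk
#'
#' Inverse of [read_counts()]: writes the counts as MTX (plus a `.genes`
#' sidecar) or CSV, and the metadata as TSV, in the dialect [read_counts()]
#' accepts, so that write -> read round-trips the dataset.
#'
#' @param ds A [count_dataset()].
#' @param dir Output directory (created if needed).
#' @param format "mtx" or "csv".
#' @return Invisibly, the paths written (named list `matrix`, `meta`).
#' @export
write_counts <- function(ds, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(dir, "meta.tsv")
  utils::write.table(ds$cell_meta, meta_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (format == "mtx") {
    matrix_path <- file.path(dir, "counts.mtx")
    Matrix::writeMM(methods::as(methods::as(ds$counts, "CsparseMatrix"),
                                "generalMatrix"), matrix_path)
    writeLines(ds$gene_ids, paste0(matrix_path, ".genes"))
  } else {
    matrix_path <- file.path(dir, "counts.csv")
    tab <- data.frame(gene_id = ds$gene_ids,
                      as.matrix(ds$counts), check.names = FALSE)
    utils::write.csv(tab, matrix_path, row.names = FALSE)
  }
  invisible(list(matrix = matrix_path, meta = meta_path))
}

#' Median-scale counts per cell
#'
#' Scales each cell so that its total count equals the median pre-scaling
#' total across cells (the standard per-cell library-size normalization for
#' UMI data): scale_factors[c] = median(totals) / totals[c]. An integer view
#' (round half up) of the scaled matrix is kept for distribution-based model
#' fitting. Cells with zero total get scale factor 1 and a warning rather
#' than being dropped.
#'
#' @param ds A [count_dataset()].
#' @return Object of class `normalized_dataset`: the fields of `ds` plus
#'   `scaled` (real matrix), `integer_view` (integer matrix), and
#'   `scale_factors` (per-cell positive reals).
#' @export
median_scale <- function(ds) {
  stopifnot(inherits(ds, "count_dataset"))
  totals <- Matrix::colSums(ds$counts)
  if (all(totals == 0)) stop("no cell has a positive total count")
  med <- stats::median(totals)
  sf <- med / totals
  zero <- !is.finite(sf)
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total count; scale factor set to 1")
    sf[zero] <- 1
  }
  scaled <- sweep(as.matrix(ds$counts), 2, sf, `*`)
  integer_view <- round_half_up(scaled)
  out <- ds
  out$scaled <- scaled
  out$integer_view <- integer_view
  out$scale_factors <- sf
  class(out) <- c("normalized_dataset", "count_dataset")
  out
}

# Deterministic round-half-up (base round() ties to even).
round_half_up <- function(x) floor(x + 0.5)

#' Pass counts through without per-cell scaling
#'
#' Wraps a [count_dataset()] as a `normalized_dataset` with unit scale
#' factors. Intended for synthetic data whose counts are generated on a
#' common scale already (per-cell median scaling is meaningless for a
#' single-gene matrix and would erase the generated condition structure).
#'
#' @param ds A [count_dataset()].
#' @return A `normalized_dataset` with `scaled` equal to the counts.
#' @export
identity_scale <- function(ds) {
  stopifnot(inherits(ds, "count_dataset"))
  out <- ds
  out$scaled <- as.matrix(ds$counts)
  out$integer_view <- round_half_up(out$scaled)
  out$scale_factors <- rep(1, ncol(ds$counts))
  class(out) <- c("normalized_dataset", "count_dataset")
  out
}

#' Per-condition count vector for one gene
#'
#' Extracts the values of one gene over the cells of one condition, from
#' either the median-scaled or the rounded-integer view.
#'
#' @param nds A [median_scale()] result.
#' @param gene Gene identifier.
#' @param condition Condition key ("treatment_time_replicate").
#' @param view "scaled" or "integer".
#' @return Numeric vector, one value per cell of the condition.
#' @export
condition_counts <- function(nds, gene, condition,
                             view = c("scaled", "integer")) {
  view <- match.arg(view)
  stopifnot(inherits(nds, "normalized_dataset"))
  if (!gene %in% nds$gene_ids) stop("unknown gene: ", gene)
  if (!condition %in% levels(nds$condition)) {
    stop("unknown condition: ", condition)
  }
  mat <- if (view == "scaled") nds$scaled else nds$integer_view
  as.numeric(mat[match(gene, nds$gene_ids), nds$condition == condition])
}

#' Read a table of mRNA half-lives
#'
#' Two-column TSV/CSV (gene id, half-life in minutes). Returns the table with
#' the implied first-order degradation rate k_d = log(2) / t_1/2 appended.
#'
#' @param path File path (TSV by default; CSV if the extension is `.csv`).
#' @return Data frame with columns `gene_id`, `half_life_min`, `k_d`.
#' @export
read_half_lives <- function(path) {
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  names(tab)[1:2] <- c("gene_id", "half_life_min")
  if (any(tab$half_life_min <= 0)) stop("half-lives must be positive")
  tab$k_d <- half_life_to_rate(tab$half_life_min)
  tab
}
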