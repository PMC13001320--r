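# Core containers and readers/writers for every external format the
# pipeline touches: expression TSV (genes x samples), sample metadata TSV,
# GMT gene sets, and ECHO-style phase tables. All tables are UTF-8 TSV with
# a decimal point and no thousands separators; expression matrices are
# genes-in-rows; ZT is stored in [0, 24) with ZT 24 == 0.

AGE_GROUPS <- c("young", "old")
SEXES <- c("M", "F")

#' Construct a validated expression dataset
#'
#' Bundles a nonnegative genes-by-samples expression matrix with per-sample
#' metadata (Zeitgeber time, age group, sex, replicate). Every matrix column
#' must have a matching metadata row; gene identifiers must be unique.
#'
#' @param matrix Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names are sample identifiers.
#' @param samples Data frame with columns `sample_id`, `zt`, `age_group`,
#'   `sex`, `replicate` (as returned by [read_sample_metadata()]).
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `gene_ids` and `samples`.
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), zt = c(3, 15),
#'                    age_group = "young", sex = c("M", "F"),
#'                    replicate = c("r1", "r1"))
#' expression_dataset(m, meta)
#' @export
expression_dataset <- function(matrix, samples) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must have gene row names and sample column names")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
               collapse = ", "))
  if (any(matrix < 0)) stop("expression values must be nonnegative")
  samples <- validate_sample_meta(samples)
  if (!setequal(colnames(matrix), samples$sample_id) ||
      ncol(matrix) != nrow(samples))
    stop("matrix columns and sample metadata do not match one-to-one")
  samples <- samples[match(colnames(matrix), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(matrix = matrix, gene_ids = rownames(matrix),
                 samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples\n")
  cat("  ZT:", paste(sort(unique(x$samples$zt)), collapse = ", "), "\n")
  cat("  age groups:",
      paste(names(table(x$samples$age_group)), table(x$samples$age_group),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

validate_sample_meta <- function(samples) {
  required <- c("sample_id", "zt", "age_group", "sex", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "))
  samples <- as.data.frame(samples)[required]
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  zt <- as.numeric(samples$zt)
  if (anyNA(zt)) stop("non-numeric zt value in sample metadata")
  if (any(zt < 0 | zt >= 48))
    stop("zt values must lie in [0, 48); got ",
         paste(zt[zt < 0 | zt >= 48], collapse = ", "))
  if (any(zt >= 24)) {
    warning("zt values in [24, 48) wrapped into [0, 24)")
    zt <- zt %% 24
  }
  samples$zt <- zt
  if (!all(samples$age_group %in% AGE_GROUPS))
    stop("age_group must be one of: ", paste(AGE_GROUPS, collapse = ", "),
         "; got ",
         paste(setdiff(unique(samples$age_group), AGE_GROUPS),
               collapse = ", "))
  if (!all(samples$sex %in% SEXES))
    stop("sex must be one of: ", paste(SEXES, collapse = ", "))
  samples$replicate <- as.character(samples$replicate)
  samples
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Every cell must parse as a nonnegative number; duplicated gene ids and
#' unparseable cells are hard errors that name the offender.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene row names and sample column names.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expression file needs a gene column plus >= 1 sample")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value '", vals[bad[1], bad[2]],
         "' at gene '", genes[bad[1]], "', sample '",
         colnames(vals)[bad[2]], "'")
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Write an expression matrix (or dataset) to TSV
#'
#' Inverse of [read_expression_matrix()]; round trips are exact to numeric
#' printing precision (15 significant digits).
#'
#' @param x A numeric matrix with dimnames, or an `expression_dataset`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  if (inherits(x, "expression_dataset")) x <- x$matrix
  df <- data.frame(gene = rownames(x),
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' Requires columns `sample_id`, `zt`, `age_group`, `sex`, `replicate`.
#' ZT values in `[24, 48)` are wrapped into `[0, 24)` with a warning;
#' values outside `[0, 48)` are errors, as are age groups outside
#' young/old and sexes outside M/F.
#'
#' @param path Path to a tab-separated file.
#' @return A validated data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  validate_sample_meta(df)
}

#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB gene1 TAB ...`.
#' Duplicate genes within a set are removed (first occurrence kept);
#' duplicate set names and sets without genes are errors.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: list with `sets`
#'   (named list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  names_ <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names_))
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(lengths(sets) == 0))
    stop("gene set(s) with no genes: ",
         paste(names_[lengths(sets) == 0], collapse = ", "))
  names(sets) <- names_
  names(desc) <- names_
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional named character vector of descriptions.
#' @export
gene_set_collection <- function(sets,
                                descriptions = setNames(rep("", length(sets)),
                                                        names(sets))) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("gene sets must have unique names")
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets")
  if (length(x$sets))
    cat("; set sizes", min(lengths(x$sets)), "-", max(lengths(x$sets)))
  cat("\n")
  invisible(x)
}

#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ECHO-style phase table
#'
#' Expects exactly the columns `gene`, `hours_shifted`, `period`,
#' `initial_amplitude` (a nonnegative amplitude weight). Validates
#' `period > 0` and `initial_amplitude >= 0`.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame with the four phase-table columns.
#' @export
read_phase_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "", comment.char = "")
  validate_phase_table(df)
}

validate_phase_table <- function(df) {
  required <- c("gene", "hours_shifted", "period", "initial_amplitude")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("phase table is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- as.data.frame(df)
  df$gene <- as.character(df$gene)
  for (col in required[-1]) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]])) stop("non-numeric value in phase-table column ", col)
  }
  if (any(df$period <= 0)) stop("phase-table periods must be > 0")
  if (any(df$initial_amplitude < 0))
    stop("initial_amplitude must be nonnegative")
  df[required]
}

#' @export
write_phase_table <- function(df, path) {
  df <- validate_phase_table(df)
  num <- c("hours_shifted", "period", "initial_amplitude")
  df[num] <- lapply(df[num], function(v)
    format(v, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense single-cell expression table (genes x cells, TSV)
#'
#' Thin wrapper around [read_expression_matrix()]; provided for symmetry
#' with sparse triplet input.
#' @param path Path to a TSV of counts or log-normalized values.
#' @export
read_cell_matrix <- function(path) read_expression_matrix(path)

#' Read a sparse triplet single-cell matrix
#'
#' MTX-convention triplets: 1-based `gene_index cell_index value` rows in
#' `path`, with gene and cell identifiers in one-per-line sidecar files.
#'
#' @param path Triplet TSV with columns gene_index, cell_index, value.
#' @param genes_path,cells_path Sidecar files of row/column identifiers.
#' @return A dense numeric matrix (genes x cells).
#' @export
read_cell_triplets <- function(path, genes_path, cells_path) {
  genes <- readLines(genes_path, warn = FALSE)
  cells <- readLines(cells_path, warn = FALSE)
  trip <- utils::read.delim(path, header = TRUE, sep = "\t")
  need <- c("gene_index", "cell_index", "value")
  if (!all(need %in% names(trip)))
    stop("triplet file needs columns: ", paste(need, collapse = ", "))
  if (any(trip$gene_index < 1 | trip$gene_index > length(genes)) ||
      any(trip$cell_index < 1 | trip$cell_index > length(cells)))
    stop("triplet index out of range (indices are 1-based)")
  m <- matrix(0, length(genes), length(cells),
              dimnames = list(genes, cells))
  m[cbind(trip$gene_index, trip$cell_index)] <- trip$value
  m
}
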